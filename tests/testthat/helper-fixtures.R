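# Fixtures built in code; no binary data.

kB <- hemeET::et_constants[["kB"]]

# Heavy-atom alanine with idealized geometry; covalent topology is
# N-CA, CA-C, C-O, CA-CB (4 bonds).
alanine_frame <- function() {
  make_frame(
    name = c("N", "CA", "C", "O", "CB"),
    element = c("N", "C", "C", "O", "C"),
    resname = "ALA", resno = 1,
    x = c(0.00, 1.46, 2.00, 1.40, 2.23),
    y = c(0.00, 0.00, 1.42, 2.49, -1.30),
    z = 0
  )
}

# 24 macrocycle atoms (plus FE) of a heme on a circle; names follow the
# standard PDB convention, coordinates are arbitrary.
heme_frame <- function(resno = 1, drop = NULL) {
  nms <- c("NA", "NB", "NC", "ND",
           paste0("C", rep(1:4, times = 4), rep(c("A", "B", "C", "D"), each = 4)),
           "CHA", "CHB", "CHC", "CHD")
  ang <- 2 * pi * seq_along(nms) / length(nms)
  fr <- make_frame(
    name = c(nms, "FE"),
    element = c(substr(nms, 1, 1), "FE"),
    resname = "HEM", resno = resno,
    x = c(3.4 * cos(ang), 0), y = c(3.4 * sin(ang), 0), z = 0
  )
  if (!is.null(drop)) fr <- fr[fr$name != drop, ]
  fr
}

# random tunneling graph for oracle-equivalence property tests
random_graph_case <- function(n_max = 12) {
  n <- sample(4:n_max, 1)
  p <- stats::runif(1, 0.25, 0.6)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sel <- stats::runif(nrow(pairs)) < p
  if (sum(sel) == 0L) sel[sample(length(sel), 1)] <- TRUE
  dec <- stats::runif(sum(sel), 0.01, 1)
  dec[stats::runif(sum(sel)) < 0.15] <- 1   # conductive-like ties
  g <- tunneling_graph(pairs[sel, 1], pairs[sel, 2], dec)
  don <- sample(n, sample(1:2, 1))
  acc <- sample(setdiff(seq_len(n), don), sample(1:2, 1))
  list(graph = g, donor = intersect(don, g$nodes),
       acceptor = intersect(acc, g$nodes))
}

# assert that engine and oracle agree (both error, or identical result)
expect_oracle_agreement <- function(case) {
  if (length(case$donor) == 0L || length(case$acceptor) == 0L)
    return(invisible(TRUE))
  a <- tryCatch(best_pathway(case$graph, case$donor, case$acceptor),
                error = function(e) "no-path")
  b <- tryCatch(brute_force_best_path(case$graph, case$donor, case$acceptor),
                error = function(e) "no-path")
  if (identical(a, "no-path") || identical(b, "no-path")) {
    expect_identical(a, b)
  } else {
    expect_identical(as.integer(a$atoms), as.integer(b$atoms))
    expect_identical(a$epsilon_tot, b$epsilon_tot)
  }
  invisible(TRUE)
}
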