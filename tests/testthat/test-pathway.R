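# Tunneling graph construction and the best-path search.

test_that("graph edges carry the expected types and decays", {
  # 4-atom covalent chain: 3 covalent edges at eps_c, plus weak
  # through-space second-neighbour contacts
  fr <- make_frame(name = paste0("C", 1:4), element = "C", resname = "UNK",
                   resno = 1, x = 1.5 * (0:3), y = 0, z = 0)
  g <- build_tunneling_graph(fr, perceive_covalent_bonds(fr))
  cov <- g$edges[g$edges$type == "covalent", ]
  expect_equal(nrow(cov), 3L)
  expect_true(all(cov$decay == 0.6))

  # bonded pair inside a conductive set: single conductive edge, decay 1
  fr2 <- make_frame(name = c("C1A", "C2A"), element = "C", resname = "HEM",
                    resno = 1, x = c(0, 1.4), y = 0, z = 0)
  g2 <- build_tunneling_graph(fr2, perceive_covalent_bonds(fr2),
                              conductive_sets = list(1:2))
  expect_equal(nrow(g2$edges), 1L)
  expect_identical(g2$edges$type, "conductive")
  expect_identical(g2$edges$decay, 1)

  # pair beyond the through-space cutoff: no edge
  fr3 <- make_frame(name = c("C1", "C2"), element = "C", resname = "UNK",
                    resno = 1:2, x = c(0, 10), y = 0, z = 0)
  expect_error(build_tunneling_graph(fr3, perceive_covalent_bonds(fr3)),
               "empty")
  # all decays in (0, 1], one edge per pair
  e <- g$edges
  expect_true(all(e$decay > 0 & e$decay <= 1))
  expect_false(anyDuplicated(paste(e$i, e$j)) > 0)
})

test_that("best path prefers bonded chains over long jumps", {
  # donor - X - acceptor via two covalent bonds (0.36) vs a direct 6 A
  # through-space jump (0.6 exp(-1.1 * 4.6) ~ 3.8e-3)
  g <- tunneling_graph(i = c(1, 2, 1), j = c(2, 3, 3),
                       decay = c(0.6, 0.6, space_decay(6.0)),
                       type = c("covalent", "covalent", "through_space"))
  pw <- best_pathway(g, donor = 1, acceptor = 3)
  expect_identical(as.integer(pw$atoms), c(1L, 2L, 3L))
  expect_equal(pw$epsilon_tot, 0.36)
  expect_equal(pw$n_covalent, 2L)

  # adjacent by one conductive edge
  g1 <- tunneling_graph(1, 2, 1, type = "conductive")
  pw1 <- best_pathway(g1, 1, 2)
  expect_identical(pw1$epsilon_tot, 1)

  # disconnected graph: explicit failure
  g2 <- tunneling_graph(i = c(1, 3), j = c(2, 4), decay = c(0.5, 0.5))
  expect_error(best_pathway(g2, 1, 4), "no pathway")
  expect_error(best_pathway(g1, 1, 1:2), "disjoint")
})

test_that("search equals exhaustive enumeration on random graphs", {
  set.seed(101)
  for (k in 1:40) expect_oracle_agreement(random_graph_case())
})

test_that("restricting the medium never improves the best decay", {
  set.seed(202)
  for (k in 1:20) {
    case <- random_graph_case(n_max = 10)
    full <- tryCatch(best_pathway(case$graph, case$donor, case$acceptor),
                     error = function(e) NULL)
    if (is.null(full)) next
    # drop a random edge not incident to donor/acceptor entry points
    e <- case$graph$edges
    if (nrow(e) < 2L) next
    drop <- sample(nrow(e), 1)
    sub <- case$graph
    sub$edges <- e[-drop, , drop = FALSE]
    red <- tryCatch(best_pathway(sub, case$donor, case$acceptor),
                    error = function(e) NULL)
    if (!is.null(red)) expect_lte(red$epsilon_tot, full$epsilon_tot + 1e-12)
  }
})

test_that("best decay is invariant under rigid-body motion of the frame", {
  toy <- make_toy_structure(list(type = "bridge"))
  pw0 <- toy_best_pathway(toy)
  th <- 1.1
  rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  fr <- toy$frame
  xyz <- as.matrix(fr[, c("x", "y", "z")]) %*% rot
  fr$x <- xyz[, 1] - 2; fr$y <- xyz[, 2] + 7; fr$z <- xyz[, 3] + 0.5
  toy2 <- toy; toy2$frame <- fr
  pw1 <- toy_best_pathway(toy2)
  expect_equal(pw1$epsilon_tot, pw0$epsilon_tot, tolerance = 1e-9)
  expect_identical(pw1$atoms, pw0$atoms)
})

test_that("pathway decomposition counts steps and labels the route", {
  toy <- make_toy_structure(list(type = "bridge"))
  pw <- toy_best_pathway(toy)
  expect_equal(pw$n_covalent + pw$n_hbond + pw$n_ts + pw$n_conductive,
               length(pw$edge_types))
  expect_equal(pw$epsilon_tot, prod(pw$edge_decays), tolerance = 1e-12)
  expect_identical(pw$route_label, "Trp378")
  expect_identical(pw$mediating_residues, c("Hem1", "Trp378", "Hem2"))

  direct <- toy_best_pathway(make_toy_structure(list(type = "direct")))
  expect_identical(direct$route_label, "direct")
  expect_equal(direct$n_ts, 1L)
})

test_that("ensembles preserve frame order and route occupancies", {
  toy <- make_toy_structure(list(type = "bridge"))
  frames <- rep(list(toy$frame), 6)
  ens <- pathway_ensemble(frames, toy$donor, toy$acceptor,
                          toy$conductive_sets)
  tab <- ensemble_table(ens)
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$epsilon_tot == tab$epsilon_tot[1]))

  # alternating constructed geometries: 50/50 route occupancy
  t_trp <- make_toy_structure(list(type = "two_route", h_trp = 1, h_phe = 2))
  t_phe <- make_toy_structure(list(type = "two_route", h_trp = 2, h_phe = 1))
  frames2 <- rep(list(t_trp$frame, t_phe$frame), 5)
  ens2 <- pathway_ensemble(frames2, t_trp$donor, t_trp$acceptor,
                           t_trp$conductive_sets)
  occ <- table(ensemble_table(ens2)$route_label)
  expect_equal(as.integer(occ[c("Trp378", "Phe348")]), c(5L, 5L))
})

test_that("visualization export writes the path atoms and a viewer script", {
  toy <- make_toy_structure(list(type = "bridge"))
  pw <- toy_best_pathway(toy)
  prefix <- tempfile()
  files <- export_path_visualization(pw, toy$frame, prefix)
  expect_true(all(file.exists(files)))
  back <- read_structure(files[1])[[1]]
  expect_equal(nrow(back), length(pw$atoms))
  expect_true(any(grepl("cylinder", readLines(files[2]))))
  empty <- pw; empty$atoms <- integer(0)
  expect_error(export_path_visualization(empty, toy$frame, tempfile()),
               "empty")
})
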