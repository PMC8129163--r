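## Synthetic-data generators.
##
## These emulate the statistical structure of the real trajectory
## observables -- not the underlying molecular physics -- so that every
## analysis stage can be exercised against known ground truth:
##   * LRA-consistent Gaussian gap series: state means DA +/- lambda,
##     variance 2*lambda*kB*T in both states, optional AR(1) correlation
##     and component splits;
##   * bimodal gap series: slow two-regime Markov switching superimposed on
##     the initial-state gaps (total variance exceeds the within-regime
##     variance, driving the ergodicity factor above 1);
##   * telegraph two-site distance series (modes near 2.5 and 4.3 A);
##   * toy structures with hand-set geometry whose best pathway and decay
##     are known in closed form;
##   * a brute-force best-path oracle for small graphs.
## All generators are deterministic under a fixed seed, which is stored in
## the output metadata.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

.ar1_noise <- function(n, sd, tau) {
  if (tau <= 0) return(stats::rnorm(n, 0, sd))
  phi <- exp(-1 / tau)
  z <- numeric(n)
  z[1] <- stats::rnorm(1, 0, sd)
  if (n > 1L) {
    innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
    for (t in 2:n) z[t] <- phi * z[t - 1] + innov[t - 1]
  }
  z
}

#' Generate an LRA-consistent pair of gap series
#'
#' Initial-state gaps are drawn from `Normal(delta_A + lambda, 2 lambda kB T)`
#' and final-state gaps from `Normal(delta_A - lambda, 2 lambda kB T)`, the
#' exact sampling distributions assumed by the linear-response estimators,
#' optionally with AR(1) time correlation.
#'
#' @param delta_A reaction free energy in eV.
#' @param lambda reorganization energy in eV, positive.
#' @param temperature temperature in K.
#' @param n samples per state.
#' @param dt sampling interval in ps.
#' @param tau AR(1) autocorrelation time in samples (0 = independent).
#' @param seed RNG seed (stored in the output metadata).
#' @param components optional data.frame with columns `name`, `delta_A`,
#'   `lambda` and optionally `var_frac` describing a split of the gap over
#'   molecular components; `delta_A` and `lambda` columns must sum to the
#'   totals and `var_frac` to 1 (default: equal variance split). Components
#'   are generated independently and summed, so the total keeps the exact
#'   LRA distribution.
#' @return list with elements `initial` and `final` (both [gap_series()])
#'   and attribute `spec` recording all generator parameters.
#' @export
generate_lra_gaps <- function(delta_A, lambda, temperature = 310, n = 1000,
                              dt = 2, tau = 0, seed = NULL,
                              components = NULL) {
  if (lambda <= 0) stop("lambda must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  if (n < 2) stop("need n >= 2")
  v <- 2 * lambda * et_constants[["kB"]] * temperature
  times <- dt * (seq_len(n) - 1)
  if (!is.null(components)) {
    if (abs(sum(components$delta_A) - delta_A) > 1e-9 ||
        abs(sum(components$lambda) - lambda) > 1e-9)
      stop("component delta_A and lambda must sum to the totals")
    if (is.null(components$var_frac))
      components$var_frac <- rep(1 / nrow(components), nrow(components))
    if (abs(sum(components$var_frac) - 1) > 1e-9)
      stop("component var_frac must sum to 1")
  }
  gen_state <- function(sign) {
    if (is.null(components)) {
      gaps <- delta_A + sign * lambda + .ar1_noise(n, sqrt(v), tau)
      gap_series(times, gaps, state = if (sign > 0) "initial" else "final",
                 temperature = temperature)
    } else {
      comp <- sapply(seq_len(nrow(components)), function(k) {
        components$delta_A[k] + sign * components$lambda[k] +
          .ar1_noise(n, sqrt(v * components$var_frac[k]), tau)
      })
      colnames(comp) <- components$name
      gap_series(times, rowSums(comp),
                 state = if (sign > 0) "initial" else "final",
                 temperature = temperature,
                 components = as.data.frame(comp),
                 component_tol = 1e-9 * max(1, abs(delta_A) + lambda))
    }
  }
  out <- .with_seed(seed, list(initial = gen_state(+1),
                               final = gen_state(-1)))
  attr(out, "spec") <- list(delta_A = delta_A, lambda = lambda,
                            temperature = temperature, n = n, dt = dt,
                            tau = tau, seed = seed)
  out
}

# symmetric two-state Markov chain of +/-1, switch probability q per step
.telegraph_chain <- function(n, q_up_down, q_down_up, start_p_up = NULL) {
  if (is.null(start_p_up))
    start_p_up <- q_down_up / (q_up_down + q_down_up)
  s <- logical(n)
  s[1] <- stats::runif(1) < start_p_up
  if (n > 1L) {
    u <- stats::runif(n - 1)
    for (t in 2:n) {
      s[t] <- if (s[t - 1]) u[t - 1] >= q_up_down else u[t - 1] < q_down_up
    }
  }
  s
}

#' Generate a bimodal (slowly switching) gap-series pair
#'
#' As [generate_lra_gaps()], but the initial-state mean wanders between two
#' regimes `+/- mode_offset/2` following a slow symmetric telegraph
#' process. The regime occupancy is symmetric, so the state means (and
#' hence the Stokes reorganization energy) are unchanged in expectation
#' while the initial-state variance is inflated by `(mode_offset/2)^2`,
#' pushing the ergodicity factor above 1 -- the signature of a slow hidden
#' degree of freedom.
#'
#' @inheritParams generate_lra_gaps
#' @param mode_offset separation between the two regime means in eV;
#'   0 reduces to the unimodal generator.
#' @param switch_prob per-sample probability of switching regime (small =
#'   slow switching).
#' @return list with `initial` and `final` gap series and a `spec`
#'   attribute (including the hidden regime sequence as `regimes`).
#' @export
generate_bimodal_gaps <- function(delta_A, lambda, mode_offset,
                                  switch_prob = 0.001, temperature = 310,
                                  n = 1000, dt = 2, seed = NULL) {
  if (switch_prob <= 0 || switch_prob >= 1)
    stop("switch_prob must lie in (0, 1)")
  base <- generate_lra_gaps(delta_A, lambda, temperature, n, dt, tau = 0,
                            seed = seed)
  regimes <- .telegraph_chain(n, switch_prob, switch_prob, start_p_up = 0.5)
  out <- base
  out$initial$gap <- out$initial$gap + ifelse(regimes, 1, -1) * mode_offset / 2
  sp <- attr(base, "spec")
  sp$mode_offset <- mode_offset
  sp$switch_prob <- switch_prob
  sp$regimes <- regimes
  attr(out, "spec") <- sp
  out
}

#' Generate a telegraph two-site distance series
#'
#' A two-state Markov jump process between a near site and a far site with
#' Gaussian jitter about the active mode, emulating a dioxygen molecule
#' hopping between an inserted cavity position (around 2.5 A from the
#' cavity center) and an edge position (around 4.3 A). Distances are
#' truncated at zero. Default switching rates depend on the redox state:
#' the near site dominates in the final (reduced terminal heme) state and
#' the far site in the initial state.
#'
#' @param n number of samples.
#' @param mode_near,mode_far site centers in Angstrom.
#' @param width_near,width_far Gaussian jitter standard deviations in
#'   Angstrom.
#' @param rate_near_to_far,rate_far_to_near switching rates in 1/ns;
#'   `NULL` picks state-dependent defaults giving a near-site occupancy of
#'   0.70 in the final state and 0.30 in the initial state.
#' @param dt sampling interval in ps.
#' @param state redox-state label.
#' @param seed RNG seed.
#' @return a [distance_series()] with attribute `truth` (stationary
#'   `fraction_near`, the mode locations, and the rates used).
#' @export
generate_two_site_distance <- function(n, mode_near = 2.5, mode_far = 4.3,
                                       width_near = 0.2, width_far = 0.2,
                                       rate_near_to_far = NULL,
                                       rate_far_to_near = NULL,
                                       dt = 20,
                                       state = c("initial", "final"),
                                       seed = NULL) {
  state <- match.arg(state)
  if (mode_near >= mode_far) stop("mode_near must be below mode_far")
  if (is.null(rate_near_to_far))
    rate_near_to_far <- if (state == "final") 0.3 else 0.7
  if (is.null(rate_far_to_near))
    rate_far_to_near <- if (state == "final") 0.7 else 0.3
  if (rate_near_to_far <= 0 || rate_far_to_near <= 0)
    stop("rates must be positive")
  q_nf <- rate_near_to_far * dt / 1000
  q_fn <- rate_far_to_near * dt / 1000
  if (q_nf >= 1 || q_fn >= 1) stop("dt too large for the given rates")
  out <- .with_seed(seed, {
    near <- .telegraph_chain(n, q_nf, q_fn)
    mu <- ifelse(near, mode_near, mode_far)
    sd <- ifelse(near, width_near, width_far)
    pmax(stats::rnorm(n, mu, sd), 0)
  })
  ds <- distance_series(dt * (seq_len(n) - 1), out, state = state)
  attr(ds, "truth") <- list(
    fraction_near = q_fn / (q_nf + q_fn),
    mode_near = mode_near, mode_far = mode_far,
    rate_near_to_far = rate_near_to_far,
    rate_far_to_near = rate_far_to_near, dt = dt, seed = seed
  )
  ds
}

## ---- toy structures ------------------------------------------------------

# Chain of atoms along +x at given x positions; y/z default 0.
.toy_atoms <- function(names, elements, resname, resno, x, y = 0, z = 0) {
  list(name = names, element = elements, resname = resname, resno = resno,
       x = x, y = rep_len(y, length(x)), z = rep_len(z, length(x)))
}

.toy_assemble <- function(parts) {
  fields <- c("name", "element", "resname", "resno", "x", "y", "z")
  v <- lapply(fields, function(f)
    unlist(lapply(parts, function(p) rep_len(p[[f]], length(p$x)))))
  names(v) <- fields
  do.call(make_frame, v)
}

#' Build a toy structure with a known optimal tunneling pathway
#'
#' Emits small hand-set geometries -- a conductive donor ring, optionally a
#' bridging residue, an acceptor ring or a dioxygen probe -- whose best
#' pathway and total decay follow in closed form from the decay formulas.
#' Atom and residue names are real PDB names (heme macrocycle naming, TRP,
#' PHE, HIS, OXY) so that bond perception runs unmodified.
#'
#' Blueprint types:
#' \describe{
#'   \item{`bridge`}{donor heme edge - hydrogen bond (`r_hb`) - bridging
#'     Trp378 chain of `n_covalent` bonds - through-space jump (`r_ts`) -
#'     acceptor heme.}
#'   \item{`direct`}{donor heme edge - single jump (`r_ts`) - acceptor
#'     heme.}
#'   \item{`conductive`}{one fully conductive six-atom ring split into
#'     donor and acceptor halves; the best decay is exactly 1.}
#'   \item{`two_route`}{two bridge residues (Trp378 at perpendicular
#'     offset `h_trp`, Phe348 at `h_phe`); the closer bridge carries the
#'     best path.}
#'   \item{`o2_short`}{heme edge - direct jump (`r_ts`) - O2.}
#'   \item{`o2_long`}{heme edge - jump (`r_ts1`) - His317 chain - jump
#'     (`r_ts2`) - O2.}
#' }
#'
#' @param blueprint list with element `type` and the type's distance
#'   parameters (see above); distances in Angstrom.
#' @param path optional file path; when given the structure is also
#'   written as a PDB file.
#' @param params a [pathway_params()] object used for the closed-form
#'   expectations.
#' @return list with `frame`, `donor`, `acceptor`, `conductive_sets`,
#'   `expected` (list `atoms`, `epsilon_tot`, `n_covalent`, `n_hbond`,
#'   `n_ts`, `n_conductive`, `route_label`) and `file` (or `NULL`).
#' @export
make_toy_structure <- function(blueprint, path = NULL,
                               params = pathway_params()) {
  type <- blueprint$type
  bp <- blueprint
  chk <- function(x, lo, hi, what) {
    if (is.null(x) || x <= lo || x > hi)
      stop("geometrically infeasible blueprint: ", what,
           " must lie in (", lo, ", ", hi, "]")
    x
  }
  ec <- params$epsilon_c
  heme3 <- function(resno, x0, n_first = FALSE) {
    nm <- if (n_first) c("NA", "C1A", "C4A") else c("C1A", "C4A", "NA")
    el <- if (n_first) c("N", "C", "C") else c("C", "C", "N")
    .toy_atoms(nm, el, "HEM", resno, x0 + c(0, 1.4, 2.8))
  }

  if (type == "bridge") {
    r_hb <- chk(bp$r_hb %||% 2.9, 2.0, 3.5, "r_hb")
    n_cov <- bp$n_covalent %||% 2L
    if (n_cov < 1L || n_cov > 5L)
      stop("geometrically infeasible blueprint: n_covalent must be 1..5")
    r_ts <- chk(bp$r_ts %||% 3.0, 2.0, params$ts_max_distance, "r_ts")
    x_ne1 <- 2.8 + r_hb
    carb <- c("CE2", "CZ2", "CH2", "CZ3", "CE3")[seq_len(n_cov)]
    x_bridge <- x_ne1 + 1.4 * seq_len(n_cov)
    x_acc <- x_bridge[n_cov] + r_ts
    parts <- list(
      heme3(1, 0),                                             # atoms 1-3
      .toy_atoms(c("NE1", carb), c("N", rep("C", n_cov)),
                 "TRP", 378, c(x_ne1, x_bridge)),              # 4..
      heme3(2, x_acc, n_first = TRUE)                          # acceptor
    )
    frame <- .toy_assemble(parts)
    donor <- 1:3; acceptor <- (4 + n_cov + 1):(4 + n_cov + 3)
    csets <- list(donor, acceptor)
    expected <- list(
      atoms = c(1:3, 4:(4 + n_cov), 4 + n_cov + 1),
      epsilon_tot = hbond_decay(r_hb, params) * ec^n_cov *
        space_decay(r_ts, params),
      n_covalent = n_cov, n_hbond = 1L, n_ts = 1L, n_conductive = 2L,
      route_label = "Trp378"
    )
  } else if (type == "direct") {
    r_ts <- chk(bp$r_ts %||% 3.0, 2.0, params$ts_max_distance, "r_ts")
    parts <- list(heme3(1, 0, n_first = TRUE),
                  heme3(2, 2.8 + r_ts))
    frame <- .toy_assemble(parts)
    donor <- 1:3; acceptor <- 4:6
    csets <- list(donor, acceptor)
    expected <- list(atoms = 1:4, epsilon_tot = space_decay(r_ts, params),
                     n_covalent = 0L, n_hbond = 0L, n_ts = 1L,
                     n_conductive = 2L, route_label = "direct")
  } else if (type == "conductive") {
    parts <- list(.toy_atoms(c("NA", "C1A", "C2A", "C3A", "C4A", "NB"),
                             c("N", "C", "C", "C", "C", "N"),
                             "HEM", 1, 1.4 * (0:5)))
    frame <- .toy_assemble(parts)
    donor <- 1:3; acceptor <- 4:6
    csets <- list(1:6)
    expected <- list(atoms = 1:4, epsilon_tot = 1,
                     n_covalent = 0L, n_hbond = 0L, n_ts = 0L,
                     n_conductive = 3L, route_label = "direct")
  } else if (type == "two_route") {
    h_trp <- chk(bp$h_trp %||% 1.0, 0.2, 4.0, "h_trp")
    h_phe <- chk(bp$h_phe %||% 2.0, 0.2, 4.0, "h_phe")
    if (abs(h_trp - h_phe) < 0.05)
      stop("geometrically infeasible blueprint: routes must differ (h_trp != h_phe)")
    dx <- 7.0
    xm <- 2.8 + dx / 2
    parts <- list(
      heme3(1, 0, n_first = TRUE),                         # 1-3, edge C4A
      .toy_atoms("CD1", "C", "TRP", 378, xm, y = h_trp),   # 4
      .toy_atoms("CZ", "C", "PHE", 348, xm, y = -h_phe),   # 5
      heme3(2, 2.8 + dx)                                   # 6-8
    )
    frame <- .toy_assemble(parts)
    donor <- 1:3; acceptor <- 6:8
    csets <- list(donor, acceptor)
    r_trp <- sqrt((dx / 2)^2 + h_trp^2)
    r_phe <- sqrt((dx / 2)^2 + h_phe^2)
    if (max(r_trp, r_phe) > params$ts_max_distance)
      stop("geometrically infeasible blueprint: bridge offsets too large")
    via_trp <- space_decay(r_trp, params)^2
    via_phe <- space_decay(r_phe, params)^2
    best_trp <- via_trp >= via_phe
    expected <- list(
      atoms = c(1:3, if (best_trp) 4L else 5L, 6L),
      epsilon_tot = max(via_trp, via_phe),
      n_covalent = 0L, n_hbond = 0L, n_ts = 2L, n_conductive = 2L,
      route_label = if (best_trp) "Trp378" else "Phe348",
      route_decays = c(Trp378 = via_trp, Phe348 = via_phe)
    )
  } else if (type == "o2_short") {
    if (!is.null(bp$target_decay))
      bp$r_ts <- params$ts_offset +
        log(params$ts_prefactor / bp$target_decay) / params$beta_s
    r_ts <- chk(bp$r_ts %||% 3.42, 2.2, params$ts_max_distance, "r_ts")
    parts <- list(heme3(1, 0, n_first = TRUE),
                  .toy_atoms(c("O1", "O2"), "O", "OXY", 500,
                             2.8 + r_ts + c(0, 1.2)))
    frame <- .toy_assemble(parts)
    donor <- 1:3; acceptor <- 4:5
    csets <- list(donor)
    expected <- list(atoms = 1:4, epsilon_tot = space_decay(r_ts, params),
                     n_covalent = 0L, n_hbond = 0L, n_ts = 1L,
                     n_conductive = 2L, route_label = "direct")
  } else if (type == "o2_long") {
    if (!is.null(bp$target_decay)) {
      # split the target evenly over the two jumps around the His chain
      per_jump <- sqrt(bp$target_decay / params$epsilon_c^2)
      bp$r_ts1 <- bp$r_ts2 <- params$ts_offset +
        log(params$ts_prefactor / per_jump) / params$beta_s
    }
    r1 <- chk(bp$r_ts1 %||% 2.98, 2.2, params$ts_max_distance, "r_ts1")
    r2 <- chk(bp$r_ts2 %||% 2.98, 2.2, params$ts_max_distance, "r_ts2")
    x_cb <- 2.8 + r1
    parts <- list(
      heme3(1, 0, n_first = TRUE),                               # 1-3
      .toy_atoms(c("CB", "CG", "CD2"), "C", "HIS", 317,
                 x_cb + 1.4 * (0:2)),                            # 4-6
      .toy_atoms(c("O1", "O2"), "O", "OXY", 500,
                 x_cb + 2.8 + r2 + c(0, 1.2))                    # 7-8
    )
    frame <- .toy_assemble(parts)
    donor <- 1:3; acceptor <- 7:8
    csets <- list(donor)
    expected <- list(
      atoms = 1:7,
      epsilon_tot = space_decay(r1, params) * params$epsilon_c^2 *
        space_decay(r2, params),
      n_covalent = 2L, n_hbond = 0L, n_ts = 2L, n_conductive = 2L,
      route_label = "His317"
    )
  } else {
    stop("unknown blueprint type: ", type)
  }

  file <- NULL
  if (!is.null(path)) {
    write_structure(frame, path)
    file <- path
  }
  list(frame = frame, donor = donor, acceptor = acceptor,
       conductive_sets = csets, expected = expected, file = file,
       blueprint = blueprint)
}

#' Run the full pathway stage on a toy structure
#'
#' Convenience wrapper: bond perception, hydrogen bonds, graph and best
#' path for the output of [make_toy_structure()].
#'
#' @param toy result of [make_toy_structure()].
#' @param params a [pathway_params()] object.
#' @return the decomposed `et_pathway`.
#' @export
toy_best_pathway <- function(toy, params = pathway_params()) {
  bonds <- perceive_covalent_bonds(toy$frame)
  bonds <- detect_hydrogen_bonds(toy$frame, bonds)
  graph <- build_tunneling_graph(toy$frame, bonds,
                                 conductive_sets = toy$conductive_sets,
                                 params = params)
  decompose_pathway(best_pathway(graph, toy$donor, toy$acceptor), toy$frame)
}

## ---- brute-force oracle --------------------------------------------------

#' Brute-force best pathway by exhaustive enumeration
#'
#' Enumerates every simple path from any donor atom to any acceptor atom
#' and returns the maximal-product path, breaking ties by the same
#' lexicographic node-sequence rule as [best_pathway()]. Independent of the
#' Dijkstra search; intended as its oracle on small graphs.
#'
#' @param graph a `tunneling_graph`.
#' @param donor,acceptor atom-index vectors.
#' @param max_nodes refuse graphs larger than this (default 12).
#' @return an `et_pathway`.
#' @export
brute_force_best_path <- function(graph, donor, acceptor, max_nodes = 12) {
  if (length(graph$nodes) > max_nodes)
    stop("graph too large for brute-force enumeration")
  donor <- sort(unique(donor)); acceptor <- sort(unique(acceptor))
  if (length(donor) == 0L || length(acceptor) == 0L)
    stop("donor and acceptor sets must be non-empty")
  if (length(intersect(donor, acceptor)) > 0L)
    stop("donor and acceptor sets must be disjoint")
  if (!all(c(donor, acceptor) %in% graph$nodes))
    stop("donor/acceptor atoms absent from graph")
  adj <- .graph_adjacency(graph)
  best <- NULL
  consider <- function(path, edge_rows, logp) {
    if (is.null(best)) {
      best <<- list(path = path, edge_rows = edge_rows, logp = logp)
      return()
    }
    tol <- .path_log_tol * max(1, abs(best$logp))
    if (logp > best$logp + tol ||
        (abs(logp - best$logp) <= tol && .seq_less(path, best$path)))
      best <<- list(path = path, edge_rows = edge_rows, logp = logp)
  }
  dfs <- function(node, path, edge_rows, logp) {
    if (node %in% acceptor) consider(path, edge_rows, logp)
    nb <- adj[[as.character(node)]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]
      if (v %in% path) next
      dfs(v, c(path, v), c(edge_rows, nb[r, 3]), logp + log(nb[r, 2]))
    }
  }
  for (s in donor) dfs(s, s, integer(0), 0)
  if (is.null(best)) stop("no pathway connects donor to acceptor")
  e <- graph$edges
  types <- e$type[best$edge_rows]
  structure(list(
    atoms = best$path,
    edge_types = types,
    edge_decays = e$decay[best$edge_rows],
    epsilon_tot = prod(e$decay[best$edge_rows]),
    n_covalent = sum(types == "covalent"),
    n_hbond = sum(types == "hbond"),
    n_ts = sum(types == "through_space"),
    n_conductive = sum(types == "conductive")
  ), class = "et_pathway")
}
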