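# Linear-response estimators from vertical energy gaps.

test_that("mean-gap estimators reproduce their closed forms", {
  expect_equal(reaction_free_energy(0.8, -1.4), -0.3)
  expect_equal(reaction_free_energy(1.1, -1.1), 0)  # self-exchange symmetry
  expect_equal(stokes_reorganization(0.8, -1.4), 1.1)
  expect_equal(stokes_reorganization(0.5, 0.5), 0)
  expect_warning(stokes_reorganization(-1.4, 0.8), "linear response")
  # the two estimators invert the state means exactly
  dA <- -0.28; lam <- 1.04
  mi <- dA + lam; mf <- dA - lam
  expect_equal(reaction_free_energy(mi, mf), dA)
  expect_equal(stokes_reorganization(mi, mf), lam)
})

test_that("variance reorganization divides the gap variance by 2 kB T", {
  expect_equal(variance_reorganization(c(1, 1, 1, 1), 310), 0)
  # population variance 2 * 1.1 * kB * 310 corresponds to 1.1 eV at 310 K
  s <- sqrt(2 * 1.1 * kB * 310)
  expect_equal(variance_reorganization(c(-s, s), 310), 1.1,
               tolerance = 1e-12)
  expect_error(variance_reorganization(1.0, 310), "two samples")
  expect_error(variance_reorganization(c(1, 2), -5), "positive")
})

test_that("ergodicity factor compares fluctuation and Stokes estimates", {
  expect_equal(ergodicity_factor(1.2, 1.2, 1.2), 1)
  expect_equal(ergodicity_factor(1.5, 1.5, 1.0), 1.5)
  expect_error(ergodicity_factor(1, 1, 0), "positive")
})

test_that("gap series validate monotonic times and component sums", {
  expect_error(gap_series(c(0, 2, 2), c(1, 2, 3)), "strictly increasing")
  comps <- data.frame(a = c(0.3, 0.4), b = c(0.7, 0.6))
  gs <- gap_series(c(0, 2), c(1.0, 1.0), components = comps)
  expect_identical(gap_components(gs), c("a", "b"))
  expect_error(gap_series(c(0, 2), c(1.0, 2.0), components = comps),
               "do not sum")
})

test_that("gap files load with unit conversion", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(time = c(0, 2, 4), gap = c(23.0605, 0, -23.0605)),
            f, row.names = FALSE)
  gs <- load_gap_series(f, units = "kcal/mol")
  expect_equal(gs$gap, c(1, 0, -1), tolerance = 1e-12)
  g2 <- load_gap_series(f, units = "eV")
  expect_equal(nrow(g2), 3L)
  expect_equal(g2$gap[1], 23.0605)
  # component columns ride along (and are converted too)
  f2 <- tempfile(fileext = ".tsv")
  df <- data.frame(time = c(0, 2), gap = c(1, 2), tm = c(0.4, 1.1),
                   env = c(0.6, 0.9))
  write.table(df, f2, sep = "\t", row.names = FALSE)
  gs2 <- load_gap_series(f2)
  expect_identical(gap_components(gs2), c("tm", "env"))
  expect_error(suppressWarnings(load_gap_series(tempfile(fileext = ".csv"))),
               "cannot open|not found|No such")
})

test_that("lra_fit recovers generator parameters within sampling error", {
  n <- 1e5
  gg <- generate_lra_gaps(delta_A = -0.28, lambda = 1.04, temperature = 310,
                          n = n, seed = 11)
  fit <- lra_fit(gg$initial, gg$final)
  v <- 2 * 1.04 * kB * 310
  se_mean <- sqrt(v / n)
  expect_equal(fit$delta_A0, -0.28, tolerance = 3 * se_mean / sqrt(2) / 0.28)
  expect_equal(fit$lambda_st, 1.04, tolerance = 3 * se_mean / sqrt(2) / 1.04)
  se_var <- 1.04 * sqrt(2 / n)
  expect_equal(fit$lambda_var_initial, 1.04, tolerance = 3 * se_var / 1.04)
  expect_equal(fit$lambda_var_final, 1.04, tolerance = 3 * se_var / 1.04)
  expect_equal(fit$chi_G, 1, tolerance = 0.03)
  expect_named(coef(fit), c("delta_A0", "lambda_st", "lambda_var_initial",
                            "lambda_var_final", "chi_G"))
  # simulate() round-trips through the generator
  sim <- simulate(fit, nsim = 100, seed = 1)
  expect_s3_class(sim$initial, "gap_series")
})

test_that("LRA identity: mean gaps reconstruct delta_A +/- lambda", {
  gg <- generate_lra_gaps(delta_A = -0.3, lambda = 1.1, n = 5000, seed = 4)
  fit <- lra_fit(gg$initial, gg$final)
  expect_equal(fit$mean_gap_initial, fit$delta_A0 + fit$lambda_st,
               tolerance = 1e-12)
  expect_equal(fit$mean_gap_final, fit$delta_A0 - fit$lambda_st,
               tolerance = 1e-12)
})

test_that("block analysis averages segments and doubles the SEM", {
  mk_seg <- function(dA, lam) list(
    initial = gap_series(c(0, 10, 20), rep(dA + lam, 3), "initial"),
    final = gap_series(c(0, 10, 20), rep(dA - lam, 3), "final"))
  # five identical segments: zero uncertainty
  bp <- block_analysis(rep(list(mk_seg(-0.3, 1.1)), 5),
                       equilibration_discard = 0)
  expect_equal(unname(bp$estimate["delta_A0"]), -0.3)
  expect_equal(unname(bp$uncertainty["delta_A0"]), 0)
  # two segments at -0.2 and -0.4: mean -0.3, 2 x SEM = 0.2
  b2 <- block_analysis(list(mk_seg(-0.2, 1.0), mk_seg(-0.4, 1.0)),
                       equilibration_discard = 0)
  expect_equal(unname(b2$estimate["delta_A0"]), -0.3)
  expect_equal(unname(b2$uncertainty["delta_A0"]), 0.2, tolerance = 1e-12)
  # equilibration window is honoured
  seg <- list(initial = gap_series(seq(0, 100, 10), rep(0.8, 11), "initial"),
              final = gap_series(seq(0, 100, 10), rep(-1.4, 11), "final"))
  expect_error(block_analysis(list(seg, seg), equilibration_discard = 1000),
               "shorter than")
  # generator segments: block mean close to truth
  segs <- lapply(1:5, function(k) {
    gg <- generate_lra_gaps(-0.3, 1.1, n = 4000, dt = 2, seed = 100 + k)
    list(initial = gg$initial, final = gg$final)
  })
  bg <- block_analysis(segs, equilibration_discard = 400)
  expect_equal(unname(bg$estimate["delta_A0"]), -0.3,
               tolerance = 3 * max(bg$uncertainty["delta_A0"], 0.01) / 0.3)
  expect_equal(unname(bg$estimate["lambda_st"]), 1.1, tolerance = 0.05)
})

test_that("component decomposition is additive and recovers generator splits", {
  gi <- gap_series(c(0, 2), c(0.7, 1.5), "initial",
                   components = data.frame(x = c(0.3, 0.5),
                                           rest = c(0.4, 1.0)))
  gf <- gap_series(c(0, 2), c(-1.1, -0.9), "final",
                   components = data.frame(x = c(-0.6, -0.4),
                                           rest = c(-0.5, -0.5)))
  dec <- decompose_gap(gi, gf)
  tot <- dec[dec$component == "total", ]
  expect_equal(sum(dec$delta_A0[dec$component != "total"]), tot$delta_A0,
               tolerance = 1e-12)
  expect_equal(sum(dec$lambda_st[dec$component != "total"]), tot$lambda_st,
               tolerance = 1e-12)

  # generator split with the domain/membrane/water/ion contributions used
  # as ground truth; estimator recovers signs and magnitudes
  split <- data.frame(
    name = c("tm", "membrane", "water", "ions", "rest"),
    delta_A = c(-0.10, 0.05, -0.10, -0.20, 0.07),
    lambda = c(1.52, 0.60, -0.27, -1.42, 0.61)
  )
  gg <- generate_lra_gaps(delta_A = -0.28, lambda = 1.04, n = 2e4,
                          seed = 21, components = split)
  dd <- decompose_gap(gg$initial, gg$final)
  for (k in seq_len(nrow(split))) {
    row <- dd[dd$component == split$name[k], ]
    expect_equal(row$lambda_st, split$lambda[k], tolerance = 0.05)
    expect_equal(row$delta_A0, split$delta_A[k], tolerance = 0.05)
  }
  # mismatched component sets are refused
  gf2 <- gap_series(c(0, 2), c(-1.1, -0.9), "final",
                    components = data.frame(x = c(-1.1, -0.9)))
  expect_error(decompose_gap(gi, gf2), "differ")
})

test_that("inner-sphere reorganization follows the four-point formula", {
  expect_equal(inner_sphere_lambda(list(E_gR_O = 0.05, E_gR_R = 0,
                                        E_gO_R = 0.05, E_gO_O = 0)), 0.10)
  expect_equal(inner_sphere_lambda(list(E_gR_O = 1, E_gR_R = 1,
                                        E_gO_R = 1, E_gO_O = 1)), 0)
  # two displaced parabolas with equal curvature: lambda_is = k d^2
  k <- 2.3; d <- 0.31
  e <- list(E_gR_R = 0, E_gR_O = k * d^2 / 2,
            E_gO_O = 0, E_gO_R = k * d^2 / 2)
  expect_equal(inner_sphere_lambda(e), k * d^2, tolerance = 1e-12)
  expect_error(inner_sphere_lambda(list(E_gR_O = -1, E_gR_R = 0,
                                        E_gO_R = 1, E_gO_O = 0)),
               "equilibrium")
})

test_that("total reorganization adds inner- and outer-sphere parts", {
  expect_equal(total_reorganization(0.10, 1.04), 1.14)
  expect_equal(total_reorganization(0, 0.7), 0.7)
  expect_equal(total_reorganization(0.2, 0.5), total_reorganization(0.5, 0.2))
  expect_error(total_reorganization(-0.1, 1), "non-negative")
})

test_that("running averages smooth interiors and truncate ends", {
  expect_equal(running_average(rep(2, 10), 5), rep(2, 6))
  expect_equal(running_average(1:10, 1), as.numeric(1:10))
  expect_equal(running_average(as.numeric(1:10), 3), as.numeric(2:9))
  gs <- gap_series(2 * (0:9), as.numeric(1:10))
  sm <- running_average(gs, 3)
  expect_equal(sm$gap, as.numeric(2:9))
  expect_equal(nrow(sm), 8L)
  expect_error(running_average(1:3, 5), "window")
})
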