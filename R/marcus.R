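## Linear-response (Marcus) estimation of electron-transfer parameters
## from vertical energy-gap time series.
##
## Sign convention, fixed package-wide: the gap is DE = E_final - E_initial
## evaluated at a single nuclear configuration. Under the linear response
## approximation the gap is Gaussian in both diabatic states with equal
## curvature, and
##   DA0        = (<DE>_i + <DE>_f) / 2          reaction free energy
##   lambda_St  = (<DE>_i - <DE>_f) / 2          Stokes reorganization energy
##   lambda_var = var(DE_x) / (2 kB T)           variance reorganization energy
##   chi_G      = (lambda_var_i + lambda_var_f) / (2 lambda_St)
## chi_G close to 1 signals an ergodic, LRA-consistent system.
## Energies in eV, temperatures in K, times in ps. Variances are population
## variances (divisor n) for bit-reproducibility.

.pop_var <- function(x) mean((x - mean(x))^2)

#' Construct a vertical energy-gap series
#'
#' @param times sampling times in ps, strictly increasing.
#' @param gaps vertical energy gaps `E_f - E_i` in eV.
#' @param state redox-state label, `"initial"` or `"final"`.
#' @param temperature simulation temperature in K (default 310).
#' @param components optional data.frame of per-component gap columns (eV),
#'   e.g. contributions of the transmembrane domain, dehydrogenase domain,
#'   environment and cofactors. Rows must sum to `gaps` within
#'   `component_tol` unless a column named `residual` absorbs the rest.
#' @param component_tol tolerance in eV for the component-sum check.
#' @return an object of class `gap_series` (a data.frame with a `time`
#'   column, a `gap` column and any component columns; state and
#'   temperature stored as attributes).
#' @export
gap_series <- function(times, gaps, state = c("initial", "final"),
                       temperature = 310, components = NULL,
                       component_tol = 1e-6) {
  state <- match.arg(state)
  if (length(times) != length(gaps)) stop("times and gaps differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  df <- data.frame(time = times, gap = gaps)
  if (!is.null(components)) {
    if (nrow(components) != length(gaps))
      stop("components and gaps differ in length")
    if (!"residual" %in% names(components)) {
      err <- max(abs(rowSums(components) - gaps))
      if (err > component_tol)
        stop(sprintf(
          "component columns do not sum to the total gap (max error %.2g eV); add a 'residual' column",
          err))
    }
    df <- cbind(df, components)
  }
  structure(df, state = state, temperature = temperature,
            class = c("gap_series", "data.frame"))
}

#' Component columns of a gap series
#' @param series a `gap_series`.
#' @return character vector of component column names (possibly empty).
#' @export
gap_components <- function(series) {
  setdiff(names(series), c("time", "gap"))
}

#' Load a gap series from a CSV/TSV file
#'
#' The file must have `time` and `gap` columns; any further numeric columns
#' are taken as component decompositions. Values in kcal/mol are converted
#' to eV (1 eV = 23.0605 kcal/mol).
#'
#' @param path file path; the field separator is a tab for `.tsv` files and
#'   a comma otherwise.
#' @param units `"eV"` or `"kcal/mol"`.
#' @param state,temperature passed to [gap_series()].
#' @param ... further arguments to [gap_series()].
#' @return a `gap_series`.
#' @export
load_gap_series <- function(path, units = c("eV", "kcal/mol"),
                            state = c("initial", "final"),
                            temperature = 310, ...) {
  units <- match.arg(units)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("time", "gap") %in% names(df)))
    stop("file must have 'time' and 'gap' columns: ", path)
  conv <- if (units == "kcal/mol") 1 / et_constants[["ev_per_kcal_mol"]] else 1
  comp_names <- setdiff(names(df), c("time", "gap"))
  comps <- if (length(comp_names) > 0L)
    df[comp_names] * conv else NULL
  gap_series(df$time, df$gap * conv, state = state,
             temperature = temperature, components = comps, ...)
}

#' Reaction free energy from state-averaged gaps
#'
#' `(mean_gap_initial + mean_gap_final) / 2`, in eV. Negative values mean
#' thermodynamically favorable electron transfer.
#'
#' @param mean_gap_initial,mean_gap_final ensemble-averaged gaps in eV.
#' @export
reaction_free_energy <- function(mean_gap_initial, mean_gap_final) {
  (mean_gap_initial + mean_gap_final) / 2
}

#' Stokes reorganization energy from state-averaged gaps
#'
#' `(mean_gap_initial - mean_gap_final) / 2`, in eV. A negative value
#' violates the linear-response picture and triggers a warning.
#'
#' @inheritParams reaction_free_energy
#' @export
stokes_reorganization <- function(mean_gap_initial, mean_gap_final) {
  lam <- (mean_gap_initial - mean_gap_final) / 2
  if (any(lam < 0))
    warning("negative Stokes reorganization energy: linear response violated?")
  lam
}

#' Variance reorganization energy of one state
#'
#' `var(gap) / (2 kB T)` with the population variance and
#' `kB = 8.617333e-5 eV/K`.
#'
#' @param series a `gap_series` or numeric vector of gaps in eV.
#' @param temperature temperature in K; defaults to the series attribute
#'   (310 K for plain vectors).
#' @export
variance_reorganization <- function(series, temperature = NULL) {
  gaps <- if (is.data.frame(series)) series$gap else series
  if (length(gaps) < 2L) stop("need at least two samples")
  if (is.null(temperature))
    temperature <- if (!is.null(attr(series, "temperature")))
      attr(series, "temperature") else 310
  if (temperature <= 0) stop("temperature must be positive")
  .pop_var(gaps) / (2 * et_constants[["kB"]] * temperature)
}

#' Ergodicity factor
#'
#' `(lambda_var_i + lambda_var_f) / (2 lambda_St)`; values close to 1
#' correspond to ergodic, LRA-consistent sampling, values above 1 indicate
#' slow degrees of freedom (e.g. bimodal gap distributions).
#'
#' @param lambda_var_i,lambda_var_f variance reorganization energies (eV).
#' @param lambda_st Stokes reorganization energy (eV), must be positive.
#' @export
ergodicity_factor <- function(lambda_var_i, lambda_var_f, lambda_st) {
  if (any(lambda_st <= 0)) stop("lambda_st must be positive")
  (lambda_var_i + lambda_var_f) / (2 * lambda_st)
}

#' Fit linear-response ET parameters to a pair of gap series
#'
#' The central estimator: from gap series sampled in the initial and final
#' redox states it computes the reaction free energy, the Stokes and
#' per-state variance reorganization energies and the ergodicity factor.
#'
#' @param initial,final `gap_series` objects (or numeric gap vectors in eV)
#'   sampled in the two redox states.
#' @param temperature temperature in K; defaults to the series attribute.
#' @return an object of class `lra_fit` with components `delta_A0`,
#'   `lambda_st`, `lambda_var_initial`, `lambda_var_final`, `chi_G`,
#'   `mean_gap_initial`, `mean_gap_final`, `temperature`, `n_initial`,
#'   `n_final`. Methods: `print`, `summary`, `coef`, `simulate`, `plot`.
#' @export
lra_fit <- function(initial, final, temperature = NULL) {
  gi <- if (is.data.frame(initial)) initial$gap else initial
  gf <- if (is.data.frame(final)) final$gap else final
  if (is.null(temperature))
    temperature <- if (!is.null(attr(initial, "temperature")))
      attr(initial, "temperature") else 310
  mi <- mean(gi); mf <- mean(gf)
  li <- variance_reorganization(gi, temperature)
  lf <- variance_reorganization(gf, temperature)
  lst <- stokes_reorganization(mi, mf)
  structure(list(
    delta_A0 = reaction_free_energy(mi, mf),
    lambda_st = lst,
    lambda_var_initial = li,
    lambda_var_final = lf,
    chi_G = if (lst > 0) ergodicity_factor(li, lf, lst) else NA_real_,
    mean_gap_initial = mi, mean_gap_final = mf,
    temperature = temperature,
    n_initial = length(gi), n_final = length(gf)
  ), class = "lra_fit")
}

#' @export
coef.lra_fit <- function(object, ...) {
  c(delta_A0 = object$delta_A0, lambda_st = object$lambda_st,
    lambda_var_initial = object$lambda_var_initial,
    lambda_var_final = object$lambda_var_final, chi_G = object$chi_G)
}

#' @export
print.lra_fit <- function(x, digits = 4, ...) {
  cat("Linear-response ET parameter fit (T =", x$temperature, "K)\n")
  cat(sprintf("  <DE>_i = %.*g eV (n = %d), <DE>_f = %.*g eV (n = %d)\n",
              digits, x$mean_gap_initial, x$n_initial,
              digits, x$mean_gap_final, x$n_final))
  cat(sprintf("  DA0 = %.*g eV, lambda_St = %.*g eV\n",
              digits, x$delta_A0, digits, x$lambda_st))
  cat(sprintf("  lambda_var(i) = %.*g eV, lambda_var(f) = %.*g eV, chi_G = %.*g\n",
              digits, x$lambda_var_initial, digits, x$lambda_var_final,
              digits, x$chi_G))
  invisible(x)
}

#' @export
summary.lra_fit <- function(object, ...) {
  print(object, ...)
  cat(if (!is.na(object$chi_G) && abs(object$chi_G - 1) < 0.1)
        "  chi_G close to 1: sampling consistent with linear response\n"
      else
        "  chi_G far from 1: non-ergodic sampling or LRA breakdown\n")
  invisible(object)
}

#' @export
simulate.lra_fit <- function(object, nsim = NULL, seed = NULL, ...) {
  n <- if (is.null(nsim)) max(object$n_initial, object$n_final) else nsim
  generate_lra_gaps(delta_A = object$delta_A0, lambda = object$lambda_st,
                    temperature = object$temperature, n = n, seed = seed,
                    ...)
}

#' @export
plot.lra_fit <- function(x, ...) {
  mu <- c(x$mean_gap_initial, x$mean_gap_final)
  kT <- et_constants[["kB"]] * x$temperature
  s <- sqrt(2 * c(x$lambda_var_initial, x$lambda_var_final) * kT)
  xs <- seq(min(mu - 4 * s), max(mu + 4 * s), length.out = 400)
  graphics::plot(xs, stats::dnorm(xs, mu[1], s[1]), type = "l", col = 2,
                 xlab = expression(Delta * E ~ "(eV)"), ylab = "density",
                 main = "LRA gap distributions", ...)
  graphics::lines(xs, stats::dnorm(xs, mu[2], s[2]), col = 3)
  graphics::legend("topright", c("initial", "final"), col = c(2, 3), lty = 1)
  invisible(x)
}

#' Block analysis of ET parameters over trajectory segments
#'
#' Computes the LRA parameters on each segment after discarding an
#' equilibration window, then reports the mean over segments with an
#' uncertainty of twice the standard error of the mean (the convention used
#' for the error bars of this analysis).
#'
#' @param segments list of segments, each a list with elements `initial`
#'   and `final` (both `gap_series`).
#' @param equilibration_discard length of the initial window dropped from
#'   every series, in ps (default 20000 ps = 20 ns).
#' @param temperature temperature in K (default: attribute of the first
#'   series).
#' @return an object of class `et_params`: list with `estimate` (named
#'   vector: `delta_A0`, `lambda_st`, `lambda_var_initial`,
#'   `lambda_var_final`, `chi_G`), `uncertainty` (2 x SEM over segments),
#'   `per_segment` (matrix), `n_segments`.
#' @export
block_analysis <- function(segments, equilibration_discard = 20000,
                           temperature = NULL) {
  if (length(segments) < 2L) stop("need at least two segments")
  discard <- function(s) {
    keep <- s$time > s$time[1] + equilibration_discard
    if (!any(keep))
      stop("segment shorter than the equilibration discard window")
    s[keep, , drop = FALSE]
  }
  fits <- lapply(segments, function(seg) {
    lra_fit(discard(seg$initial), discard(seg$final),
            temperature = temperature)
  })
  per <- t(vapply(fits, coef, numeric(5)))
  est <- colMeans(per)
  sem <- apply(per, 2, stats::sd) / sqrt(nrow(per))
  structure(list(estimate = est, uncertainty = 2 * sem, per_segment = per,
                 n_segments = length(segments)),
            class = "et_params")
}

#' @export
print.et_params <- function(x, digits = 3, ...) {
  cat("Block-averaged ET parameters (", x$n_segments, "segments )\n")
  for (k in seq_along(x$estimate)) {
    cat(sprintf("  %-20s %8.*g +/- %.*g\n", names(x$estimate)[k],
                digits, x$estimate[k], digits, x$uncertainty[k]))
  }
  cat("  (uncertainty = 2 x standard error over segments)\n")
  invisible(x)
}

#' @export
coef.et_params <- function(object, ...) object$estimate

#' Decompose the reaction free energy and Stokes reorganization energy
#' over molecular components
#'
#' Applies the two mean-gap estimators to every component column of the
#' series (e.g. transmembrane domain, dehydrogenase domain, membrane,
#' water, counter-ions, cofactors); by linearity the component
#' contributions sum to the totals.
#'
#' @param initial,final `gap_series` objects carrying the same component
#'   columns.
#' @return data.frame with one row per component plus a `total` row,
#'   columns `component`, `delta_A0`, `lambda_st` (eV).
#' @export
decompose_gap <- function(initial, final) {
  ci <- gap_components(initial); cf <- gap_components(final)
  if (length(ci) == 0L) stop("no component columns present")
  if (!setequal(ci, cf))
    stop("component sets differ between states: ",
         paste(symdiff <- union(setdiff(ci, cf), setdiff(cf, ci)),
               collapse = ", "))
  rows <- lapply(ci, function(cc) {
    mi <- mean(initial[[cc]]); mf <- mean(final[[cc]])
    data.frame(component = cc,
               delta_A0 = reaction_free_energy(mi, mf),
               lambda_st = (mi - mf) / 2)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(
    component = "total",
    delta_A0 = reaction_free_energy(mean(initial$gap), mean(final$gap)),
    lambda_st = (mean(initial$gap) - mean(final$gap)) / 2))
  out
}

#' Inner-sphere reorganization energy from four-point energies
#'
#' From the energies of the cofactor in each redox state X (O = oxidized,
#' R = reduced) at each state's equilibrium geometry gY:
#' `lambda_is = (E_gR_O - E_gR_R) + (E_gO_R - E_gO_O)`, i.e. twice the
#' average of the two relaxation energies. For two equal-curvature
#' parabolas with force constant k displaced by d this equals `k d^2`.
#'
#' @param e named list or vector with elements `E_gR_O`, `E_gR_R`,
#'   `E_gO_R`, `E_gO_O` in eV (`E_gY_X` = energy of redox state X at the
#'   equilibrium geometry of state Y).
#' @return inner-sphere reorganization energy in eV.
#' @export
inner_sphere_lambda <- function(e) {
  e <- as.list(e)
  need <- c("E_gR_O", "E_gR_R", "E_gO_R", "E_gO_O")
  if (!all(need %in% names(e))) stop("need elements ", paste(need, collapse = ", "))
  if (e$E_gR_O < e$E_gO_O || e$E_gO_R < e$E_gR_R)
    stop("each redox state must be lowest at its own equilibrium geometry")
  (e$E_gR_O - e$E_gR_R) + (e$E_gO_R - e$E_gO_O)
}

#' Total reorganization energy
#'
#' Sum of the inner-sphere (cofactor) and outer-sphere (environment)
#' contributions.
#'
#' @param lambda_is,lambda_os non-negative energies in eV.
#' @export
total_reorganization <- function(lambda_is, lambda_os) {
  if (any(c(lambda_is, lambda_os) < 0)) stop("inputs must be non-negative")
  lambda_is + lambda_os
}

#' Centered running average of a gap series
#'
#' Ends are truncated (no padding). With an even window the center falls
#' half a sample late, as in [stats::filter()].
#'
#' @param series a `gap_series` or numeric vector.
#' @param window window length in samples.
#' @return the smoothed series (same class as the input, shorter).
#' @export
running_average <- function(series, window) {
  x <- if (is.data.frame(series)) series$gap else series
  if (window < 1L || window > length(x))
    stop("window must lie in [1, length(series)]")
  sm <- stats::filter(x, rep(1 / window, window), sides = 2)
  keep <- !is.na(sm)
  if (is.data.frame(series)) {
    out <- series[keep, , drop = FALSE]
    out$gap <- as.numeric(sm[keep])
    out
  } else {
    as.numeric(sm[keep])
  }
}
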