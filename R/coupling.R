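## Ensemble statistics of tunneling decay factors.
##
## The coherence ratio R_coh = <eps>^2 / <eps^2> distinguishes coupling
## governed by its average (R_coh near 1) from coupling governed by its
## fluctuations (R_coh near 0.5). It is computed from the (mean, variance)
## pair through the identity <eps^2> = <eps>^2 + sigma^2, which is exact as
## computed here (population moments, divisor n).

#' Coherence ratio from coupling-decay moments
#'
#' `mean^2 / (mean^2 + variance)`; lies in (0, 1].
#'
#' @param mean_epsilon ensemble mean of the decay factor.
#' @param variance population variance of the decay factor (>= 0).
#' @export
coherence_ratio <- function(mean_epsilon, variance) {
  if (any(variance < 0)) stop("variance must be non-negative")
  mean_epsilon^2 / (mean_epsilon^2 + variance)
}

#' Contact coupling from a frequency
#'
#' `h * frequency` with `h = 4.135667696e-15 eV s`; the conventional
#' contact value 4.3e13 Hz gives 0.177829 eV.
#'
#' @param frequency frequency in Hz, positive.
#' @return coupling in eV.
#' @export
contact_coupling_from_frequency <- function(frequency) {
  if (any(frequency <= 0)) stop("frequency must be positive")
  et_constants[["h"]] * frequency
}

#' Absolute coupling from a decay factor
#'
#' `H_if = H_if_contact * eps_tot`.
#'
#' @param epsilon_tot decay factor(s) in (0, 1].
#' @param contact_coupling contact coupling in eV (default 0.177829).
#' @return coupling in eV.
#' @export
coupling_from_decay <- function(epsilon_tot, contact_coupling = 0.177829) {
  if (any(epsilon_tot <= 0 | epsilon_tot > 1))
    stop("epsilon_tot must lie in (0, 1]")
  epsilon_tot * contact_coupling
}

#' Ensemble statistics of pathway decay factors
#'
#' Population moments of the decay factors, the coherence ratio, the mean
#' absolute coupling, and a per-route breakdown (occupancy in percent,
#' per-route mean and variance).
#'
#' @param decays numeric vector of per-frame decay factors in (0, 1], or an
#'   `et_pathway_ensemble` (routes then taken from its labels).
#' @param routes optional character vector of route labels, same length.
#' @param contact_coupling contact coupling in eV.
#' @return an object of class `coupling_stats`: list with `mean_epsilon`,
#'   `variance`, `mean_square`, `r_coh`, `mean_hif`, `n_frames`, `routes`
#'   (data.frame `route`, `occupancy_pct`, `mean_epsilon`, `variance`).
#' @export
ensemble_stats <- function(decays, routes = NULL,
                           contact_coupling = 0.177829) {
  if (inherits(decays, "et_pathway_ensemble")) {
    tab <- ensemble_table(decays)
    routes <- tab$route_label
    decays <- tab$epsilon_tot
  }
  if (length(decays) == 0L) stop("no decay factors supplied")
  if (any(decays <= 0 | decays > 1)) stop("decays must lie in (0, 1]")
  m <- mean(decays)
  v <- .pop_var(decays)
  route_df <- NULL
  if (!is.null(routes)) {
    stopifnot(length(routes) == length(decays))
    sp <- split(decays, routes)
    route_df <- data.frame(
      route = names(sp),
      occupancy_pct = 100 * vapply(sp, length, integer(1)) / length(decays),
      mean_epsilon = vapply(sp, mean, numeric(1)),
      variance = vapply(sp, .pop_var, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE
    )
    route_df <- route_df[order(-route_df$occupancy_pct), , drop = FALSE]
  }
  structure(list(
    mean_epsilon = m, variance = v, mean_square = m^2 + v,
    r_coh = coherence_ratio(m, v),
    mean_hif = coupling_from_decay(m, contact_coupling),
    n_frames = length(decays), routes = route_df
  ), class = "coupling_stats")
}

#' @export
print.coupling_stats <- function(x, ...) {
  cat("coupling statistics over", x$n_frames, "frames\n")
  cat(sprintf("  <eps> = %.3g, sigma^2 = %.3g, <eps^2> = %.3g\n",
              x$mean_epsilon, x$variance, x$mean_square))
  cat(sprintf("  R_coh = %.2f, <H_if> = %.3g eV\n", x$r_coh, x$mean_hif))
  if (!is.null(x$routes)) {
    cat("  routes:\n")
    for (k in seq_len(nrow(x$routes)))
      cat(sprintf("    %-12s %5.1f%%  <eps> = %.3g  sigma^2 = %.3g\n",
                  x$routes$route[k], x$routes$occupancy_pct[k],
                  x$routes$mean_epsilon[k], x$routes$variance[k]))
  }
  invisible(x)
}

#' Normalized histogram of decay factors, optionally per route
#'
#' @param decays numeric decay factors, or an `et_pathway_ensemble`.
#' @param routes optional route labels.
#' @param bins number of bins.
#' @param log_scale histogram `log10(eps)` instead of `eps`.
#' @return data.frame with columns `route`, `mid` (bin midpoint), `prob`
#'   (bin probability; sums to 1 within each route).
#' @export
decay_histogram <- function(decays, routes = NULL, bins = 30,
                            log_scale = FALSE) {
  if (inherits(decays, "et_pathway_ensemble")) {
    tab <- ensemble_table(decays)
    routes <- tab$route_label
    decays <- tab$epsilon_tot
  }
  if (length(decays) == 0L) stop("no decay factors supplied")
  x <- if (log_scale) log10(decays) else decays
  breaks <- seq(min(x), max(x), length.out = bins + 1L)
  if (breaks[1] == breaks[bins + 1L])
    breaks <- breaks[1] + seq(-0.5, 0.5, length.out = bins + 1L)
  if (is.null(routes)) routes <- rep("all", length(x))
  sp <- split(x, routes)
  out <- lapply(names(sp), function(r) {
    h <- graphics::hist(sp[[r]], breaks = breaks, plot = FALSE)
    data.frame(route = r, mid = h$mids, prob = h$counts / length(sp[[r]]))
  })
  do.call(rbind, out)
}
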