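## Semi-empirical per-step decay factors of the tunneling pathway model.
##
## The electronic coupling between donor and acceptor is attenuated
## multiplicatively along a chain of steps:
##   covalent bond        eps_c  = 0.6
##   hydrogen bond        eps_hb = 0.36 * exp(-beta_S * (R_H - 2.8))
##   through-space jump   eps_ts = 0.6  * exp(-beta_S * (R_S - 1.4))
## with R_H the inter-heavy-atom hydrogen-bond length and R_S the atom-atom
## jump distance, both in Angstrom. beta_S defaults to 1.1 1/A (the value
## recalibrated against quantum chemistry; the original 1990s calibration
## used 1.7 1/A and remains available through the parameter object).

#' Parameters of the tunneling pathway model
#'
#' @param epsilon_c per-covalent-bond decay (dimensionless).
#' @param hb_prefactor,hb_offset hydrogen-bond prefactor and distance
#'   offset (Angstrom).
#' @param ts_prefactor,ts_offset through-space prefactor and offset
#'   (Angstrom).
#' @param beta_s exponential distance-decay constant in 1/Angstrom.
#' @param ts_max_distance graph-construction cutoff for through-space
#'   edges (Angstrom); longer jumps are exponentially negligible.
#' @param contact_coupling contact coupling H_if at zero attenuation, in eV.
#' @return an object of class `pathway_params`.
#' @export
pathway_params <- function(epsilon_c = 0.6, hb_prefactor = 0.36,
                           hb_offset = 2.8, ts_prefactor = 0.6,
                           ts_offset = 1.4, beta_s = 1.1,
                           ts_max_distance = 6.0,
                           contact_coupling = 0.177829) {
  p <- list(epsilon_c = epsilon_c, hb_prefactor = hb_prefactor,
            hb_offset = hb_offset, ts_prefactor = ts_prefactor,
            ts_offset = ts_offset, beta_s = beta_s,
            ts_max_distance = ts_max_distance,
            contact_coupling = contact_coupling)
  if (any(unlist(p) <= 0)) stop("all pathway parameters must be positive")
  if (ts_max_distance <= ts_offset)
    stop("ts_max_distance must exceed ts_offset")
  structure(p, class = "pathway_params")
}

#' @export
print.pathway_params <- function(x, ...) {
  cat("pathway model parameters:\n")
  cat(sprintf("  eps_c = %g, eps_hb = %g*exp[-%g(R_H - %g)], eps_ts = %g*exp[-%g(R_S - %g)]\n",
              x$epsilon_c, x$hb_prefactor, x$beta_s, x$hb_offset,
              x$ts_prefactor, x$beta_s, x$ts_offset))
  cat(sprintf("  through-space cutoff %g A, contact coupling %g eV\n",
              x$ts_max_distance, x$contact_coupling))
  invisible(x)
}

#' Per-covalent-bond decay factor
#' @param params a [pathway_params()] object.
#' @return `epsilon_c` (default 0.6).
#' @export
covalent_decay <- function(params = pathway_params()) params$epsilon_c

#' Hydrogen-bond decay factor
#'
#' `hb_prefactor * exp(-beta_s * (r_h - hb_offset))`, capped at `epsilon_c`
#' so that no single step ever beats a covalent bond.
#'
#' @param r_h hydrogen-bond length (heavy-atom distance) in Angstrom; may
#'   be a vector.
#' @param params a [pathway_params()] object.
#' @export
hbond_decay <- function(r_h, params = pathway_params()) {
  if (any(r_h <= 0)) stop("r_h must be positive")
  pmin(params$hb_prefactor * exp(-params$beta_s * (r_h - params$hb_offset)),
       params$epsilon_c)
}

#' Through-space decay factor
#'
#' `ts_prefactor * exp(-beta_s * (r_s - ts_offset))`, capped at `epsilon_c`.
#'
#' @param r_s jump distance in Angstrom; may be a vector.
#' @param params a [pathway_params()] object.
#' @export
space_decay <- function(r_s, params = pathway_params()) {
  if (any(r_s <= 0)) stop("r_s must be positive")
  pmin(params$ts_prefactor * exp(-params$beta_s * (r_s - params$ts_offset)),
       params$epsilon_c)
}
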