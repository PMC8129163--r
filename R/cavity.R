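## Dioxygen-cavity analysis near the terminal heme.
##
## The O2 position relative to the binding cavity is tracked as the
## distance between the O2 center and the center of the cavity-lining
## group (by default the geometric center; mass weighting optional). The
## distance distribution is bimodal -- an inserted site around 2.5 A and an
## edge site around 4.3 A -- and the two-site occupancy, dwell times and
## transition counts are obtained by thresholding at a boundary between
## the two modes (default 3.4 A, their midpoint).

.atomic_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    S = 32.06, P = 30.974, FE = 55.845)

.group_center <- function(frame, idx, mass_weighted = FALSE) {
  sub <- frame[frame$atom_index %in% idx, , drop = FALSE]
  if (nrow(sub) == 0L) stop("empty selection in frame")
  co <- as.matrix(sub[, c("x", "y", "z")])
  if (mass_weighted) {
    m <- .atomic_masses[sub$element]
    if (any(is.na(m))) stop("no mass for element(s): ",
                            paste(unique(sub$element[is.na(m)]), collapse = ", "))
    colSums(co * m) / sum(m)
  } else {
    colMeans(co)
  }
}

#' Construct a distance series
#'
#' @param times sampling times in ps, strictly increasing.
#' @param dist distances in Angstrom, non-negative.
#' @param state redox-state label (`"initial"` or `"final"`).
#' @return an object of class `distance_series` (data.frame `time`,
#'   `dist`).
#' @export
distance_series <- function(times, dist, state = c("initial", "final")) {
  state <- match.arg(state)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(dist < 0)) stop("distances must be non-negative")
  structure(data.frame(time = times, dist = dist), state = state,
            class = c("distance_series", "data.frame"))
}

#' Center-to-center distance series between two atom groups
#'
#' @param frames an `et_frames` list.
#' @param group_a,group_b integer atom-index vectors (e.g. the O2 atoms and
#'   the cavity-lining atoms), or functions of a frame returning them.
#' @param times sampling times in ps (default: frame index).
#' @param mass_weighted use mass-weighted centers (default: geometric
#'   centers).
#' @param state redox-state label.
#' @return a `distance_series`.
#' @export
com_distance_series <- function(frames, group_a, group_b, times = NULL,
                                mass_weighted = FALSE,
                                state = c("initial", "final")) {
  if (is.null(times)) times <- seq_along(frames)
  d <- vapply(seq_along(frames), function(k) {
    fr <- frames[[k]]
    ga <- if (is.function(group_a)) group_a(fr) else group_a
    gb <- if (is.function(group_b)) group_b(fr) else group_b
    sqrt(sum((.group_center(fr, ga, mass_weighted) -
                .group_center(fr, gb, mass_weighted))^2))
  }, numeric(1))
  distance_series(times, d, state = state)
}

#' Two-site occupancy of a distance series
#'
#' Samples with `dist <= boundary` belong to the near site. Dwell times are
#' the mean lengths of contiguous same-site runs (converted to ps with the
#' median sampling interval); transitions are counted at site changes.
#'
#' @param series a `distance_series`.
#' @param boundary site boundary in Angstrom; the default 3.4 A is the
#'   midpoint of the two observed modes at 2.5 and 4.3 A.
#' @return an object of class `site_occupancy`: list with `boundary`,
#'   `fraction_near`, `fraction_far`, `mean_dwell_near`, `mean_dwell_far`
#'   (ps, `NA` when a site is never visited), `n_transitions`, `n_samples`.
#' @export
site_occupancy <- function(series, boundary = 3.4) {
  if (nrow(series) == 0L) stop("empty distance series")
  near <- series$dist <= boundary
  dt <- if (nrow(series) > 1L) stats::median(diff(series$time)) else 1
  runs <- rle(near)
  dwell <- function(val) {
    len <- runs$lengths[runs$values == val]
    if (length(len) == 0L) NA_real_ else mean(len) * dt
  }
  structure(list(
    boundary = boundary,
    fraction_near = mean(near),
    fraction_far = mean(!near),
    mean_dwell_near = dwell(TRUE),
    mean_dwell_far = dwell(FALSE),
    n_transitions = length(runs$lengths) - 1L,
    n_samples = nrow(series)
  ), class = "site_occupancy")
}

#' @export
print.site_occupancy <- function(x, ...) {
  cat(sprintf("two-site occupancy (boundary %.2f A, n = %d)\n",
              x$boundary, x$n_samples))
  cat(sprintf("  near %.1f%% (mean dwell %.3g ps), far %.1f%% (mean dwell %.3g ps)\n",
              100 * x$fraction_near, x$mean_dwell_near,
              100 * x$fraction_far, x$mean_dwell_far))
  cat("  transitions:", x$n_transitions, "\n")
  invisible(x)
}

#' Normalized distance histogram, per state
#'
#' @param series a `distance_series` or a (possibly named) list of them,
#'   e.g. one per redox state.
#' @param bins number of bins (common breaks across states).
#' @return data.frame with columns `state`, `mid`, `prob` (probabilities
#'   sum to 1 within each state).
#' @export
distance_histogram <- function(series, bins = 40) {
  if (is.data.frame(series)) series <- list(series)
  if (is.null(names(series)))
    names(series) <- vapply(series, function(s)
      attr(s, "state") %||% "all", character(1))
  all_d <- unlist(lapply(series, function(s) s$dist))
  if (length(all_d) == 0L) stop("empty distance series")
  breaks <- seq(min(all_d), max(all_d), length.out = bins + 1L)
  if (breaks[1] == breaks[bins + 1L])
    breaks <- breaks[1] + seq(-0.5, 0.5, length.out = bins + 1L)
  out <- lapply(names(series), function(st) {
    h <- graphics::hist(series[[st]]$dist, breaks = breaks, plot = FALSE)
    data.frame(state = st, mid = h$mids,
               prob = h$counts / nrow(series[[st]]))
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify heme-to-dioxygen pathways as short or long
#'
#' A pathway is `"short"` when its final step is a direct through-space
#' jump from a heme conductive atom onto O2, and `"long"` when the path
#' passes through an intervening residue (e.g. a histidine of the cavity)
#' before reaching O2.
#'
#' @param ensemble an `et_pathway_ensemble` computed with the heme
#'   macrocycle as donor and the O2 atoms as acceptor (the last atom of
#'   every pathway is then an O2 atom).
#' @param heme_atoms atom indices of the heme conductive set.
#' @param states optional character vector of per-frame redox-state labels
#'   for a per-state breakdown.
#' @return an object of class `o2_pathway_classes`: list with `classes`
#'   (per-pathway factor `"short"`/`"long"`), `summary` (data.frame
#'   `class`, `n`, `occupancy_pct`, `mean_decay`) and, when `states` is
#'   given, `by_state` (occupancy of each class within each state, pct).
#' @export
classify_o2_pathways <- function(ensemble, heme_atoms, states = NULL) {
  ok <- which(!vapply(ensemble, is.null, logical(1)))
  if (length(ok) == 0L) stop("no heme-to-O2 pathways supplied")
  cls <- vapply(ok, function(k) {
    p <- ensemble[[k]]
    nstep <- length(p$edge_types)
    direct <- nstep > 0L && p$edge_types[nstep] == "through_space" &&
      p$atoms[nstep] %in% heme_atoms
    if (direct) "short" else "long"
  }, character(1))
  eps <- vapply(ensemble[ok], function(p) p$epsilon_tot, numeric(1))
  sp <- split(eps, cls)
  smry <- data.frame(
    class = names(sp),
    n = vapply(sp, length, integer(1)),
    occupancy_pct = 100 * vapply(sp, length, integer(1)) / length(eps),
    mean_decay = vapply(sp, mean, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  by_state <- NULL
  if (!is.null(states)) {
    st <- states[ok]
    by_state <- as.data.frame(100 * prop.table(table(state = st,
                                                     class = cls), 1))
    names(by_state)[3] <- "occupancy_pct"
  }
  structure(list(classes = factor(cls, levels = c("short", "long")),
                 summary = smry, by_state = by_state),
            class = "o2_pathway_classes")
}

#' @export
print.o2_pathway_classes <- function(x, ...) {
  cat("heme-to-O2 pathway classification\n")
  for (k in seq_len(nrow(x$summary)))
    cat(sprintf("  %-6s %5.1f%%  <eps> = %.3g  (n = %d)\n",
                x$summary$class[k], x$summary$occupancy_pct[k],
                x$summary$mean_decay[k], x$summary$n[k]))
  if (!is.null(x$by_state)) print(x$by_state)
  invisible(x)
}
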