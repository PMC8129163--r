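## Covalent-bond and hydrogen-bond perception.
##
## Bonds are perceived geometrically: a pair is covalently bonded when its
## distance does not exceed the sum of the two covalent radii plus a
## tolerance (0.4 A by default, the common distance-based convention).
## Hydrogen bonds are recorded between N/O/S heavy atoms; the stored length
## R_H is the inter-heavy-atom distance, the quantity entering the
## hydrogen-bond decay factor.

# Single-bond covalent radii in Angstrom (Cordero et al. compilation).
.covalent_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, CL = 1.02, BR = 1.20, SE = 1.20, I = 1.39,
  FE = 1.32, ZN = 1.22, CU = 1.32, MG = 1.41, MN = 1.39, NI = 1.24,
  CO = 1.26, MO = 1.54, "NA" = 1.66, K = 2.03, CA = 1.76
)

.dist_matrix <- function(frame) {
  as.matrix(stats::dist(as.matrix(frame[, c("x", "y", "z")])))
}

#' Perceive covalent bonds from inter-atomic distances
#'
#' Two atoms are bonded when their distance is at most
#' `radius(i) + radius(j) + tolerance` (or the entry of an explicit
#' `cutoffs` table). Each hydrogen is bonded only to its nearest heavy
#' atom; hydrogen-hydrogen bonds are never recorded.
#'
#' @param frame a frame data.frame (see [read_structure()]).
#' @param cutoffs optional named matrix of element-pair cutoffs in Angstrom
#'   (dimnames = element symbols); overrides the radii-based default.
#' @param tolerance additive tolerance in Angstrom for the default table.
#' @return an object of class `bond_graph`: list with `covalent`
#'   (data.frame `i`, `j`, `dist`, atom indices with `i < j`) and `hydrogen`
#'   (empty until [detect_hydrogen_bonds()] is run).
#' @export
perceive_covalent_bonds <- function(frame, cutoffs = NULL, tolerance = 0.4) {
  el <- frame$element
  if (is.null(cutoffs)) {
    unknown <- setdiff(unique(el), names(.covalent_radii))
    if (length(unknown) > 0L)
      stop("no covalent radius for element(s): ",
           paste(unknown, collapse = ", "),
           "; supply a 'cutoffs' table")
    r <- .covalent_radii[el]
    cut <- outer(r, r, "+") + tolerance
  } else {
    missing_el <- setdiff(unique(el), rownames(cutoffs))
    if (length(missing_el) > 0L)
      stop("cutoff table lacks element(s): ", paste(missing_el, collapse = ", "))
    cut <- cutoffs[el, el]
  }
  d <- .dist_matrix(frame)
  n <- nrow(frame)
  bonded <- d <= cut & upper.tri(d)

  # hydrogens: keep only the bond to the nearest heavy atom
  hyd <- which(el == "H")
  if (length(hyd) > 0L) {
    full <- d <= cut
    diag(full) <- FALSE
    for (h in hyd) {
      partners <- which(full[h, ] & el != "H")
      keep <- if (length(partners) > 0L) partners[which.min(d[h, partners])]
              else integer(0)
      bonded[h, ] <- FALSE; bonded[, h] <- FALSE
      if (length(keep) == 1L) {
        i <- min(h, keep); j <- max(h, keep)
        bonded[i, j] <- TRUE
      }
    }
  }

  idx <- which(bonded, arr.ind = TRUE)
  cov <- data.frame(
    i = frame$atom_index[idx[, 1]],
    j = frame$atom_index[idx[, 2]],
    dist = d[idx]
  )
  swap <- cov$i > cov$j
  if (any(swap)) cov[swap, c("i", "j")] <- cov[swap, c("j", "i")]
  cov <- cov[order(cov$i, cov$j), , drop = FALSE]
  rownames(cov) <- NULL
  structure(list(covalent = cov,
                 hydrogen = data.frame(donor = integer(0),
                                       acceptor = integer(0),
                                       r_h = numeric(0))),
            class = "bond_graph")
}

#' @export
print.bond_graph <- function(x, ...) {
  cat("bond_graph:", nrow(x$covalent), "covalent bond(s),",
      nrow(x$hydrogen), "hydrogen bond(s)\n")
  invisible(x)
}

#' Detect hydrogen bonds between heavy atoms
#'
#' A hydrogen bond is recorded between a donor heavy atom (N/O/S) and an
#' acceptor heavy atom (N/O/S) when the inter-heavy-atom distance is at most
#' `dist_cutoff` and, when the angle criterion is active, some donor
#' hydrogen makes a donor-H-acceptor angle of at least `angle_cutoff`.
#' The angle criterion is active by default only when the frame contains
#' hydrogens; on hydrogen-free structures every N/O/S pair within the
#' distance cutoff (and not covalently bonded or sharing a bonded
#' neighbour) counts, which keeps the criterion reproducible on
#' heavy-atom-only snapshots. The stored `r_h` is the heavy-heavy distance.
#'
#' @param frame a frame data.frame.
#' @param bonds a `bond_graph` from [perceive_covalent_bonds()].
#' @param dist_cutoff maximum donor-acceptor heavy-atom distance (Angstrom).
#' @param angle_cutoff minimum donor-H-acceptor angle in degrees.
#' @param use_angle logical; `NULL` (default) enables the angle criterion
#'   iff hydrogens are present.
#' @return the `bond_graph` with its `hydrogen` component filled
#'   (data.frame `donor`, `acceptor`, `r_h`).
#' @export
detect_hydrogen_bonds <- function(frame, bonds, dist_cutoff = 3.5,
                                  angle_cutoff = 120, use_angle = NULL) {
  el <- frame$element
  has_h <- any(el == "H")
  if (is.null(use_angle)) use_angle <- has_h

  pos <- function(ai) match(ai, frame$atom_index)
  cov <- bonds$covalent
  adj <- lapply(seq_len(nrow(frame)), function(k) integer(0))
  for (r in seq_len(nrow(cov))) {
    a <- pos(cov$i[r]); b <- pos(cov$j[r])
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }

  heavy_nos <- which(el %in% c("N", "O", "S"))
  if (has_h) {
    donors <- heavy_nos[vapply(heavy_nos, function(k)
      any(el[adj[[k]]] == "H"), logical(1))]
  } else {
    donors <- heavy_nos
  }
  d <- .dist_matrix(frame)
  hb <- list()
  seen <- character(0)
  for (dn in donors) {
    for (ac in heavy_nos) {
      if (ac == dn) next
      if (ac %in% adj[[dn]]) next               # covalently bonded
      if (length(intersect(adj[[dn]], adj[[ac]])) > 0L) next  # 1-3 pair
      if (d[dn, ac] > dist_cutoff) next
      if (use_angle) {
        hs <- adj[[dn]][el[adj[[dn]]] == "H"]
        ok <- FALSE
        for (h in hs) {
          v1 <- as.numeric(frame[dn, c("x", "y", "z")] - frame[h, c("x", "y", "z")])
          v2 <- as.numeric(frame[ac, c("x", "y", "z")] - frame[h, c("x", "y", "z")])
          ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                     sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          if (ang >= angle_cutoff) { ok <- TRUE; break }
        }
        if (!ok) next
      }
      # without hydrogens donor/acceptor roles are symmetric; record each
      # unordered pair once
      key <- paste(sort(c(dn, ac)), collapse = "-")
      if (!has_h && key %in% seen) next
      seen <- c(seen, key)
      hb[[length(hb) + 1L]] <- data.frame(
        donor = frame$atom_index[dn],
        acceptor = frame$atom_index[ac],
        r_h = d[dn, ac]
      )
    }
  }
  bonds$hydrogen <- if (length(hb) > 0L) do.call(rbind, hb) else
    data.frame(donor = integer(0), acceptor = integer(0), r_h = numeric(0))
  rownames(bonds$hydrogen) <- NULL
  bonds
}
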