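## Tunneling-graph construction.
##
## Nodes are heavy atoms; each unordered pair carries at most one edge, of
## the type giving the largest decay:
##   conductive    eps = 1        covalent bond inside a porphyrin macrocycle
##                                (or any user-declared conductive set)
##   covalent      eps = eps_c
##   hbond         eps_hb(R_H)
##   through_space eps_ts(R_S)    only for pairs within ts_max_distance

#' Build the tunneling decay graph of a frame
#'
#' @param frame a frame data.frame (see [read_structure()]).
#' @param bonds a `bond_graph`, ideally after [detect_hydrogen_bonds()].
#' @param conductive_sets list of integer vectors of `atom_index`; covalent
#'   bonds with both endpoints inside the same set become fully conductive
#'   (decay exactly 1). Typically one set per heme macrocycle
#'   ([porphyrin_core_atoms()]).
#' @param params a [pathway_params()] object.
#' @return an object of class `tunneling_graph`: list with `nodes` (heavy
#'   atom indices), `edges` (data.frame `i`, `j`, `type`, `decay`, `dist`)
#'   and `params`.
#' @export
build_tunneling_graph <- function(frame, bonds,
                                  conductive_sets = list(),
                                  params = pathway_params()) {
  heavy <- frame[frame$element != "H", , drop = FALSE]
  if (nrow(heavy) < 2L) stop("graph needs at least two heavy atoms")
  d <- .dist_matrix(heavy)
  n <- nrow(heavy)
  id <- heavy$atom_index

  pairs <- which(upper.tri(d) & d <= params$ts_max_distance, arr.ind = TRUE)
  edges <- data.frame(
    i = id[pairs[, 1]], j = id[pairs[, 2]],
    type = rep_len("through_space", nrow(pairs)),
    decay = if (nrow(pairs) > 0L)
      space_decay(pmax(d[pairs], 1e-12), params) else numeric(0),
    dist = d[pairs], stringsAsFactors = FALSE
  )

  # largest decay wins; on exact ties the more "bonded" type is recorded
  # (a capped through-space factor never outranks a real covalent bond)
  type_rank <- c(through_space = 1, hbond = 2, covalent = 3, conductive = 4)
  upgrade <- function(edges, i, j, type, decay, dist) {
    key_new <- paste(pmin(i, j), pmax(i, j))
    key_old <- paste(pmin(edges$i, edges$j), pmax(edges$i, edges$j))
    hit <- match(key_new, key_old)
    for (k in seq_along(hit)) {
      if (is.na(hit[k])) {
        edges <- rbind(edges, data.frame(i = min(i[k], j[k]),
                                         j = max(i[k], j[k]),
                                         type = type[k], decay = decay[k],
                                         dist = dist[k]))
      } else if (decay[k] > edges$decay[hit[k]] ||
                 (decay[k] == edges$decay[hit[k]] &&
                  type_rank[type[k]] > type_rank[edges$type[hit[k]]])) {
        edges$type[hit[k]] <- type[k]
        edges$decay[hit[k]] <- decay[k]
      }
    }
    edges
  }

  cov <- bonds$covalent
  cov <- cov[cov$i %in% id & cov$j %in% id, , drop = FALSE]  # heavy only
  if (nrow(cov) > 0L) {
    in_same_set <- function(a, b) any(vapply(
      conductive_sets, function(s) a %in% s && b %in% s, logical(1)))
    conductive <- mapply(in_same_set, cov$i, cov$j)
    type <- ifelse(conductive, "conductive", "covalent")
    decay <- ifelse(conductive, 1, params$epsilon_c)
    edges <- upgrade(edges, cov$i, cov$j, type, decay, cov$dist)
  }

  hb <- bonds$hydrogen
  hb <- hb[hb$donor %in% id & hb$acceptor %in% id, , drop = FALSE]
  if (nrow(hb) > 0L) {
    edges <- upgrade(edges, hb$donor, hb$acceptor,
                     rep("hbond", nrow(hb)), hbond_decay(hb$r_h, params),
                     hb$r_h)
  }

  if (nrow(edges) == 0L) stop("empty tunneling graph")
  stopifnot(all(edges$decay > 0 & edges$decay <= 1))
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = sort(id), edges = edges, params = params),
            class = "tunneling_graph")
}

#' Assemble a tunneling graph directly from an edge table
#'
#' Mainly for toy graphs and property tests; bypasses geometry.
#'
#' @param i,j integer node ids.
#' @param decay per-edge decay factors in (0, 1].
#' @param type edge types (default `"through_space"`).
#' @param params a [pathway_params()] object.
#' @return a `tunneling_graph`.
#' @export
tunneling_graph <- function(i, j, decay, type = "through_space",
                            params = pathway_params()) {
  stopifnot(length(i) == length(j), length(decay) == length(i))
  if (any(decay <= 0 | decay > 1)) stop("decays must lie in (0, 1]")
  if (any(i == j)) stop("self-edges not allowed")
  edges <- data.frame(i = pmin(i, j), j = pmax(i, j),
                      type = rep_len(type, length(i)), decay = decay,
                      dist = NA_real_, stringsAsFactors = FALSE)
  key <- paste(edges$i, edges$j)
  if (anyDuplicated(key)) {
    edges <- edges[order(key, -edges$decay), , drop = FALSE]
    edges <- edges[!duplicated(paste(edges$i, edges$j)), , drop = FALSE]
  }
  structure(list(nodes = sort(unique(c(i, j))), edges = edges,
                 params = params),
            class = "tunneling_graph")
}

#' @export
print.tunneling_graph <- function(x, ...) {
  cat("tunneling_graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  print(table(x$edges$type))
  invisible(x)
}
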