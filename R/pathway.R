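## Best-pathway search.
##
## Maximizing the product of edge decays is equivalent to minimizing the
## sum of weights w = -ln(eps), which are non-negative because every decay
## lies in (0, 1]; Dijkstra is therefore exact. A virtual source connects
## to every donor atom and a virtual sink to every acceptor atom with
## zero-weight edges, so the search is independent of the particular
## donor/acceptor atom chosen. Ties are broken deterministically: among all
## optimal simple paths the lexicographically smallest atom-index sequence
## is returned (a shorter optimal path precedes its extensions).

# two log-costs are considered tied when they differ by less than this
.path_log_tol <- 1e-9

# lexicographic comparison of integer sequences; a proper prefix sorts first
.seq_less <- function(a, b) {
  n <- min(length(a), length(b))
  for (k in seq_len(n)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  length(a) < length(b)
}

.graph_adjacency <- function(graph) {
  nodes <- graph$nodes
  adj <- stats::setNames(vector("list", length(nodes)), as.character(nodes))
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    ci <- as.character(e$i[r]); cj <- as.character(e$j[r])
    adj[[ci]] <- rbind(adj[[ci]], c(e$j[r], e$decay[r], r))
    adj[[cj]] <- rbind(adj[[cj]], c(e$i[r], e$decay[r], r))
  }
  adj
}

#' Best tunneling pathway between donor and acceptor atom sets
#'
#' Finds the pathway maximizing the product of edge decay factors with a
#' Dijkstra search (shortest path under additive weights `-ln(eps)`).
#'
#' @param graph a `tunneling_graph`.
#' @param donor,acceptor non-empty, disjoint integer vectors of atom
#'   indices.
#' @return an object of class `et_pathway`: list with `atoms` (ordered
#'   atom-index sequence), `edge_types`, `edge_decays`, `epsilon_tot`, and
#'   step counts `n_covalent`, `n_hbond`, `n_ts`, `n_conductive`.
#' @export
best_pathway <- function(graph, donor, acceptor) {
  donor <- sort(unique(donor)); acceptor <- sort(unique(acceptor))
  if (length(donor) == 0L || length(acceptor) == 0L)
    stop("donor and acceptor sets must be non-empty")
  if (length(intersect(donor, acceptor)) > 0L)
    stop("donor and acceptor sets must be disjoint")
  if (!all(c(donor, acceptor) %in% graph$nodes))
    stop("donor/acceptor atoms absent from graph")

  e <- graph$edges
  vnames <- as.character(graph$nodes)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$i), to = as.character(e$j)),
    directed = FALSE,
    vertices = data.frame(name = vnames)
  )
  w <- -log(e$decay)
  d_src <- igraph::distances(g, v = as.character(donor), weights = w)
  d_snk <- igraph::distances(g, v = as.character(acceptor), weights = w)
  ds <- apply(d_src, 2, min)    # virtual source = min over donor atoms
  dt <- apply(d_snk, 2, min)
  total <- min(ds[as.character(acceptor)])
  if (!is.finite(total)) stop("no pathway connects donor to acceptor")

  adj <- .graph_adjacency(graph)
  tol <- .path_log_tol * max(1, abs(total))

  # depth-first search restricted to edges lying on an optimal path,
  # visiting candidate next atoms in increasing index order; the first
  # complete path found is the lexicographically smallest optimal one.
  found <- NULL
  dfs <- function(node, cost, path, edge_rows) {
    if (!is.null(found)) return()
    cn <- as.character(node)
    if (node %in% acceptor && abs(cost - total) <= tol) {
      found <<- list(path = path, edge_rows = edge_rows)
      return()
    }
    nb <- adj[[cn]]
    if (is.null(nb)) return()
    cand <- nb[order(nb[, 1]), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      v <- cand[r, 1]
      if (v %in% path) next
      wuv <- -log(cand[r, 2])
      nc <- cost + wuv
      cv <- as.character(v)
      if (nc + dt[cv] > total + tol) next       # not on an optimal path
      if (abs(nc - ds[cv]) > tol && nc > ds[cv] + tol) next
      dfs(v, nc, c(path, v), c(edge_rows, cand[r, 3]))
      if (!is.null(found)) return()
    }
  }
  starts <- donor[abs(ds[as.character(donor)]) <= tol |
                    ds[as.character(donor)] + dt[as.character(donor)] <=
                    total + tol]
  for (s in sort(starts)) {
    dfs(s, 0, s, integer(0))
    if (!is.null(found)) break
  }
  if (is.null(found)) stop("no pathway connects donor to acceptor")

  rows <- found$edge_rows
  types <- e$type[rows]
  decays <- e$decay[rows]
  structure(list(
    atoms = found$path,
    edge_types = types,
    edge_decays = decays,
    epsilon_tot = prod(decays),
    n_covalent = sum(types == "covalent"),
    n_hbond = sum(types == "hbond"),
    n_ts = sum(types == "through_space"),
    n_conductive = sum(types == "conductive")
  ), class = "et_pathway")
}

#' @export
print.et_pathway <- function(x, ...) {
  cat("tunneling pathway:", paste(x$atoms, collapse = " - "), "\n")
  cat(sprintf("  eps_tot = %.4g  (N_c = %d, N_hb = %d, N_ts = %d, conductive = %d)\n",
              x$epsilon_tot, x$n_covalent, x$n_hbond, x$n_ts,
              x$n_conductive))
  if (!is.null(x$route_label)) cat("  route:", x$route_label, "\n")
  invisible(x)
}

#' Decompose a pathway over step types and mediating residues
#'
#' Annotates a pathway with the ordered list of residues its atoms cross
#' and a route label: the non-cofactor mediating residue carrying the path
#' (the one contributing most path atoms; ties go to the first visited), or
#' `"direct"` when the path touches only the donor/acceptor cofactors.
#'
#' @param pathway an `et_pathway`.
#' @param frame the frame the pathway was computed on.
#' @param cofactor_resnames residue names treated as cofactors (hemes,
#'   flavins, dioxygen) and therefore excluded from route labelling.
#' @return the pathway with `mediating_residues` and `route_label` added.
#' @export
decompose_pathway <- function(pathway, frame,
                              cofactor_resnames = c("HEM", "HEC", "HEB",
                                                    "HEA", "FAD", "FMN",
                                                    "OXY", "O2", "OXG")) {
  at <- frame[match(pathway$atoms, frame$atom_index), , drop = FALSE]
  lab <- paste0(substr(at$resname, 1, 1),
                tolower(substr(at$resname, 2, nchar(at$resname))), at$resno)
  runs <- rle(lab)
  pathway$mediating_residues <- runs$values
  medi <- !(at$resname %in% cofactor_resnames)
  if (any(medi)) {
    tab <- table(factor(lab[medi], levels = unique(lab[medi])))
    pathway$route_label <- names(tab)[which.max(tab)]
  } else {
    pathway$route_label <- "direct"
  }
  pathway
}

#' Best pathway for every frame of a trajectory
#'
#' Runs bond perception, hydrogen-bond detection, graph construction and
#' the best-path search on each frame. Frames where donor and acceptor are
#' disconnected are recorded as missing (`NULL`, counted in the summary),
#' never dropped silently.
#'
#' @param frames an `et_frames` list (or list of frame data.frames).
#' @param donor,acceptor atom-index vectors, or functions of a frame
#'   returning them (e.g. wrapping [porphyrin_core_atoms()]).
#' @param conductive_sets list of atom-index vectors, or a function of a
#'   frame returning such a list; defaults to `list(donor, acceptor)`.
#' @param params a [pathway_params()] object.
#' @param hbond_args list of extra arguments for
#'   [detect_hydrogen_bonds()].
#' @return an object of class `et_pathway_ensemble`: list of pathways (with
#'   `NULL` for pathless frames) with a `frames_missing` attribute.
#' @export
pathway_ensemble <- function(frames, donor, acceptor,
                             conductive_sets = NULL,
                             params = pathway_params(),
                             hbond_args = list()) {
  if (length(frames) < 1L) stop("need at least one frame")
  out <- vector("list", length(frames))
  n_missing <- 0L
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    don <- if (is.function(donor)) donor(fr) else donor
    acc <- if (is.function(acceptor)) acceptor(fr) else acceptor
    cs <- if (is.function(conductive_sets)) conductive_sets(fr)
          else if (is.null(conductive_sets)) list(don, acc)
          else conductive_sets
    bonds <- perceive_covalent_bonds(fr)
    bonds <- do.call(detect_hydrogen_bonds,
                     c(list(frame = fr, bonds = bonds), hbond_args))
    graph <- build_tunneling_graph(fr, bonds, conductive_sets = cs,
                                   params = params)
    pw <- tryCatch(best_pathway(graph, don, acc), error = function(e) NULL)
    if (is.null(pw)) n_missing <- n_missing + 1L
    else pw <- decompose_pathway(pw, fr)
    out[[k]] <- pw
  }
  if (n_missing == length(frames)) stop("no frame admits a pathway")
  structure(out, class = "et_pathway_ensemble", frames_missing = n_missing)
}

#' @export
print.et_pathway_ensemble <- function(x, ...) {
  ok <- !vapply(x, is.null, logical(1))
  cat("pathway ensemble:", length(x), "frame(s),",
      attr(x, "frames_missing"), "without a pathway\n")
  if (any(ok)) {
    eps <- vapply(x[ok], function(p) p$epsilon_tot, numeric(1))
    cat(sprintf("  <eps_tot> = %.4g (n = %d)\n", mean(eps), sum(ok)))
    labs <- vapply(x[ok], function(p)
      if (is.null(p$route_label)) NA_character_ else p$route_label,
      character(1))
    if (!all(is.na(labs))) print(round(100 * table(labs) / sum(ok), 1))
  }
  invisible(x)
}

#' Extract per-frame decay factors and route labels from an ensemble
#'
#' @param ensemble an `et_pathway_ensemble`.
#' @return data.frame with columns `frame`, `epsilon_tot`, `n_covalent`,
#'   `n_hbond`, `n_ts`, `route_label` (pathless frames excluded).
#' @export
ensemble_table <- function(ensemble) {
  ok <- which(!vapply(ensemble, is.null, logical(1)))
  data.frame(
    frame = ok,
    epsilon_tot = vapply(ensemble[ok], function(p) p$epsilon_tot, numeric(1)),
    n_covalent = vapply(ensemble[ok], function(p) p$n_covalent, integer(1)),
    n_hbond = vapply(ensemble[ok], function(p) p$n_hbond, integer(1)),
    n_ts = vapply(ensemble[ok], function(p) p$n_ts, integer(1)),
    route_label = vapply(ensemble[ok], function(p)
      if (is.null(p$route_label)) "direct" else p$route_label, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Export a pathway for molecular-viewer rendering
#'
#' Writes `<prefix>.pdb` containing the pathway atoms and `<prefix>.vmd`,
#' a VMD Tcl script drawing the pathway as a tube through those atoms.
#'
#' @param pathway an `et_pathway`.
#' @param frame the frame it was computed on.
#' @param prefix output path prefix.
#' @return character vector of the two file paths, invisibly.
#' @export
export_path_visualization <- function(pathway, frame, prefix) {
  if (length(pathway$atoms) == 0L) stop("empty pathway")
  sub <- frame[match(pathway$atoms, frame$atom_index), , drop = FALSE]
  pdb_file <- paste0(prefix, ".pdb")
  vmd_file <- paste0(prefix, ".vmd")
  write_structure(sub, pdb_file)
  lines <- c(
    "# draw the tunneling pathway as a tube",
    sprintf("mol new {%s} type pdb", pdb_file),
    "draw color green",
    vapply(seq_len(nrow(sub) - 1L), function(k) {
      sprintf("draw cylinder {%.3f %.3f %.3f} {%.3f %.3f %.3f} radius 0.2",
              sub$x[k], sub$y[k], sub$z[k],
              sub$x[k + 1], sub$y[k + 1], sub$z[k + 1])
    }, character(1))
  )
  writeLines(lines, vmd_file)
  invisible(c(pdb_file, vmd_file))
}
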