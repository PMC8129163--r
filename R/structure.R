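## Structure model: frames from multi-model PDB files.
##
## A "frame" is a plain data.frame with one row per atom and columns
##   atom_index, name, element, resname, resno, chain, x, y, z
## Coordinates are in Angstrom, residue numbering is the 1-based PDB
## numbering. A collection of frames is an ordinary list of such
## data.frames (class "et_frames") in file order.

# Two-letter element symbols accepted during name-based inference. NA and CA
# are deliberately absent: as bare atom names they almost always denote the
# heme pyrrole nitrogen and the alpha carbon, not sodium/calcium. Monatomic
# ion residues are handled separately by matching residue name == atom name.
.two_letter_elements <- c("FE", "ZN", "CU", "MG", "MN", "NI", "CO", "SE",
                          "CL", "BR", "MO")
.ion_residues <- c("NA", "CA", "K", "CL", "MG", "ZN", "FE", "MN", "BR")

#' Infer element symbols from PDB atom names
#'
#' Used as a fallback when the PDB element column is absent. Leading digits
#' are stripped (e.g. `"1HB"` is hydrogen); two-letter metal/halide symbols
#' are recognised when the atom name starts with them; monatomic ion
#' residues (residue name equal to the atom name, e.g. `NA`/`CL`) map to the
#' ion's element. Everything else takes the first alphabetic character.
#'
#' @param name character vector of PDB atom names.
#' @param resname character vector of residue names (same length), used only
#'   to disambiguate monatomic ions.
#' @return character vector of element symbols.
#' @export
infer_element <- function(name, resname = rep("", length(name))) {
  name <- toupper(trimws(name))
  resname <- toupper(trimws(resname))
  out <- character(length(name))
  for (k in seq_along(name)) {
    nm <- sub("^[0-9']+", "", name[k])
    if (nzchar(resname[k]) && resname[k] %in% .ion_residues &&
        nm == resname[k]) {
      out[k] <- resname[k]
    } else if (nchar(nm) >= 2 && substr(nm, 1, 2) %in% .two_letter_elements) {
      out[k] <- substr(nm, 1, 2)
    } else {
      out[k] <- substr(gsub("[^A-Z]", "", nm), 1, 1)
    }
    if (!nzchar(out[k]))
      stop("cannot resolve element for atom name '", name[k], "'")
  }
  out
}

#' Read trajectory snapshots from a (multi-model) PDB file
#'
#' MODEL/ENDMDL records delimit frames; a single-model file yields one
#' frame. Alternate locations other than blank or 'A' are dropped. Elements
#' come from the PDB element column when present, with a fall back to
#' atom-name conventions (see [infer_element()]).
#'
#' @param path path to a PDB file.
#' @param keep_hydrogens keep hydrogen atoms (default `TRUE`); hydrogens are
#'   needed for the geometric hydrogen-bond criterion but are never pathway
#'   nodes.
#' @return an object of class `et_frames`: a list of atom data.frames, one
#'   per model, each with columns `atom_index`, `name`, `element`,
#'   `resname`, `resno`, `chain`, `x`, `y`, `z`.
#' @export
read_structure <- function(path, keep_hydrogens = TRUE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L) stop("PDB file contains no atoms after filtering: ", path)

  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | !nzchar(elem)
  if (any(miss))
    elem[miss] <- infer_element(at$elety[miss], at$resid[miss])

  atoms <- data.frame(
    atom_index = at$eleno,
    name = trimws(at$elety),
    element = elem,
    resname = trimws(at$resid),
    resno = at$resno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    stringsAsFactors = FALSE
  )
  if (!keep_hydrogens) atoms <- atoms[atoms$element != "H", , drop = FALSE]
  if (anyDuplicated(atoms$atom_index))
    stop("duplicate atom indices within a frame")

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nmod <- nrow(xyz)
  sel3 <- as.vector(rbind(3L * (which(keep)) - 2L,
                          3L * (which(keep)) - 1L,
                          3L * (which(keep))))
  frames <- vector("list", nmod)
  for (m in seq_len(nmod)) {
    co <- matrix(xyz[m, sel3], ncol = 3L, byrow = TRUE)
    if (!keep_hydrogens) co <- co[elem != "H", , drop = FALSE]
    fr <- atoms
    fr$x <- co[, 1]; fr$y <- co[, 2]; fr$z <- co[, 3]
    if (any(!is.finite(c(fr$x, fr$y, fr$z))))
      stop("non-finite coordinates in model ", m)
    attr(fr, "frame_index") <- m
    class(fr) <- c("et_frame", "data.frame")
    frames[[m]] <- fr
  }
  structure(frames, class = "et_frames", source = path)
}

#' Write frames to a (multi-model) PDB file
#'
#' The inverse of [read_structure()]; one MODEL block per frame.
#'
#' @param frames an `et_frames` list, or a single frame data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(frames, path) {
  if (is.data.frame(frames)) frames <- list(frames)
  a <- frames[[1]]
  xyz <- do.call(rbind, lapply(frames, function(fr) {
    as.vector(t(as.matrix(fr[, c("x", "y", "z")])))
  }))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    eleno = a$atom_index, elety = a$name, resid = a$resname,
    resno = a$resno, chain = a$chain, elesy = a$element
  )
  invisible(path)
}

#' @export
print.et_frames <- function(x, ...) {
  cat("et_frames:", length(x), "frame(s),", nrow(x[[1]]), "atoms each\n")
  invisible(x)
}

# Construct a frame data.frame from vectors; used by fixtures and generators.
#' Build a single frame from atom vectors
#'
#' Convenience constructor used by the synthetic-structure generator and by
#' tests; performs the same validation as [read_structure()].
#'
#' @param name,element,resname,chain character vectors (recycled to the
#'   number of atoms).
#' @param resno integer residue numbers.
#' @param x,y,z coordinates in Angstrom.
#' @param atom_index atom serial numbers (default `1:n`).
#' @return an `et_frame` data.frame.
#' @export
make_frame <- function(name, element, resname, resno, x, y, z,
                       chain = "A", atom_index = seq_along(x)) {
  n <- length(x)
  fr <- data.frame(
    atom_index = atom_index,
    name = rep_len(name, n), element = rep_len(toupper(element), n),
    resname = rep_len(resname, n), resno = rep_len(resno, n),
    chain = rep_len(chain, n),
    x = x, y = y, z = z, stringsAsFactors = FALSE
  )
  if (n < 1L) stop("frame must contain at least one atom")
  if (anyDuplicated(fr$atom_index)) stop("atom_index must be unique")
  if (any(!is.finite(c(x, y, z)))) stop("coordinates must be finite")
  if (any(!nzchar(fr$element))) stop("element must be non-empty")
  class(fr) <- c("et_frame", "data.frame")
  fr
}

# Residue identity is (chain, resno, resname) throughout.
.residue_key <- function(fr) paste(fr$chain, fr$resno, fr$resname)

#' Select atoms of a frame by residue/atom attributes
#'
#' All supplied filters are combined with AND; `NULL` means "any".
#'
#' @param frame a frame data.frame.
#' @param resname,resno,chain,name,element optional filters.
#' @return integer vector of `atom_index` values (possibly empty).
#' @export
select_atoms <- function(frame, resname = NULL, resno = NULL, chain = NULL,
                         name = NULL, element = NULL) {
  keep <- rep(TRUE, nrow(frame))
  if (!is.null(resname)) keep <- keep & frame$resname %in% resname
  if (!is.null(resno)) keep <- keep & frame$resno %in% resno
  if (!is.null(chain)) keep <- keep & frame$chain %in% chain
  if (!is.null(name)) keep <- keep & frame$name %in% name
  if (!is.null(element)) keep <- keep & frame$element %in% element
  frame$atom_index[keep]
}

#' Prune a frame to the tunneling-relevant region
#'
#' Keeps whole residues, either those named explicitly in `residues` or
#' those with at least one atom within `radius` of the donor-acceptor axis
#' (the segment joining the geometric centers of the donor and acceptor
#' residues). Donor and acceptor residues are always retained. Coordinates
#' and atom indices are untouched; only membership changes.
#'
#' @param frame a frame data.frame.
#' @param residues data.frame with columns `resname`, `resno` and optionally
#'   `chain` listing residues to keep.
#' @param donor,acceptor residue specifiers (single-row data.frames or lists
#'   with `resname`/`resno`/`chain`) used for the axis selection and for the
#'   retention guarantee.
#' @param radius radial cutoff in Angstrom for the axis selection.
#' @return the pruned frame.
#' @export
prune_to_region <- function(frame, residues = NULL, donor = NULL,
                            acceptor = NULL, radius = NULL) {
  key <- .residue_key(frame)
  res_id <- function(spec) {
    idx <- select_atoms(frame, resname = spec$resname, resno = spec$resno,
                        chain = spec$chain)
    if (length(idx) == 0L) stop("donor/acceptor residue not found in frame")
    unique(key[frame$atom_index %in% idx])
  }
  if (!is.null(residues)) {
    if (is.null(residues$chain)) residues$chain <- unique(frame$chain)[1]
    want <- paste(residues$chain, residues$resno, residues$resname)
    keep_key <- intersect(unique(key), want)
  } else if (!is.null(donor) && !is.null(acceptor) && !is.null(radius)) {
    da <- res_id(donor); aa <- res_id(acceptor)
    p1 <- colMeans(frame[key %in% da, c("x", "y", "z")])
    p2 <- colMeans(frame[key %in% aa, c("x", "y", "z")])
    d <- .point_segment_distance(as.matrix(frame[, c("x", "y", "z")]), p1, p2)
    keep_key <- unique(key[d <= radius])
    keep_key <- union(keep_key, c(da, aa))
  } else {
    stop("supply either 'residues' or donor/acceptor plus 'radius'")
  }
  if (!is.null(donor)) keep_key <- union(keep_key, res_id(donor))
  if (!is.null(acceptor)) keep_key <- union(keep_key, res_id(acceptor))
  out <- frame[key %in% keep_key, , drop = FALSE]
  if (nrow(out) == 0L) stop("selection is empty")
  out
}

# Distance from each row of matrix p (n x 3) to segment [a, b].
.point_segment_distance <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt(rowSums(sweep(p, 2, a)^2)))
  t <- pmin(1, pmax(0, (sweep(p, 2, a) %*% ab) / len2))
  proj <- outer(as.vector(t), ab) + matrix(a, nrow(p), 3, byrow = TRUE)
  sqrt(rowSums((p - proj)^2))
}

# Standard PDB naming of the heme macrocycle: 4 pyrrole nitrogens, 16 ring
# carbons and 4 meso carbons.
.porphyrin_names <- c(
  "NA", "NB", "NC", "ND",
  paste0("C", rep(1:4, times = 4), rep(c("A", "B", "C", "D"), each = 4)),
  "CHA", "CHB", "CHC", "CHD"
)

#' Atoms of the porphyrin macrocycle of a heme residue
#'
#' Returns the 24 macrocycle atoms (four pyrrole rings plus the four meso
#' carbons, by standard PDB heme atom naming). These atoms form the
#' fully-conductive set of the tunneling graph.
#'
#' @param frame a frame data.frame.
#' @param resno residue number of the heme.
#' @param chain chain identifier (default: any).
#' @param recognized residue names accepted as hemes.
#' @return integer vector of 24 `atom_index` values.
#' @export
porphyrin_core_atoms <- function(frame, resno, chain = NULL,
                                 recognized = c("HEM", "HEC", "HEB", "HEA")) {
  idx <- select_atoms(frame, resno = resno, chain = chain)
  if (length(idx) == 0L) stop("no residue ", resno, " in frame")
  sub <- frame[frame$atom_index %in% idx, , drop = FALSE]
  rn <- unique(sub$resname)
  if (!any(rn %in% recognized))
    stop("residue ", resno, " (", paste(rn, collapse = ","),
         ") is not a recognized heme")
  core <- sub$atom_index[sub$name %in% .porphyrin_names]
  missing <- setdiff(.porphyrin_names, sub$name)
  if (length(missing) > 0L)
    stop("heme residue ", resno, " is missing macrocycle atoms: ",
         paste(missing, collapse = ", "))
  core
}
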