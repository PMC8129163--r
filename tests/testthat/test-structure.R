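# Structure model: PDB reading, bond perception, pruning, heme macrocycle.

pdb_line <- function(serial, name, resname, resno, x, y, z, element) {
  sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, resname, resno, x, y, z, element)
}

test_that("single- and multi-model PDB files yield the right frames", {
  f1 <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "N", "ALA", 1, 0, 0, 0, "N"),
    pdb_line(2, "CA", "ALA", 1, 1.46, 0, 0, "C"),
    pdb_line(3, "C", "ALA", 1, 2.0, 1.42, 0, "C"),
    pdb_line(4, "O", "ALA", 1, 1.4, 2.49, 0, "O"),
    pdb_line(5, "CB", "ALA", 1, 2.23, -1.3, 0, "C"),
    "END"), f1)
  frames <- read_structure(f1)
  expect_length(frames, 1L)
  expect_equal(nrow(frames[[1]]), 5L)
  expect_equal(frames[[1]]$element, c("N", "C", "C", "O", "C"))

  f3 <- tempfile(fileext = ".pdb")
  body <- c(pdb_line(1, "N", "GLY", 1, 0, 0, 0, "N"),
            pdb_line(2, "CA", "GLY", 1, 1.45, 0, 0, "C"))
  writeLines(c("MODEL        1", body, "ENDMDL",
               "MODEL        2", sub("0.000", "1.000", body), "ENDMDL",
               "MODEL        3", body, "ENDMDL", "END"), f3)
  frames3 <- read_structure(f3)
  expect_length(frames3, 3L)
  for (k in 2:3) {
    expect_identical(frames3[[k]]$name, frames3[[1]]$name)
    expect_identical(frames3[[k]]$atom_index, frames3[[1]]$atom_index)
  }
  expect_error(read_structure(tempfile()), "cannot read")
})

test_that("write-then-read round trip preserves coordinates to PDB precision", {
  toy <- make_toy_structure(list(type = "bridge"))
  f <- tempfile(fileext = ".pdb")
  write_structure(toy$frame, f)
  back <- read_structure(f)[[1]]
  expect_equal(nrow(back), nrow(toy$frame))
  expect_equal(back$x, toy$frame$x, tolerance = 1e-3)
  expect_equal(back$y, toy$frame$y, tolerance = 1e-3)
  expect_equal(back$z, toy$frame$z, tolerance = 1e-3)
  expect_identical(back$element, toy$frame$element)
})

test_that("element inference handles digits, ions and metals", {
  expect_identical(infer_element(c("CA", "1HB", "NE1", "FE", "OXT")),
                   c("C", "H", "N", "FE", "O"))
  expect_identical(infer_element("NA", "HEM"), "N")  # pyrrole nitrogen
  expect_identical(infer_element("NA", "NA"), "NA")  # sodium ion
})

test_that("covalent perception matches simple geometry and hand topology", {
  two_c <- function(d) make_frame(name = c("C1", "C2"), element = "C",
                                  resname = "UNK", resno = 1,
                                  x = c(0, d), y = 0, z = 0)
  expect_equal(nrow(perceive_covalent_bonds(two_c(1.5))$covalent), 1L)
  expect_equal(nrow(perceive_covalent_bonds(two_c(2.5))$covalent), 0L)

  # alanine heavy atoms: exactly N-CA, CA-C, C-O, CA-CB
  b <- perceive_covalent_bonds(alanine_frame())
  expect_equal(nrow(b$covalent), 4L)
  expect_setequal(paste(b$covalent$i, b$covalent$j),
                  c("1 2", "2 3", "3 4", "2 5"))

  bad <- make_frame(name = "X", element = "XX", resname = "UNK", resno = 1,
                    x = 0, y = 0, z = 0)
  expect_error(perceive_covalent_bonds(bad), "covalent radius")
})

test_that("bond perception is symmetric and rigid-motion invariant", {
  fr <- alanine_frame()
  b0 <- perceive_covalent_bonds(fr)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(fr[, c("x", "y", "z")]) %*% rot
  fr2 <- fr
  fr2$x <- xyz[, 1] + 5; fr2$y <- xyz[, 2] - 3; fr2$z <- xyz[, 3] + 1
  b1 <- perceive_covalent_bonds(fr2)
  expect_equal(b1$covalent[, c("i", "j")], b0$covalent[, c("i", "j")])
})

test_that("hydrogen bonds follow distance and angle criteria", {
  # explicit hydrogen, near-linear N-H...O at 2.8 A
  fr <- make_frame(name = c("N", "H", "O"), element = c("N", "H", "O"),
                   resname = c("ASN", "ASN", "SER"), resno = c(1, 1, 2),
                   x = c(0, 1.0, 2.8), y = 0, z = 0)
  b <- detect_hydrogen_bonds(fr, perceive_covalent_bonds(fr))
  expect_equal(nrow(b$hydrogen), 1L)
  expect_equal(b$hydrogen$r_h, 2.8)
  expect_equal(b$hydrogen$donor, 1L)

  # same donor at 4.0 A: outside the default cutoff
  fr4 <- fr; fr4$x[3] <- 4.0
  expect_equal(nrow(detect_hydrogen_bonds(
    fr4, perceive_covalent_bonds(fr4))$hydrogen), 0L)

  # bent geometry fails the angle criterion
  frb <- fr; frb$x[2] <- 0.2; frb$y[2] <- 1.0
  expect_equal(nrow(detect_hydrogen_bonds(
    frb, perceive_covalent_bonds(frb))$hydrogen), 0L)

  # hydrogen-free fixture: two constructed pairs at 2.9 and 3.2 A
  fr2 <- make_frame(name = c("N", "O", "N", "O"),
                    element = c("N", "O", "N", "O"),
                    resname = "SER", resno = 1:4,
                    x = c(0, 2.9, 10, 13.2), y = 0, z = 0)
  hb <- detect_hydrogen_bonds(fr2, perceive_covalent_bonds(fr2))$hydrogen
  expect_equal(nrow(hb), 2L)
  expect_equal(sort(hb$r_h), c(2.9, 3.2))
})

test_that("hydrogen-bond pairs are N/O/S heavy atoms, never covalently bonded", {
  toy <- make_toy_structure(list(type = "bridge"))
  fr <- toy$frame
  b <- detect_hydrogen_bonds(fr, perceive_covalent_bonds(fr))
  nos <- fr$atom_index[fr$element %in% c("N", "O", "S")]
  cov_key <- paste(b$covalent$i, b$covalent$j)
  for (r in seq_len(nrow(b$hydrogen))) {
    d <- b$hydrogen$donor[r]; a <- b$hydrogen$acceptor[r]
    expect_true(all(c(d, a) %in% nos))
    expect_false(paste(min(d, a), max(d, a)) %in% cov_key)
    expect_gt(b$hydrogen$r_h[r], 0)
  }
})

test_that("pruning keeps selected residues without touching coordinates", {
  fr <- make_frame(
    name = "CA", element = "C",
    resname = c("HEM", "TRP", "PHE", "HEM"), resno = c(1, 2, 3, 4),
    x = c(0, 5, 5, 10), y = c(0, 0, 3, 0), z = 0
  )
  # identity
  all_res <- data.frame(resname = fr$resname, resno = fr$resno)
  expect_equal(prune_to_region(fr, residues = all_res)$atom_index, 1:4)
  # explicit list
  kept <- prune_to_region(fr, residues = data.frame(resname = "TRP", resno = 2),
                          donor = list(resname = "HEM", resno = 1),
                          acceptor = list(resname = "HEM", resno = 4))
  expect_setequal(kept$resno, c(1, 2, 4))
  expect_equal(kept$x, fr$x[fr$resno %in% c(1, 2, 4)])
  # axis selection, radius ~0: only residues on the donor-acceptor line;
  # cross-check against brute-force point-to-line distances
  ax <- prune_to_region(fr, donor = list(resname = "HEM", resno = 1),
                        acceptor = list(resname = "HEM", resno = 4),
                        radius = 1e-6)
  d_line <- abs(fr$y)  # the axis is the x-axis here
  expect_setequal(ax$resno, fr$resno[d_line <= 1e-6])
  expect_false(3 %in% ax$resno)
  expect_error(prune_to_region(fr, residues = data.frame(resname = "XXX",
                                                         resno = 99)),
               "empty")
})

test_that("porphyrin macrocycle resolves to its 24 standard atoms", {
  fr <- heme_frame()
  core <- porphyrin_core_atoms(fr, resno = 1)
  expect_length(core, 24L)
  expect_false(fr$atom_index[fr$name == "FE"] %in% core)
  expect_error(porphyrin_core_atoms(heme_frame(drop = "NB"), resno = 1),
               "missing macrocycle")
  expect_error(porphyrin_core_atoms(alanine_frame(), resno = 1),
               "not a recognized heme")
})
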