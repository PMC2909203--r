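# Coordinate model, PDB dialect I/O, superposition, torsions, and helix
# assignment.

test_that("PDB writer/reader round-trips coordinates at 3-decimal precision", {
  m <- makeBundle(2, 8, 3, packing_radius = 5.5, seed = 3)
  f <- tempfile(fileext = ".pdb")
  writePdbModel(m, f)
  m2 <- readPdbModel(f)
  expect_identical(m2@sequence, m@sequence)
  expect_identical(m2@atoms$atom, m@atoms$atom)
  expect_equal(coords(m2), round(coords(m), 3), ignore_attr = TRUE)
  # second write is byte-identical (fixed-column format is canonical)
  f2 <- tempfile(fileext = ".pdb")
  writePdbModel(m2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("minimal and coarse-grained PDB files parse as specified", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       3.100   1.500   0.500  1.00  0.00           O",
    "END"), f)
  m <- readPdbModel(f)
  expect_equal(nResidues(m), 1)
  expect_equal(nAtoms(m), 4)
  expect_identical(m@sequence, "G")
  # CA-only trace: accepted, flagged coarse-grained
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  ALA A   3       7.600   0.100   0.000  1.00  0.00           C",
    "END"), f)
  m <- readPdbModel(f)
  expect_true(isCoarseGrained(m))
  expect_equal(nResidues(m), 3)
})

test_that("PDB dialect violations are rejected with clear errors", {
  f <- tempfile(fileext = ".pdb")
  # missing CA
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "END"), f)
  expect_error(readPdbModel(f), "CA")
  # unknown residue
  writeLines(c(
    "ATOM      1  CA  XYZ A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  expect_error(readPdbModel(f), "residue type")
  # HETATM
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  O   HOH A   2       5.000   0.000   0.000  1.00  0.00           O",
    "END"), f)
  expect_error(readPdbModel(f), "HETATM")
  # multi-chain
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA B   2       5.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  expect_error(readPdbModel(f), "chain")
  expect_error(readPdbModel(tempfile()), "not found")
})

test_that("altloc handling keeps the highest-occupancy copy", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  ALA A   3       7.600   0.000   0.000  1.00  0.00           C",
    "END"), f)
  m <- readPdbModel(f)
  expect_equal(nAtoms(m), 3)
  expect_equal(m@atoms$x[1], 9.0)
})

test_that("atom serial overflow raises a plain error instead of wrapping", {
  m <- caModel(matrix(rnorm(9), 3, 3))
  expect_error(ConsensusFold:::formatAtomLines(m, serial_offset = 99998L),
               "overflow")
  expect_silent(ConsensusFold:::formatAtomLines(m, serial_offset = 99996L))
})

test_that("multi-model ensemble PDB round-trips", {
  b <- makeBundle(2, 8, 3, packing_radius = 5.5, seed = 1)
  ens <- perturbEnsemble(b, 1.0, 3, seed = 2)
  f <- tempfile(fileext = ".pdb")
  writeEnsemblePdb(ens, f)
  ens2 <- readEnsemblePdb(f)
  expect_equal(nModels(ens2), 3)
  expect_equal(coords(models(ens2)[[2]]),
               round(coords(models(ens)[[2]]), 3), ignore_attr = TRUE)
})

test_that("Kabsch superposition matches the quaternion oracle to 1e-9", {
  set.seed(11)
  for (k in 1:10) {
    A <- matrix(rnorm(30, sd = 5), 10, 3)
    B <- matrix(rnorm(30, sd = 5), 10, 3)
    fit <- kabschSuperimpose(A, B)
    expect_equal(fit$rmsd, quaternionRmsd(A, B), tolerance = 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    # symmetry
    expect_equal(fit$rmsd, kabschSuperimpose(B, A)$rmsd, tolerance = 1e-9)
  }
})

test_that("superposition RMSD is zero for rigid copies and invariant under rigid motion", {
  set.seed(4)
  A <- matrix(rnorm(45, sd = 6), 15, 3)
  R <- randomRotation()
  B <- A %*% t(R) + matrix(rep(c(3, -7, 2), each = 15), 15, 3)
  fit <- kabschSuperimpose(A, B)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(t(fit$rotation) %*% fit$rotation, diag(3), tolerance = 1e-9)
  # rmsd invariant when either input is rigidly moved
  C <- matrix(rnorm(45, sd = 6), 15, 3)
  r0 <- kabschSuperimpose(A, C)$rmsd
  expect_equal(kabschSuperimpose(A %*% t(R), C)$rmsd, r0, tolerance = 1e-9)
  expect_equal(kabschSuperimpose(A, C %*% t(R))$rmsd, r0, tolerance = 1e-9)
})

test_that("degenerate superposition inputs raise errors", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabschSuperimpose(line, line + 1), "collinear")
  expect_error(kabschSuperimpose(matrix(0, 4, 3), matrix(0, 5, 3)),
               "identical dimensions")
})

test_that("repeat superposition equivalences Calpha intervals", {
  set.seed(9)
  helix <- ConsensusFold:::modelFromTorsions(rep("A", 12), rep(-57, 12),
                                             rep(-47, 12))
  ha <- helix@atoms
  hb <- ha
  R <- randomRotation()
  xyz <- as.matrix(hb[, c("x", "y", "z")]) %*% t(R)
  hb$x <- xyz[, 1] + 20; hb$y <- xyz[, 2]; hb$z <- xyz[, 3]
  hb$resno <- hb$resno + 12L
  m <- proteinModel(rep("A", 24), rbind(ha, hb))
  out <- superimposeRepeats(m, c(1, 12), c(13, 24))
  expect_equal(out$rmsd, 0, tolerance = 1e-9)
  expect_equal(out$n_atoms, 12)
  expect_equal(superimposeRepeats(m, c(1, 5), c(1, 5))$rmsd, 0,
               tolerance = 1e-9)
  expect_error(superimposeRepeats(m, c(1, 5), c(10, 20)), "equal length")
})

test_that("1 A isotropic noise on a 30-residue repeat gives RMSD near 1", {
  set.seed(21)
  xa <- matrix(rnorm(90, sd = 6), 30, 3)
  # unit mean-squared displacement: sd 1/sqrt(3) per component
  xb <- xa + matrix(rnorm(90, sd = 1 / sqrt(3)), 30, 3)
  m <- caModel(rbind(xa, xb))
  out <- superimposeRepeats(m, c(1, 30), c(31, 60))
  expect_gt(out$rmsd, 0.8)
  expect_lt(out$rmsd, 1.6)
  expect_equal(out$n_atoms, 30)
})

test_that("backbone torsions recover construction values and flag termini", {
  n <- 14
  set.seed(2)
  phi <- runif(n, -170, 160)
  psi <- runif(n, -170, 160)
  m <- ConsensusFold:::modelFromTorsions(rep("A", n), phi, psi)
  tt <- backboneTorsions(m)
  expect_true(is.na(tt$phi[1]))
  expect_true(is.na(tt$psi[n]))
  expect_equal(tt$phi[-1], phi[-1], tolerance = 1e-8)
  expect_equal(tt$psi[-n], psi[-n], tolerance = 1e-8)
  # ideal helix and fully extended chain
  h <- ConsensusFold:::modelFromTorsions(rep("A", 10), rep(-57, 10),
                                         rep(-47, 10))
  th <- backboneTorsions(h)
  expect_true(all(abs(th$phi[-1] + 57) < 0.5))
  expect_true(all(abs(th$psi[-10] + 47) < 0.5))
  e <- ConsensusFold:::modelFromTorsions(rep("A", 8), rep(180, 8),
                                         rep(180, 8))
  te <- backboneTorsions(e)
  expect_true(all(abs(abs(te$phi[-1]) - 180) < 0.5))
})

test_that("a hand-placed dihedral of exactly +90 degrees is recovered", {
  atoms <- data.frame(
    atom = c("N", "CA", "C", "N", "CA", "C"),
    element = c("N", "C", "C", "N", "C", "C"),
    resno = c(1L, 1L, 1L, 2L, 2L, 2L),
    restype = "A",
    x = c(1, 0, 0, 0, 5, 6),
    y = c(0, 0, 1, 1, 5, 5),
    z = c(0, 0, 0, 1, 5, 5), stringsAsFactors = FALSE)
  m <- proteinModel(c("A", "A"), atoms)
  tt <- backboneTorsions(m)
  expect_equal(tt$psi[1], 90, tolerance = 1e-6)
})

test_that("helix fraction follows the torsion-window and min-run rule", {
  h <- ConsensusFold:::modelFromTorsions(rep("A", 20), rep(-57, 20),
                                         rep(-47, 20))
  expect_equal(helixFraction(h), 18 / 20)
  e <- ConsensusFold:::modelFromTorsions(rep("A", 20), rep(180, 20),
                                         rep(180, 20))
  expect_equal(helixFraction(e), 0)
  # 30-residue helix + 10-residue extended tail, transition at psi_30
  phi <- c(rep(-57, 30), rep(180, 10))
  psi <- c(rep(-47, 29), rep(180, 11))
  m <- ConsensusFold:::modelFromTorsions(rep("A", 40), phi, psi)
  expect_equal(helixFraction(m), 28 / 40)
  # adding one qualifying residue never decreases the numerator
  phi2 <- c(rep(-57, 31), rep(180, 9))
  psi2 <- c(rep(-47, 30), rep(180, 10))
  m2 <- ConsensusFold:::modelFromTorsions(rep("A", 40), phi2, psi2)
  expect_gte(helixFraction(m2) * 40, helixFraction(m) * 40)
})

test_that("ProteinModel validity enforces the structural invariants", {
  expect_error(caModel(matrix(c(0, 0, NA), 1, 3)), "finite")
  at <- data.frame(atom = "N", element = "N", resno = 1L, restype = "A",
                   x = 0, y = 0, z = 0)
  expect_error(proteinModel("A", at), "CA")
  expect_error(proteinModel("B", data.frame(atom = "CA", element = "C",
                                            resno = 1L, restype = "B",
                                            x = 0, y = 0, z = 0)),
               "non-canonical")
})
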