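# RAPDF training/scoring and the three auxiliary decoy-filter terms.

test_that("log-odds arithmetic matches hand-computed Bayesian values", {
  # pair AB counts (3,1), pair CD counts (1,3): marginal (4,4), no smoothing
  counts <- rbind(AB = c(3L, 1L), CD = c(1L, 3L))
  lo <- ConsensusFold:::rapdfLogOdds(counts, pseudocount = 0)
  expect_equal(unname(lo["AB", 1]), -log(0.75 / 0.5), tolerance = 1e-12)
  expect_equal(unname(lo["AB", 2]), -log(0.25 / 0.5), tolerance = 1e-12)
  # identical distributions for every pair: all log-odds exactly zero
  counts2 <- rbind(a = c(5L, 2L, 3L), b = c(5L, 2L, 3L), c = c(5L, 2L, 3L))
  expect_equal(max(abs(ConsensusFold:::rapdfLogOdds(counts2, 1))), 0,
               tolerance = 1e-12)
})

test_that("training accumulates exactly the qualifying atom pairs", {
  tr <- makeRapdfTraining(5, seed = 4)[1:2]
  tab <- trainRapdf(tr)
  # oracle: count pairs with residue separation >= 3 and d in [3, 20)
  n_expected <- 0
  for (m in tr) {
    a <- m@atoms
    xyz <- coords(m)
    for (i in seq_len(nrow(a) - 1)) {
      d <- sqrt(colSums((t(xyz[(i + 1):nrow(a), , drop = FALSE]) -
                         xyz[i, ])^2))
      sep <- abs(a$resno[(i + 1):nrow(a)] - a$resno[i])
      n_expected <- n_expected + sum(sep >= 3 & d >= 3 & d < 20)
    }
  }
  expect_equal(sum(tab@counts), n_expected)
  expect_true(validObject(tab))
  expect_error(trainRapdf(list()), "empty")
})

test_that("scoring follows the summed log-odds contract", {
  flat <- flatRapdfTable()
  b <- makeBundle(2, 14, 4, packing_radius = 5.5, seed = 1)
  sc <- scoreModel(b, flat)
  expect_equal(sc$rapdf_raw, 0)
  expect_equal(sc$rapdf_normalized, 0)
  expect_gt(sc$n_contacts, 0)
  # single qualifying pair in a bin scored -2 -> raw -2, normalized -200
  xyz <- rbind(c(0, 0, 0), c(0, 50, 0), c(25, 50, 0), c(50, 50, 0),
               c(5.5, 0, 0))
  m <- caModel(xyz)
  tab <- flatRapdfTable()
  bin <- floor((5.5 - tab@breaks[1]) / (tab@breaks[2] - tab@breaks[1])) + 1
  tab@logOdds[match("CA|CA", tab@pairs), bin] <- -2
  sc <- scoreModel(m, tab)
  expect_equal(sc$n_contacts, 1)
  expect_equal(sc$rapdf_raw, -2)
  expect_equal(sc$rapdf_normalized, -200)
})

test_that("near-native models outscore far decoys under a trained table", {
  tab <- trainRapdf(makeRapdfTraining(20, seed = 7))
  wins <- 0
  n_trials <- 30
  for (k in seq_len(n_trials)) {
    b <- makeBundle(3, 12, 4, packing_radius = 6.5, seed = 100 + k)
    far <- models(perturbEnsemble(b, 5, 2, seed = k))[[1]]
    s_native <- scoreModel(b, tab)$rapdf_normalized
    s_far <- scoreModel(far, tab)$rapdf_normalized
    if (s_native < s_far) wins <- wins + 1
  }
  expect_gte(wins, ceiling(0.95 * n_trials))
})

test_that("topology flag applies the strict -55 threshold", {
  expect_true(flagCorrectTopology(-60))
  expect_false(flagCorrectTopology(-55))
  expect_false(flagCorrectTopology(0))
  expect_error(flagCorrectTopology(NA_real_), "undefined")
})

test_that("soft-sphere clash term matches arithmetic and the brute oracle", {
  # two carbons at 2.06 A with one residue between them: penalty exactly 1
  m <- caModel(rbind(c(0, 0, 0), c(0, 100, 0), c(2.06, 0, 0)))
  expect_equal(vdwTerm(m), 1.0, tolerance = 1e-9)
  # separated atoms contribute nothing
  m0 <- caModel(rbind(c(0, 0, 0), c(0, 100, 0), c(8, 0, 0)))
  expect_equal(vdwTerm(m0), 0)
  # 50-atom random fixture: cell-list implementation vs double loop
  set.seed(31)
  for (k in 1:3) {
    xyz <- matrix(rnorm(150, sd = 4), 50, 3)
    resno <- sort(rep(1:20, length.out = 50))
    m <- proteinModel(rep("A", 20), data.frame(
      atom = ifelse(duplicated(resno), "CB", "CA"), element = "C",
      resno = resno, restype = "A",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
    radii <- rep(ConsensusFold:::VDW_RADII[["C"]], 50)
    expect_equal(vdwTerm(m), vdwOracle(coords(m), radii, m@atoms$resno),
                 tolerance = 1e-9)
  }
})

test_that("compactness ratio reflects hydrophobic burial", {
  # all residues hydrophobic with CB on top of CA: ratio is exactly 1
  xyz <- matrix(rnorm(30, sd = 5), 10, 3)
  at <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(atom = c("CA", "CB"), element = "C", resno = i,
               restype = "L", x = xyz[i, 1], y = xyz[i, 2], z = xyz[i, 3])
  }))
  expect_equal(compactnessTerm(proteinModel(rep("L", 10), at)), 1,
               tolerance = 1e-9)
  # buried hydrophobic core vs inside-out arrangement
  mk <- function(hyd_r, pol_r) {
    ang <- seq(0, 2 * pi, length.out = 11)[1:10]
    rows <- lapply(1:10, function(i) {
      r <- if (i <= 5) hyd_r else pol_r
      rt <- if (i <= 5) "L" else "S"
      data.frame(atom = c("CA", "CB"), element = "C", resno = i,
                 restype = rt,
                 x = r * cos(ang[i]), y = r * sin(ang[i]),
                 z = c(0, 0.5))
    })
    proteinModel(c(rep("L", 5), rep("S", 5)), do.call(rbind, rows))
  }
  native_like <- mk(0.5, 10)
  inside_out <- mk(10, 0.5)
  expect_lt(compactnessTerm(native_like), 0.5)
  expect_gt(compactnessTerm(inside_out), compactnessTerm(native_like))
  # no hydrophobic residues: undefined flag
  m <- caModel(matrix(rnorm(9), 3, 3), restype = rep("S", 3))
  expect_true(is.na(compactnessTerm(m)))
})

test_that("screened electrostatics follows the 1/(4 d^2) form", {
  mk2 <- function(rt1, rt2, d) {
    at <- rbind(
      data.frame(atom = c("CA", "CB"), element = "C", resno = 1,
                 restype = rt1, x = c(0, 0), y = 0, z = 0),
      data.frame(atom = c("CA", "CB"), element = "C", resno = 2,
                 restype = rt2, x = c(d, d), y = 0, z = 0))
    proteinModel(c(rt1, rt2), at)
  }
  expect_equal(electrostaticsTerm(mk2("K", "E", 5)), -1 / 100,
               tolerance = 1e-12)
  expect_equal(electrostaticsTerm(mk2("A", "S", 5)), 0)
  expect_lt(electrostaticsTerm(mk2("K", "E", 5)),
            electrostaticsTerm(mk2("K", "K", 5)))
})

test_that("all four terms are invariant under rigid transforms", {
  tab <- trainRapdf(makeRapdfTraining(6, seed = 5))
  b <- makeBundle(2, 12, 4, packing_radius = 5.5, seed = 9)
  set.seed(77)
  b2 <- transformModel(b, randomRotation(), c(11, -4, 7))
  s1 <- scoreModel(b, tab)
  s2 <- scoreModel(b2, tab)
  expect_equal(s1$rapdf_raw, s2$rapdf_raw, tolerance = 1e-9)
  expect_equal(s1$vdw_energy, s2$vdw_energy, tolerance = 1e-9)
  expect_equal(s1$compactness, s2$compactness, tolerance = 1e-9)
  expect_equal(s1$electrostatics, s2$electrostatics, tolerance = 1e-9)
})

test_that("RAPDF tables round-trip through the text format bit-exactly", {
  tab <- trainRapdf(makeRapdfTraining(6, seed = 2))
  f <- tempfile(fileext = ".tsv")
  writeRapdfTable(tab, f)
  tab2 <- readRapdfTable(f)
  expect_identical(unname(tab@logOdds), unname(tab2@logOdds))
  expect_identical(unname(tab@counts), unname(tab2@counts))
  expect_identical(tab@breaks, tab2@breaks)
  expect_identical(tab@pseudocount, tab2@pseudocount)
  expect_identical(tab@meta$n_structures, tab2@meta$n_structures)
})
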