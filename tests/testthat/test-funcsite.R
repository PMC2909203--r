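# Sequence- and surface-level functional-site analyses.

test_that("hydrophobic moment follows the Eisenberg vector sum", {
  # 18 residues x 100 degrees = 5 full turns: identical vectors cancel
  expect_lt(hydrophobicMoment(strrep("L", 18)), 1e-12)
  # independent complex-sum oracle on random windows
  set.seed(6)
  for (k in 1:10) {
    w <- sample(names(ConsensusFold:::EISENBERG), 12, replace = TRUE)
    h <- unname(ConsensusFold:::EISENBERG[w])
    th <- (seq_along(w) - 1) * 100 * pi / 180
    oracle <- sqrt(sum(h * cos(th))^2 + sum(h * sin(th))^2) / length(w)
    expect_equal(hydrophobicMoment(w), oracle, tolerance = 1e-6)
  }
  # shifting the scale by a constant changes nothing when the unit
  # vectors cancel (18-mer at 100 degrees)
  set.seed(7)
  w <- sample(names(ConsensusFold:::EISENBERG), 18, replace = TRUE)
  shifted <- ConsensusFold:::EISENBERG + 3.7
  expect_equal(hydrophobicMoment(w),
               hydrophobicMoment(w, scale = shifted), tolerance = 1e-9)
  # reversal combined with angle negation leaves the moment unchanged
  expect_equal(hydrophobicMoment(w, angle = 100),
               hydrophobicMoment(rev(w), angle = -100), tolerance = 1e-9)
  expect_error(hydrophobicMoment("LLL"), "length >= 6")
  expect_error(hydrophobicMoment(c("L", "L", "L", "L", "L", "X")),
               "non-canonical")
})

test_that("planted amphipathic helices are detected, homopolymers are not", {
  pos <- 20 + c(0, 3, 10, 14, 17)
  s <- makeAmphipathicSequence(60, 20, 18, basic_positions = pos, seed = 3)
  hel <- findAmphipathicHelices(s)
  expect_gt(nrow(hel), 0)
  # at least 80% of the planted window covered by one annotation
  overlap <- max(vapply(seq_len(nrow(hel)), function(i) {
    length(intersect(hel$start[i]:hel$end[i], 20:37))
  }, numeric(1)))
  expect_gte(overlap, 0.8 * 18)
  expect_equal(nrow(findAmphipathicHelices(strrep("A", 40))), 0)
  expect_error(findAmphipathicHelices("LLLLL"), "shorter")
})

test_that("shuffling the planted sequence destroys the planted signal", {
  # the planted signal is an amphipathic helix carrying a five-lysine
  # cluster; a shuffle only rarely reassembles that signature (isolated
  # high-moment windows do recur, because the composition stays
  # amphipathic-capable)
  s <- makeAmphipathicSequence(60, 20, 18,
                               basic_positions = 20 + c(0, 3, 10, 14, 17),
                               seed = 3)
  v <- strsplit(s, "")[[1]]
  set.seed(41)
  hits <- 0
  n_shuffles <- 200
  for (k in seq_len(n_shuffles)) {
    sv <- sample(v)
    hel <- findAmphipathicHelices(sv)
    if (nrow(hel) == 0) next
    if (nrow(findBasicClusters(sv, hel, min_basic = 5)) > 0) hits <- hits + 1
  }
  expect_lt(hits / n_shuffles, 0.05)
})

test_that("basic clusters anchored to helices follow the span rules", {
  pos <- 20 + c(0, 3, 10, 14, 17)
  s <- makeAmphipathicSequence(60, 20, 18, basic_positions = pos, seed = 3)
  hel <- findAmphipathicHelices(s)
  bc <- findBasicClusters(s, hel)
  expect_equal(nrow(bc), 1)
  expect_equal(bc$n_basic, 5)
  expect_equal(bc$span, 18)  # the alpha5-style 18-residue span
  expect_equal(bc$positions, paste(pos, collapse = ","))
  # no basic residues at all
  s0 <- makeAmphipathicSequence(60, 20, 18, seed = 3)
  hel0 <- findAmphipathicHelices(s0)
  bc0 <- findBasicClusters(s0, hel0)
  if (nrow(hel0) > 0) expect_equal(nrow(bc0), 0)
  # threshold semantics with exactly three lysines
  pos3 <- 20 + c(0, 4, 9)
  s3 <- makeAmphipathicSequence(60, 20, 18, basic_positions = pos3, seed = 5)
  hel3 <- findAmphipathicHelices(s3)
  expect_equal(nrow(findBasicClusters(s3, hel3, min_basic = 4)), 0)
  expect_equal(nrow(findBasicClusters(s3, hel3, min_basic = 3)), 1)
})

test_that("solvent accessibility matches closed forms and symmetry", {
  m1 <- proteinModel("A", data.frame(atom = "CA", element = "C", resno = 1L,
                                     restype = "A", x = 0, y = 0, z = 0))
  a1 <- sasa(m1)
  expect_equal(a1, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.02 * a1)
  # an atom enclosed by a shell is fully buried
  sp <- ConsensusFold:::spherePoints(60) * 2.2
  at <- rbind(data.frame(atom = "CA", element = "C", resno = 1L,
                         restype = "A", x = 0, y = 0, z = 0),
              data.frame(atom = "CB", element = "C", resno = 1L,
                         restype = "A", x = sp[, 1], y = sp[, 2],
                         z = sp[, 3]))
  m2 <- proteinModel("A", at)
  expect_equal(sasa(m2)[1], 0)
  # two identical atoms: equal areas by symmetry
  m3 <- proteinModel(c("A", "A", "A", "A"), data.frame(
    atom = "CA", element = "C", resno = 1:4, restype = "A",
    x = c(0, 2.5, 100, 102.5), y = 0, z = 0))
  a3 <- sasa(m3)
  expect_equal(a3[1], a3[2], tolerance = 0.01)  # quadrature-level agreement
  # additivity: identical far-separated copies have identical total area
  expect_equal(sum(a3[1:2]), sum(a3[3:4]), tolerance = 1e-6)
})

test_that("desolvation patches prefer apolar surface and skip buried atoms", {
  # tight sphere of apolar residues with a charged polar cap; the centre
  # atom is fully enclosed by the shell
  sp <- ConsensusFold:::spherePoints(50) * 5
  cap <- sp[, 3] > 4
  restype <- ifelse(cap, "K", "L")
  at <- data.frame(atom = "CA", element = "C", resno = seq_len(50),
                   restype = restype, x = sp[, 1], y = sp[, 2], z = sp[, 3])
  at <- rbind(at, data.frame(atom = "CA", element = "C", resno = 51L,
                             restype = "L", x = 0, y = 0, z = 0))
  m <- proteinModel(c(restype, "L"), at)
  patches <- odaPatches(m, patch_radius = 5)
  expect_gt(nrow(patches), 0)
  expect_lte(nrow(patches), 51)
  # the buried central atom appears in no patch
  members <- unlist(strsplit(patches$members, ","))
  expect_false("51" %in% members)
  # the best-ranked patch's center is not in the charged cap
  cap_idx <- which(cap)
  expect_false(patches$center[1] %in% cap_idx)
  # ranks ascend with score
  expect_true(all(diff(patches$oda_score) >= 0))
  # rigid-transform invariance at quadrature tolerance: the favored
  # (apolar) region and the best score are stable under rotation
  set.seed(55)
  m2 <- transformModel(m, randomRotation(), c(4, -9, 1))
  p2 <- odaPatches(m2, patch_radius = 5)
  expect_false(p2$center[1] %in% cap_idx)
  expect_equal(p2$oda_score[1], patches$oda_score[1],
               tolerance = 0.05 * abs(patches$oda_score[1]))
  expect_lte(abs(nrow(p2) - nrow(patches)), 2)
})

test_that("residue composition counts exactly", {
  rc <- residueComposition("KEKE")
  expect_equal(unname(rc["K"]), 2)
  expect_equal(unname(rc["E"]), 2)
  expect_equal(sum(rc), 4)
  set.seed(17)
  s <- paste(sample(ConsensusFold:::AA20, 120, replace = TRUE),
             collapse = "")
  expect_equal(sum(residueComposition(s)), 120)
  expect_error(residueComposition("ABZ"), "non-canonical")
})

test_that("sequence masses follow condensation arithmetic and doubling", {
  expect_equal(estimateMw("G"), 75.07, tolerance = 0.01)
  expect_equal(estimateMw("GG"), 132.12, tolerance = 0.01)
  set.seed(23)
  s1 <- paste(sample(ConsensusFold:::AA20, 30, replace = TRUE), collapse = "")
  s2 <- paste(sample(ConsensusFold:::AA20, 25, replace = TRUE), collapse = "")
  expect_identical(estimateMw(s1, 2), 2 * estimateMw(s1, 1))
  expect_equal(estimateMw(paste0(s1, s2)),
               estimateMw(s1) + estimateMw(s2) - 18.02, tolerance = 1e-9)
})

test_that("heptad register lands hydrophobics on the a/d positions", {
  unit <- c("L", "Q", "Q", "L", "Q", "Q", "Q")  # a and d hydrophobic
  s <- paste(rep(unit, 5), collapse = "")
  hel <- data.frame(start = 1, end = 28)
  hr <- detectHeptadRepeats(s, hel)
  expect_equal(hr$frame, 0L)
  expect_gt(hr$margin, 1)
  # frame choice is invariant to prepending a full heptad
  s2 <- paste0(paste(unit, collapse = ""), s)
  hr2 <- detectHeptadRepeats(s2, data.frame(start = 8, end = 35))
  expect_equal(hr2$frame, hr$frame)
  # a random helix has a much smaller margin than the ideal pattern
  set.seed(61)
  sr <- paste(sample(ConsensusFold:::AA20, 28, replace = TRUE), collapse = "")
  hrr <- detectHeptadRepeats(sr, data.frame(start = 1, end = 28))
  expect_lt(hrr$margin, hr$margin)
  # an ideal-pattern margin beats the 95th percentile of its shuffles
  vv <- strsplit(s, "")[[1]]
  null <- replicate(200, {
    detectHeptadRepeats(paste(sample(vv), collapse = ""),
                        data.frame(start = 1, end = 28))$margin
  })
  expect_gt(hr$margin, quantile(null, 0.95))
  # short helices get an undefined register
  expect_true(is.na(detectHeptadRepeats(s, data.frame(start = 1,
                                                      end = 10))$frame))
})
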