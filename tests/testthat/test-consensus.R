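# Consensus distance extraction, RAPDF weighting, and constraint-set
# compilation.

# ensemble whose only qualifying pair (residues 1-4) has controlled
# per-model distances; residues 2-3 are fixed far away
pairEnsemble <- function(dists) {
  caEnsemble(lapply(dists, function(d) {
    rbind(c(0, 0, 0), c(0, 60, 0), c(30, 60, 0), c(d, 0, 0))
  }))
}

test_that("window extraction reproduces the worked examples", {
  # five identical models: degenerate window, unanimous support
  cons <- extractConsensus(pairEnsemble(rep(8, 5)), 0.5, 4)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$distance, 8)
  expect_equal(cons$support, 5)
  # 4 of 5 within the window: mean of the supporting values
  cons <- extractConsensus(pairEnsemble(c(8.0, 8.1, 8.2, 8.3, 9.5)), 0.5, 4)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$distance, 8.15)
  expect_equal(cons$support, 4)
  # maximal window occupancy 2: no constraint
  cons <- extractConsensus(pairEnsemble(c(8.0, 8.4, 8.9, 9.3, 9.8)), 0.5, 4)
  expect_equal(nrow(cons), 0)
  expect_error(extractConsensus(pairEnsemble(rep(8, 3)), 0.5, 4),
               "smaller than min_support")
})

test_that("extraction agrees exactly with the brute-force window oracle", {
  for (sd_ in 1:3) {
    set.seed(sd_)
    n_res <- 10
    M <- 5 + sd_
    base <- matrix(rnorm(n_res * 3, sd = 4), n_res, 3)
    ens <- caEnsemble(lapply(seq_len(M), function(m) {
      base + matrix(rnorm(n_res * 3, sd = 0.3), n_res, 3)
    }))
    got <- extractConsensus(ens, 0.5, 4)
    want <- consensusOracle(ens, 0.5, 4)
    ord <- function(k) k[order(k$res_i, k$res_j), ]
    got <- ord(got); want <- ord(want)
    expect_equal(got$res_i, want$res_i)
    expect_equal(got$res_j, want$res_j)
    expect_equal(got$support, want$support)
    expect_equal(got$distance, want$distance, tolerance = 1e-9)
  }
})

test_that("support is monotone in window width and min_support", {
  set.seed(5)
  base <- matrix(rnorm(24, sd = 4), 8, 3)
  ens <- caEnsemble(lapply(1:5, function(m) {
    base + matrix(rnorm(24, sd = 0.4), 8, 3)
  }))
  narrow <- extractConsensus(ens, 0.25, 2)
  wide <- extractConsensus(ens, 1.0, 2)
  key <- function(k) paste(k$res_i, k$res_j)
  shared <- intersect(key(narrow), key(wide))
  expect_true(all(wide$support[match(shared, key(wide))] >=
                  narrow$support[match(shared, key(narrow))]))
  expect_gte(nrow(extractConsensus(ens, 0.5, 3)),
             nrow(extractConsensus(ens, 0.5, 4)))
})

test_that("consensus of identical copies reproduces the distance matrix", {
  b <- makeBundle(2, 10, 4, packing_radius = 5.5, seed = 3)
  ens <- modelEnsemble(rep(list(b), 5))
  cons <- extractConsensus(ens, 0.5, 4)
  a <- b@atoms
  key <- paste(a$resno, a$atom)
  xyz <- coords(b)
  d_true <- sqrt(rowSums((xyz[match(paste(cons$res_i, cons$atom_i), key), ] -
                          xyz[match(paste(cons$res_j, cons$atom_j), key),
                              ])^2))
  expect_equal(cons$distance, d_true, tolerance = 1e-12)
  expect_true(all(cons$support == 5))
})

test_that("weights combine support factor and RAPDF rank factor", {
  flat <- flatRapdfTable()
  k <- data.frame(res_i = c(1L, 2L), atom_i = "CA", res_j = c(5L, 6L),
                  atom_j = "CA", distance = c(8, 9),
                  support = c(5L, 4L), stringsAsFactors = FALSE)
  w <- attachRapdfWeights(k, flat, ensemble_size = 5,
                          restypes = rep("A", 6))
  # equal scores: equal rank factors, so weights in the 1.0 : 0.8 ratio
  expect_equal(w$weight[2] / w$weight[1], 0.8, tolerance = 1e-12)
  w1 <- attachRapdfWeights(k[1, ], flat, 5, rep("A", 6))
  expect_equal(w1$weight, 1.0)
  # weights always in (0, 1]
  set.seed(8)
  tab <- trainRapdf(makeRapdfTraining(6, seed = 3))
  b <- makeBundle(2, 12, 4, packing_radius = 5.5, seed = 2)
  ens <- perturbEnsemble(b, 1.5, 5, seed = 4)
  cons <- extractConsensus(ens)
  w2 <- attachRapdfWeights(cons, tab, 5, ens@sequence)
  expect_true(all(w2$weight > 0 & w2$weight <= 1))
})

test_that("constraint-set compilation respects cutoffs and tie-breaks", {
  k <- data.frame(res_i = c(1L, 1L, 1L), atom_i = "CA",
                  res_j = c(5L, 6L, 7L), atom_j = "CA",
                  distance = c(11, 15, 19), support = 5L,
                  rapdf = -1, weight = 0.9, stringsAsFactors = FALSE)
  sets <- compileConstraintSets(k)
  expect_equal(vapply(sets, function(s) nrow(constraints(s)), integer(1)),
               c(1L, 2L, 3L))
  expect_true(all(vapply(sets, validObject, logical(1))))
  # per residue pair, the most favorable (lowest) RAPDF score is kept
  k2 <- data.frame(res_i = 1L, atom_i = c("CA", "CB"), res_j = 5L,
                   atom_j = c("CA", "CB"), distance = c(8, 9),
                   support = 5L, rapdf = c(-1.0, -2.5), weight = 0.9,
                   stringsAsFactors = FALSE)
  sets2 <- compileConstraintSets(k2, cutoffs = 12)
  expect_equal(constraints(sets2[[1]])$atom_i, "CB")
  # the "largest" interpretation is exposed as a switch
  sets3 <- compileConstraintSets(k2, cutoffs = 12,
                                 score_direction = "largest")
  expect_equal(constraints(sets3[[1]])$atom_i, "CA")
  # empty input: three empty sets
  sets4 <- compileConstraintSets(k2[0, ])
  expect_true(all(vapply(sets4, function(s) nrow(constraints(s)) == 0,
                         logical(1))))
  # sizes monotone in cutoff on a random constraint list
  set.seed(10)
  kr <- data.frame(res_i = 1:40, atom_i = "CA", res_j = 5:44,
                   atom_j = "CA", distance = runif(40, 4, 25),
                   support = 4L, rapdf = rnorm(40), weight = 0.5,
                   stringsAsFactors = FALSE)
  sizes <- vapply(compileConstraintSets(kr),
                  function(s) nrow(constraints(s)), integer(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("constraint sets round-trip as tab-delimited and CYANA limits", {
  tab <- trainRapdf(makeRapdfTraining(6, seed = 3))
  b <- makeBundle(2, 12, 4, packing_radius = 5.5, seed = 2)
  ens <- perturbEnsemble(b, 1.5, 5, seed = 4)
  w <- attachRapdfWeights(extractConsensus(ens), tab, 5, ens@sequence)
  set1 <- compileConstraintSets(w, cutoffs = 16, source = "toy")[[1]]
  f <- tempfile(fileext = ".tsv")
  writeConstraintSet(set1, f)
  set2 <- readConstraintSet(f)
  expect_identical(constraints(set1), constraints(set2))
  expect_identical(set1@cutoff, set2@cutoff)
  stem <- tempfile()
  writeCyanaLimits(set1, stem, ens@sequence)
  upl <- readLines(paste0(stem, ".upl"))
  lol <- readLines(paste0(stem, ".lol"))
  expect_length(upl, nrow(constraints(set1)))
  expect_length(lol, nrow(constraints(set1)))
  # upper limit = distance + window/2 to the printed precision
  first_upl <- as.numeric(sub(".* ", "", upl[1]))
  expect_equal(first_upl, constraints(set1)$distance[1] + 0.25,
               tolerance = 0.006)
})
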