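# Synthetic-data generators: toy helical-bundle folds, perturbed "server
# model" ensembles, miniature RAPDF training corpora, and sequences with a
# planted amphipathic lysine-cluster helix. Every generator is a pure
# function of its arguments plus seed, so the whole pipeline is testable
# with no external downloads.

# Evaluate code under a fixed seed without disturbing the caller's RNG.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

# Rotation taking unit vector u onto unit vector v (Rodrigues).
rotationBetween <- function(u, v) {
  u <- u / sqrt(sum(u^2))
  v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees: rotate about any axis orthogonal to u
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- a - sum(a * u) * u
    w <- w / sqrt(sum(w^2))
    return(2 * outer(w, w) - diag(3))
  }
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  K <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K / (1 + c_)
}

HELIX_CORE_AA <- c("L", "I", "V", "F")
HELIX_SURF_AA <- c("E", "K", "Q", "A", "S", "T", "D", "R")
LOOP_AA <- c("G", "S", "T", "N", "D")

# Ideal helical segment of m residues for a given sub-sequence, as an atom
# table (NeRF layout), centred with its axis along +z and N->C towards +z.
idealHelixSegment <- function(subseq) {
  m <- length(subseq)
  has_cb <- subseq != "G"
  xyz <- .nerf_chain(rep(HELIX_PHI, m), rep(HELIX_PSI, m), has_cb)
  tab <- nerfAtomTable(subseq)
  ca <- xyz[tab$atom == "CA", , drop = FALSE]
  ctr <- colMeans(ca)
  axis <- prcomp(ca)$rotation[, 1]
  if (sum(axis * (ca[m, ] - ca[1, ])) < 0) axis <- -axis
  R <- rotationBetween(axis, c(0, 0, 1))
  xyz <- sweep(xyz, 2, ctr) %*% t(R)
  tab$x <- xyz[, 1]; tab$y <- xyz[, 2]; tab$z <- xyz[, 3]
  tab
}

applyRigid <- function(tab, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(tab[, c("x", "y", "z")]) %*% t(R)
  tab$x <- xyz[, 1] + t[1]; tab$y <- xyz[, 2] + t[2]; tab$z <- xyz[, 3] + t[3]
  tab
}

#' Build a toy helical-bundle model
#'
#' Constructs an idealized backbone+CB bundle: \code{n_helices} ideal
#' alpha-helices (phi = -57, psi = -47 degrees) with axes placed on a circle
#' of \code{packing_radius}, alternately inverted when \code{antiparallel},
#' joined by extended loop connectors. The sequence follows a heptad-style
#' pattern (hydrophobic a/d positions facing the bundle core is emulated
#' statistically, not enforced geometrically) and is drawn deterministically
#' from \code{seed}. This is the topology class of a six-helix bundle formed
#' by two three-helix hairpins.
#'
#' @param n_helices number of helices (>= 1).
#' @param residues_per_helix residues per helix (>= 6).
#' @param loop_length residues per inter-helix connector.
#' @param packing_radius circle radius in Angstrom for helix axes.
#' @param antiparallel alternate helix directions?
#' @param seed integer seed; same seed, same model.
#' @return A \linkS4class{ProteinModel} with
#'   \code{n_helices * residues_per_helix + (n_helices - 1) * loop_length}
#'   residues.
#' @export
makeBundle <- function(n_helices = 6, residues_per_helix = 20,
                       loop_length = 5, packing_radius = 9,
                       antiparallel = TRUE, seed = 1) {
  stopifnot(n_helices >= 1, residues_per_helix >= 6, loop_length >= 0)
  withSeed(seed, {
    helix_seqs <- lapply(seq_len(n_helices), function(k) {
      pos <- seq_len(residues_per_helix)
      hept <- (pos - 1) %% 7
      ifelse(hept %in% c(0, 3),
             sample(HELIX_CORE_AA, residues_per_helix, replace = TRUE),
             sample(HELIX_SURF_AA, residues_per_helix, replace = TRUE))[pos]
    })
    loop_seqs <- if (n_helices > 1 && loop_length > 0) {
      lapply(seq_len(n_helices - 1), function(k) {
        sample(LOOP_AA, loop_length, replace = TRUE)
      })
    } else rep(list(character(0)), max(n_helices - 1, 0))

    # target layout: ideal helices on a circle (CA positions only); the
    # actual chain is then built from torsions alone (ideal covalent
    # geometry throughout), with loop torsions solved numerically so each
    # following helix lands on its target. The resulting model is exactly
    # reproducible from its own torsions, i.e. it lives on the same
    # idealized-geometry manifold the model builder searches.
    target_ca <- vector("list", n_helices)
    for (k in seq_len(n_helices)) {
      tab <- idealHelixSegment(helix_seqs[[k]])
      if (antiparallel && k %% 2 == 0) {
        tab <- applyRigid(tab, R = diag(c(1, -1, -1)))  # flip about x-axis
      }
      theta <- 2 * pi * (k - 1) / max(n_helices, 2)
      tab <- applyRigid(tab, t = c(packing_radius * cos(theta),
                                   packing_radius * sin(theta), 0))
      target_ca[[k]] <- as.matrix(tab[tab$atom == "CA", c("x", "y", "z")])
    }
    sequence <- character(0)
    hel_id <- integer(0)
    for (k in seq_len(n_helices)) {
      sequence <- c(sequence, helix_seqs[[k]])
      hel_id <- c(hel_id, rep(k, residues_per_helix))
      if (k < n_helices && loop_length > 0) {
        sequence <- c(sequence, loop_seqs[[k]])
        hel_id <- c(hel_id, rep(0L, loop_length))
      }
    }
    n <- length(sequence)
    has_cb <- sequence != "G"
    # CA atom row per residue within the NeRF layout
    per_res <- ifelse(has_cb, 5L, 4L)
    ca_row <- cumsum(c(0L, per_res[-n])) + 2L
    phi <- rep(HELIX_PHI, n)
    psi <- rep(HELIX_PSI, n)
    h_first <- function(k) (k - 1L) * (residues_per_helix + loop_length) + 1L
    # express all targets in the frame of the built first helix
    built1 <- .nerf_chain(phi[1:residues_per_helix], psi[1:residues_per_helix],
                          has_cb[1:residues_per_helix])
    ca1 <- built1[ca_row[1:residues_per_helix], , drop = FALSE]
    fit1 <- kabschSuperimpose(ca1, target_ca[[1]])
    target_ca <- lapply(target_ca, function(m) {
      sweep(m %*% t(fit1$rotation), 2, fit1$translation, "+")
    })
    # solve each connector: free torsions are psi of the helix end, phi/psi
    # of the loop residues and phi of the next helix start, fitted so the
    # first four CA atoms of the next helix land on their targets
    n_anchor <- 4L
    for (k in seq_len(n_helices - 1)) {
      hend <- h_first(k) + residues_per_helix - 1L
      nstart <- h_first(k + 1L)
      free_psi <- c(hend, seq(hend + 1L, length.out = loop_length))
      free_phi <- c(seq(hend + 1L, length.out = loop_length), nstart)
      pend <- nstart + n_anchor - 1L
      anchors <- target_ca[[k + 1L]][seq_len(n_anchor), , drop = FALSE]
      objective <- function(p) {
        psi[free_psi] <- p[seq_along(free_psi)]
        phi[free_phi] <- p[length(free_psi) + seq_along(free_phi)]
        xyz <- .nerf_chain(phi[1:pend], psi[1:pend], has_cb[1:pend])
        sum((xyz[ca_row[nstart:pend], , drop = FALSE] - anchors)^2)
      }
      inits <- list(c(150, 150), c(-60, -40), c(-100, 120), c(60, 60),
                    c(-140, 160), c(100, -100))
      best <- NULL
      for (ini in inits) {
        p0 <- c(rep(ini[1], length(free_psi)), rep(ini[2], length(free_phi)))
        fit <- stats::optim(p0, objective, method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-10))
        if (is.null(best) || fit$value < best$value) best <- fit
        if (sqrt(best$value / n_anchor) < 0.5) break
      }
      if (sqrt(best$value / n_anchor) > 2.0) {
        stop("loop_length cannot connect consecutive helices for this spec")
      }
      p <- best$par
      psi[free_psi] <- p[seq_along(free_psi)]
      phi[free_phi] <- p[length(free_psi) + seq_along(free_phi)]
    }
    phi <- ((phi + 180) %% 360) - 180
    psi <- ((psi + 180) %% 360) - 180
    model <- modelFromTorsions(sequence, phi, psi,
                               label = sprintf("bundle_h%d_r%d_s%d",
                                               n_helices, residues_per_helix,
                                               seed))
    # steric sanity: CA atoms of different helices must not interpenetrate
    ca <- caCoords(model)
    d <- as.matrix(stats::dist(ca))
    other <- outer(hel_id, hel_id, function(a, b) a > 0 & b > 0 & a != b)
    if (any(d[other] < 2.5)) {
      stop("packing_radius too small: steric overlap between helices")
    }
    model
  })
}

# Rotate the chain about the phi/psi axes of each residue by the given
# angles (degrees); exact torsion-space perturbation that preserves all
# covalent geometry, ideal or not.
pivotPerturb <- function(model, dphi, dpsi) {
  a <- model@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nResidues(model)
  idxN <- match(paste(seq_len(n), "N"), paste(a$resno, a$atom))
  idxCA <- match(paste(seq_len(n), "CA"), paste(a$resno, a$atom))
  idxC <- match(paste(seq_len(n), "C"), paste(a$resno, a$atom))
  idxO <- match(paste(seq_len(n), "O"), paste(a$resno, a$atom))
  rot_about <- function(xyz, rows, axis_a, axis_b, angle_deg) {
    u <- axis_b - axis_a
    u <- u / sqrt(sum(u^2))
    th <- angle_deg * pi / 180
    K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
                byrow = TRUE)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    xyz[rows, ] <- sweep(sweep(xyz[rows, , drop = FALSE], 2, axis_a) %*% t(R),
                         2, axis_a, "+")
    xyz
  }
  for (i in seq_len(n)) {
    if (dphi[i] != 0 && !is.na(idxN[i])) {
      # phi: rotate C/O/CB of residue i and all later residues
      rows <- c(setdiff(which(a$resno == i), c(idxN[i], idxCA[i])),
                which(a$resno > i))
      xyz <- rot_about(xyz, rows, xyz[idxN[i], ], xyz[idxCA[i], ], dphi[i])
    }
    if (dpsi[i] != 0 && !is.na(idxC[i])) {
      # psi: rotate O of residue i and all later residues
      rows <- c(idxO[i][!is.na(idxO[i])], which(a$resno > i))
      xyz <- rot_about(xyz, rows, xyz[idxCA[i], ], xyz[idxC[i], ], dpsi[i])
    }
  }
  model@atoms$x <- xyz[, 1]
  model@atoms$y <- xyz[, 2]
  model@atoms$z <- xyz[, 3]
  model
}

#' Perturb a model into an ensemble of noisy copies
#'
#' Applies independent Gaussian torsion noise (pivot moves about the phi/psi
#' axes, preserving covalent geometry exactly) to produce \code{n_models}
#' copies. The per-torsion noise scale is calibrated by bisection so the
#' mean Calpha RMSD of the members to the source lies within 25 percent of
#' \code{target_rmsd}. Emulates the diversity of independent server models
#' of one sequence.
#'
#' @param model source \linkS4class{ProteinModel}.
#' @param target_rmsd desired mean Calpha RMSD to the source, Angstrom.
#' @param n_models number of copies (>= 2).
#' @param seed integer seed.
#' @return A \linkS4class{ModelEnsemble}.
#' @export
perturbEnsemble <- function(model, target_rmsd, n_models = 5, seed = 1) {
  stopifnot(target_rmsd >= 0, n_models >= 2)
  n <- nResidues(model)
  eps <- withSeed(seed, {
    lapply(seq_len(n_models), function(m) {
      list(phi = stats::rnorm(n), psi = stats::rnorm(n))
    })
  })
  build <- function(sigma) {
    lapply(seq_len(n_models), function(m) {
      out <- pivotPerturb(model, sigma * eps[[m]]$phi, sigma * eps[[m]]$psi)
      out@label <- sprintf("%s_pert%d", model@label, m)
      out
    })
  }
  meanRmsd <- function(ms) {
    mean(vapply(ms, caRmsd, numeric(1), model_b = model))
  }
  if (target_rmsd == 0) {
    return(modelEnsemble(build(0)))
  }
  lo <- 0
  hi <- 0.25
  while (meanRmsd(build(hi)) < target_rmsd) {
    hi <- hi * 2
    if (hi > 120) stop("target_rmsd unreachable for this chain")
  }
  for (k in seq_len(30)) {
    mid <- (lo + hi) / 2
    if (meanRmsd(build(mid)) < target_rmsd) lo <- mid else hi <- mid
    if (abs(meanRmsd(build((lo + hi) / 2)) - target_rmsd) <
        0.05 * target_rmsd) break
  }
  modelEnsemble(build((lo + hi) / 2))
}

#' Generate a miniature RAPDF training corpus
#'
#' A deterministic mixture of idealized topology classes -- two-helix
#' hairpins, three- and four-helix bundles, and sheet-free random-coil
#' decoys -- with seed-varied sequence compositions. A stand-in for a
#' structurally non-redundant database of experimental structures, at
#' desk scale.
#'
#' @param n_structures number of models (>= 5).
#' @param seed integer seed.
#' @return list of \linkS4class{ProteinModel} objects.
#' @export
makeRapdfTraining <- function(n_structures = 10, seed = 1) {
  stopifnot(n_structures >= 5)
  classes <- rep(c("hairpin", "bundle3", "bundle4", "coil"),
                 length.out = n_structures)
  lapply(seq_len(n_structures), function(k) {
    sk <- seed * 1000L + k
    switch(classes[k],
      hairpin = makeBundle(2, 14, 4, packing_radius = 5.5, seed = sk),
      bundle3 = makeBundle(3, 12, 4, packing_radius = 6.5, seed = sk),
      bundle4 = makeBundle(4, 11, 4, packing_radius = 7, seed = sk),
      coil = withSeed(sk, {
        n <- 36
        sseq <- sample(setdiff(AA20, "P"), n, replace = TRUE)
        phi <- stats::runif(n, -160, -50)
        psi <- stats::runif(n, -60, 160)
        modelFromTorsions(sseq, phi, psi, label = sprintf("coil_s%d", sk))
      }))
  })
}

#' Generate a sequence with a planted amphipathic lysine-cluster helix
#'
#' Within the helix window, positions whose helical-wheel angle (100
#' degrees per residue) falls on one face receive hydrophobic residues
#' (L/I/F) and the opposite face receives polar ones (S/E/Q); lysines are
#' then forced at \code{basic_positions}. Outside the window the sequence
#' is random polar. Emulates the alpha5 helix of PDCD10 with its
#' K169/K172/K179/K183/K186 cluster.
#'
#' @param length total sequence length.
#' @param helix_start 1-based first residue of the helix window.
#' @param helix_len helix window length.
#' @param basic_positions 1-based absolute indices (inside the window) to
#'   force to lysine.
#' @param seed integer seed.
#' @return one-letter sequence string.
#' @export
makeAmphipathicSequence <- function(length, helix_start, helix_len,
                                    basic_positions = integer(0), seed = 1) {
  h_end <- helix_start + helix_len - 1
  if (length < h_end || helix_start < 1) stop("helix window outside sequence")
  if (anyDuplicated(basic_positions)) {
    stop("overlapping basic position constraints")
  }
  if (length(basic_positions) &&
      (any(basic_positions < helix_start) || any(basic_positions > h_end))) {
    stop("basic_positions must lie inside the helix window")
  }
  withSeed(seed, {
    s <- sample(c("S", "T", "N", "Q", "E", "D", "G"), length, replace = TRUE)
    for (i in helix_start:h_end) {
      ang <- ((i - helix_start) * 100) %% 360
      s[i] <- if (cos(ang * pi / 180) > 0) {
        sample(c("L", "I", "F"), 1)
      } else {
        sample(c("S", "E", "Q"), 1)
      }
    }
    s[basic_positions] <- "K"
    paste(s, collapse = "")
  })
}
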