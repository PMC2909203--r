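# Constraint-restrained model building: Ramachandran-like torsion priors,
# Metropolis simulated annealing in torsion space (a self-contained
# stand-in for restrained torsion-angle dynamics), Cartesian relaxation,
# and the sequential four-term decoy filter.

PRIOR_CLASSES <- c("gly", "pro", "prepro", "generic")

priorClassOf <- function(sequence) {
  n <- length(sequence)
  nxt <- c(sequence[-1], "")
  ifelse(sequence == "G", "gly",
         ifelse(sequence == "P", "pro",
                ifelse(nxt == "P", "prepro", "generic")))
}

#' Train a Ramachandran-like torsion prior
#'
#' Binned (phi, psi) frequencies over 10-degree bins with add-one
#' smoothing, per residue class (Gly, Pro, pre-Pro, generic), from the
#' torsion angles observed in a structure corpus. Used as the proposal
#' distribution during torsion-space annealing.
#'
#' @param structures list of \linkS4class{ProteinModel} objects.
#' @param bin_width bin width in degrees (divisor of 360).
#' @return A \linkS4class{TorsionPrior}.
#' @export
trainTorsionPrior <- function(structures, bin_width = 10) {
  if (length(structures) < 1) stop("empty training set")
  breaks <- seq(-180, 180, by = bin_width)
  nb <- length(breaks) - 1
  counts <- stats::setNames(
    lapply(PRIOR_CLASSES, function(cl) matrix(0, nb, nb)), PRIOR_CLASSES)
  binOf <- function(a) pmin(floor((a + 180) / bin_width) + 1, nb)
  for (s in structures) {
    tt <- backboneTorsions(s)
    cls <- priorClassOf(s@sequence)
    ok <- !is.na(tt$phi) & !is.na(tt$psi)
    for (cl in PRIOR_CLASSES) {
      sel <- ok & cls == cl
      if (!any(sel)) next
      pb <- binOf(tt$phi[sel])
      sb <- binOf(tt$psi[sel])
      for (q in seq_along(pb)) {
        counts[[cl]][pb[q], sb[q]] <- counts[[cl]][pb[q], sb[q]] + 1
      }
    }
  }
  probs <- lapply(counts, function(m) {
    m <- m + 1  # add-one smoothing
    m / sum(m)
  })
  new("TorsionPrior", classes = PRIOR_CLASSES, breaks = breaks,
      probs = probs)
}

#' Draw (phi, psi) pairs from a torsion prior
#'
#' @param prior a \linkS4class{TorsionPrior}.
#' @param class residue class name.
#' @param n number of draws.
#' @return data.frame with columns \code{phi}, \code{psi} in degrees.
#' @export
sampleTorsionPrior <- function(prior, class = "generic", n = 1) {
  p <- prior@probs[[class]]
  nb <- nrow(p)
  bw <- prior@breaks[2] - prior@breaks[1]
  flat <- as.vector(t(p))  # index = (phi_bin - 1) * nb + psi_bin
  idx <- sample.int(nb * nb, n, replace = TRUE, prob = flat) - 1
  pb <- idx %/% nb
  sb <- idx %% nb
  data.frame(phi = -180 + bw * (pb + stats::runif(n)),
             psi = -180 + bw * (sb + stats::runif(n)))
}

# cumulative flattened prior, one column per class, for the C++ annealer
priorCumMatrix <- function(prior) {
  nb <- nrow(prior@probs[[1]])
  out <- vapply(prior@classes, function(cl) {
    v <- cumsum(as.vector(t(prior@probs[[cl]])))
    v / v[length(v)]
  }, numeric(nb * nb))
  out
}

#' Build-configuration constructor
#'
#' @param rounds number of build rounds (protocol default 50).
#' @param models_per_round models per round (protocol default 20).
#' @param t_start,t_end Metropolis temperature schedule endpoints
#'   (geometric decay) for the basin-hopping stage, in energy units of the
#'   restraint objective.
#' @param steps basin-hopping steps per model.
#' @param iters_hop gradient-minimization iterations per hop.
#' @param iters_final iterations of the final polish.
#' @param seed integer seed.
#' @return list of class \code{"buildConfig"}.
#' @export
buildConfig <- function(rounds = 50, models_per_round = 20,
                        t_start = 30, t_end = 1, steps = 30,
                        iters_hop = 50, iters_final = 300, seed = 1) {
  stopifnot(rounds >= 1, models_per_round >= 1, t_start > t_end, t_end > 0,
            steps >= 1, iters_hop >= 1, iters_final >= 1)
  structure(list(rounds = rounds, models_per_round = models_per_round,
                 t_start = t_start, t_end = t_end, steps = steps,
                 iters_hop = iters_hop, iters_final = iters_final,
                 seed = seed), class = "buildConfig")
}

# map constraint rows to 0-based atom indices of the NeRF layout
constraintAtomIndices <- function(set, atom_tab) {
  k <- set@constraints
  key <- paste(atom_tab$resno, atom_tab$atom)
  ai <- match(paste(k$res_i, k$atom_i), key)
  aj <- match(paste(k$res_j, k$atom_j), key)
  if (anyNA(ai) || anyNA(aj)) {
    stop("constraint references a residue/atom outside the sequence")
  }
  list(ai = ai - 1L, aj = aj - 1L, target = k$distance, weight = k$weight)
}

#' Generate conformations under a constraint set
#'
#' Builds \code{rounds * models_per_round} backbone+CB models in torsion
#' space, minimizing \code{U = sum weight * (d - target)^2 + vdW}. Each
#' model starts from an extended chain, takes one Metropolis sweep of
#' prior-drawn torsions per residue (the infinite-temperature limit of
#' prior-proposal annealing), and is then refined by basin hopping:
#' prior redraws of one or two residues followed by torsion-space
#' gradient minimization, accepted on a geometric temperature ladder,
#' with a deep final polish. Covalent geometry is idealized throughout.
#' Deterministic for a given (seed, round, model) triple.
#'
#' @param sequence one-letter codes (string or vector).
#' @param constraint_set a \linkS4class{ConstraintSet} (may be empty).
#' @param prior a \linkS4class{TorsionPrior}.
#' @param config a \code{\link{buildConfig}}.
#' @return A \linkS4class{ModelEnsemble} with an \code{"energies"}
#'   attribute (data.frame round, model, u_init, u_final, accepted).
#' @export
buildConformations <- function(sequence, constraint_set, prior,
                               config = buildConfig()) {
  if (length(sequence) == 1 && nchar(sequence) > 1) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  if (nrow(constraint_set@constraints) &&
      max(constraint_set@constraints$res_j) > length(sequence)) {
    stop("constraint references a residue outside the sequence")
  }
  atom_tab <- nerfAtomTable(sequence)
  cons <- constraintAtomIndices(constraint_set, atom_tab)
  has_cb <- sequence != "G"
  radii <- unname(VDW_RADII[atom_tab$element])
  radii[is.na(radii)] <- VDW_RADII[["C"]]
  cls_idx <- match(priorClassOf(sequence), prior@classes) - 1L
  cum <- priorCumMatrix(prior)
  n <- length(sequence)
  out <- vector("list", config$rounds * config$models_per_round)
  energies <- data.frame()
  k <- 1L
  for (r in seq_len(config$rounds)) {
    for (m in seq_len(config$models_per_round)) {
      set.seed((config$seed * 7919 + r * 1009 + m) %% 2147483647L)
      res <- .build_model_search(has_cb, cls_idx, cum, radii,
                                 as.integer(atom_tab$resno),
                                 cons$ai, cons$aj, cons$target, cons$weight,
                                 as.integer(config$steps),
                                 as.integer(config$iters_hop),
                                 as.integer(config$iters_final),
                                 config$t_start, config$t_end)
      out[[k]] <- modelFromTorsions(sequence, res$phi, res$psi,
                                    label = sprintf("r%03dm%03d", r, m))
      energies <- rbind(energies,
                        data.frame(round = r, model = m,
                                   u_init = res$u_init,
                                   u_final = res$u_final))
      k <- k + 1L
    }
  }
  ens <- modelEnsemble(out)
  attr(ens, "energies") <- energies
  ens
}

#' Relax a model by steepest descent on the clash penalty
#'
#' Cartesian steepest descent on the soft-sphere van der Waals term with
#' harmonic bond-length restraints to the model's covalent connectivity
#' (a simplified stand-in for full energy minimization plus sidechain
#' optimization). The clash penalty never increases; a clash-free model is
#' returned unchanged.
#'
#' @param model a \linkS4class{ProteinModel}.
#' @param steps maximum descent steps.
#' @param k_bond bond-restraint force constant.
#' @return the relaxed \linkS4class{ProteinModel}.
#' @export
relaxModel <- function(model, steps = 50, k_bond = 50) {
  a <- model@atoms
  na <- nrow(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  radii <- unname(VDW_RADII[a$element])
  radii[is.na(radii)] <- VDW_RADII[["C"]]
  resno <- a$resno
  # covalent connectivity of the backbone+CB layout
  key <- paste(resno, a$atom)
  bond_of <- function(r1, a1, r2, a2) {
    i <- match(paste(r1, a1), key)
    j <- match(paste(r2, a2), key)
    cbind(i, j)[!is.na(i) & !is.na(j), , drop = FALSE]
  }
  rs <- seq_len(max(resno))
  bonds <- rbind(bond_of(rs, "N", rs, "CA"), bond_of(rs, "CA", rs, "C"),
                 bond_of(rs, "C", rs, "O"), bond_of(rs, "CA", rs, "CB"),
                 bond_of(rs[-length(rs)], "C", rs[-1], "N"))
  d0 <- sqrt(rowSums((xyz[bonds[, 1], , drop = FALSE] -
                      xyz[bonds[, 2], , drop = FALSE])^2))
  sepmat <- abs(outer(resno, resno, "-")) >= 2
  smat <- 0.9 * outer(radii, radii, "+")
  vdw_of <- function(x) {
    dm <- as.matrix(stats::dist(x))
    ov <- pmax(smat - dm, 0)  # first argument keeps the dim attribute
    ov[!sepmat] <- 0
    sum(ov[upper.tri(ov)]^2)
  }
  grad_of <- function(x) {
    dm <- as.matrix(stats::dist(x))
    diag(dm) <- Inf
    ov <- smat - dm
    act <- sepmat & ov > 0
    coef <- matrix(0, na, na)
    coef[act] <- -2 * ov[act] / dm[act]
    g <- matrix(0, na, 3)
    for (dim in 1:3) {
      diff <- outer(x[, dim], x[, dim], "-")
      g[, dim] <- rowSums(coef * diff)
    }
    bd <- x[bonds[, 1], , drop = FALSE] - x[bonds[, 2], , drop = FALSE]
    dl <- sqrt(rowSums(bd^2))
    cb <- 2 * k_bond * (dl - d0) / pmax(dl, 1e-9)
    gb1 <- rowsum(cb * bd, bonds[, 1], reorder = FALSE)
    g[as.integer(rownames(gb1)), ] <- g[as.integer(rownames(gb1)), ] + gb1
    gb2 <- rowsum(-cb * bd, bonds[, 2], reorder = FALSE)
    g[as.integer(rownames(gb2)), ] <- g[as.integer(rownames(gb2)), ] + gb2
    g
  }
  e_cur <- vdw_of(xyz)
  lambda <- 1e-3
  for (it in seq_len(steps)) {
    if (e_cur <= 0) break
    g <- grad_of(xyz)
    gn <- sqrt(sum(g^2))
    if (gn < 1e-10) break
    moved <- FALSE
    while (lambda > 1e-9) {
      trial <- xyz - lambda * g
      if (vdw_of(trial) <= e_cur) {
        xyz <- trial
        e_cur <- vdw_of(trial)
        lambda <- lambda * 1.2
        moved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!moved) break
  }
  model@atoms$x <- xyz[, 1]
  model@atoms$y <- xyz[, 2]
  model@atoms$z <- xyz[, 3]
  model
}

#' Sequential four-term decoy filter
#'
#' Removes half of the models (keeps \code{ceiling(N/2)}) by applying, in
#' order, RAPDF, the van der Waals clash term, the hydrophobic compactness
#' factor, and the electrostatics term. Total removals are split equally
#' across the four stages (remainder removed at the last); each stage
#' removes its count of worst-scoring survivors, with ties broken by
#' stable input order. The output is a subsequence of the input.
#'
#' @param ensemble a \linkS4class{ModelEnsemble}.
#' @param table a trained \linkS4class{RapdfTable}.
#' @param keep_fraction fraction to keep (default 0.5).
#' @return the filtered \linkS4class{ModelEnsemble} with attributes
#'   \code{"removed_per_stage"} (named integer vector) and \code{"kept"}
#'   (indices into the input).
#' @export
sequentialFilter <- function(ensemble, table, keep_fraction = 0.5) {
  N <- nModels(ensemble)
  K <- ceiling(N * keep_fraction)
  R <- N - K
  base <- R %/% 4
  removals <- c(rapdf = base, vdw = base, compactness = base,
                electrostatics = R - 3 * base)
  scores <- lapply(ensemble@models, scoreModel, table = table)
  stage_score <- list(
    rapdf = vapply(scores, function(s) {
      if (is.na(s$rapdf_normalized)) Inf else s$rapdf_normalized
    }, numeric(1)),
    vdw = vapply(scores, `[[`, numeric(1), "vdw_energy"),
    compactness = vapply(scores, function(s) {
      if (is.na(s$compactness)) Inf else s$compactness
    }, numeric(1)),
    electrostatics = vapply(scores, `[[`, numeric(1), "electrostatics"))
  alive <- seq_len(N)
  for (stage in names(removals)) {
    r <- removals[[stage]]
    if (r == 0) next
    sc <- stage_score[[stage]][alive]
    worst <- alive[order(sc, decreasing = TRUE)[seq_len(r)]]
    alive <- setdiff(alive, worst)
  }
  out <- modelEnsemble(ensemble@models[alive])
  attr(out, "removed_per_stage") <- removals
  attr(out, "kept") <- alive
  out
}
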