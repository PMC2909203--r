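# Sequence- and surface-level functional-site analyses: hydrophobic
# moments and amphipathic helix detection (Eisenberg scale, 100 degrees
# per residue), basic-residue cluster mapping, Shrake-Rupley solvent
# accessibility, desolvation-ranked surface patches, residue composition
# and sequence-mass estimates, and heptad-repeat register assignment.

seqChars <- function(sequence) {
  if (length(sequence) == 1 && nchar(sequence) > 1) {
    strsplit(sequence, "")[[1]]
  } else sequence
}

#' Hydrophobic moment of a sequence window
#'
#' \code{mu_H = |sum_n h_n exp(i n delta)| / N} with the Eisenberg
#' consensus hydrophobicity scale and helical twist \code{delta} (100
#' degrees per residue for an alpha helix).
#'
#' @param sequence_window one-letter codes (string or vector), length >= 6.
#' @param angle helical twist per residue, degrees.
#' @param scale named hydrophobicity scale (defaults to Eisenberg).
#' @return non-negative moment (dimensionless, per-residue normalized).
#' @export
hydrophobicMoment <- function(sequence_window, angle = 100,
                              scale = EISENBERG) {
  s <- seqChars(sequence_window)
  if (length(s) < 6) stop("window must have length >= 6")
  if (!all(s %in% names(scale))) {
    stop("non-canonical residue in window")
  }
  h <- unname(scale[s])
  n <- seq_along(s) - 1
  th <- n * angle * pi / 180
  Mod(sum(h * complex(modulus = 1, argument = th))) / length(s)
}

# phase (degrees) of the moment vector, for face assignment
momentPhase <- function(s, angle = 100, scale = EISENBERG) {
  h <- unname(scale[s])
  n <- seq_along(s) - 1
  th <- n * angle * pi / 180
  Arg(sum(h * complex(modulus = 1, argument = th))) * 180 / pi
}

#' Scan a sequence for amphipathic helices
#'
#' Slides a window over the sequence, computes the hydrophobic moment of
#' each window, and reports maximal runs of windows with moment >=
#' \code{min_moment}, merged into residue intervals. Face assignment
#' (hydrophobic vs polar face) comes from the phase of the complex moment
#' sum.
#'
#' @param sequence one-letter codes (string or vector).
#' @param window window length in residues.
#' @param min_moment detection threshold on the per-residue moment.
#' @param angle helical twist, degrees per residue.
#' @return data.frame with one row per detected helix: \code{start},
#'   \code{end}, \code{mean_moment}, \code{face} (string of H/P flags per
#'   residue of the interval).
#' @export
findAmphipathicHelices <- function(sequence, window = 18, min_moment = 0.25,
                                   angle = 100) {
  s <- seqChars(sequence)
  n <- length(s)
  if (n < window) stop("sequence shorter than the scan window")
  starts <- seq_len(n - window + 1)
  mu <- vapply(starts, function(i) {
    hydrophobicMoment(s[i:(i + window - 1)], angle = angle)
  }, numeric(1))
  hits <- mu >= min_moment
  if (!any(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      mean_moment = numeric(0), face = character(0),
                      stringsAsFactors = FALSE))
  }
  r <- rle(hits)
  ends_run <- cumsum(r$lengths)
  starts_run <- ends_run - r$lengths + 1
  out <- lapply(which(r$values), function(q) {
    ws <- starts_run[q]:ends_run[q]           # window start indices
    start <- ws[1]
    end <- ws[length(ws)] + window - 1
    seg <- s[start:end]
    ph <- momentPhase(seg, angle = angle)
    th <- (seq_along(seg) - 1) * angle
    face <- ifelse(cos((th - ph) * pi / 180) > 0, "H", "P")
    data.frame(start = start, end = end, mean_moment = mean(mu[ws]),
               face = paste(face, collapse = ""), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Find basic-residue (K/R) clusters anchored to amphipathic helices
#'
#' Reports maximal groups of lysine/arginine residues spanning at most
#' \code{max_span} residues and containing at least \code{min_basic}
#' members, lying within an annotated helix extended by
#' \code{loop_extension} residues past its end (basic clusters often spill
#' into the flexible loop that follows the helix).
#'
#' @param sequence one-letter codes (string or vector).
#' @param helices data.frame from \code{\link{findAmphipathicHelices}}.
#' @param min_basic minimum number of basic residues per cluster.
#' @param max_span maximal first-to-last span in residues (inclusive).
#' @param loop_extension residues past the helix end still considered.
#' @return data.frame with one row per cluster: \code{helix_start},
#'   \code{helix_end}, \code{first}, \code{last}, \code{span},
#'   \code{n_basic}, \code{positions} (comma-separated).
#' @export
findBasicClusters <- function(sequence, helices, min_basic = 4,
                              max_span = 20, loop_extension = 5) {
  s <- seqChars(sequence)
  empty <- data.frame(helix_start = integer(0), helix_end = integer(0),
                      first = integer(0), last = integer(0),
                      span = integer(0), n_basic = integer(0),
                      positions = character(0), stringsAsFactors = FALSE)
  if (nrow(helices) == 0) return(empty)
  out <- empty
  for (hx in seq_len(nrow(helices))) {
    lo <- helices$start[hx]
    hi <- min(helices$end[hx] + loop_extension, length(s))
    basics <- which(s %in% POSITIVE_AA)
    basics <- basics[basics >= lo & basics <= hi]
    if (length(basics) < min_basic) next
    # maximal windows of basic positions within max_span
    groups <- list()
    for (i in seq_along(basics)) {
      j <- max(which(basics - basics[i] + 1 <= max_span))
      if (j - i + 1 >= min_basic) groups[[length(groups) + 1]] <- c(i, j)
    }
    if (!length(groups)) next
    # drop groups contained in another
    keep <- vapply(seq_along(groups), function(g) {
      !any(vapply(seq_along(groups), function(g2) {
        g2 != g && groups[[g2]][1] <= groups[[g]][1] &&
          groups[[g2]][2] >= groups[[g]][2]
      }, logical(1)))
    }, logical(1))
    for (g in groups[keep]) {
      pos <- basics[g[1]:g[2]]
      out <- rbind(out, data.frame(
        helix_start = lo, helix_end = helices$end[hx],
        first = pos[1], last = pos[length(pos)],
        span = pos[length(pos)] - pos[1] + 1L,
        n_basic = length(pos),
        positions = paste(pos, collapse = ","), stringsAsFactors = FALSE))
    }
  }
  unique(out)
}

# Deterministic quasi-uniform unit sphere points (golden-spiral).
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom accessible area from quasi-uniform sphere points at radius
#' \code{r_atom + probe}, counting points not buried inside any
#' neighbour's expanded sphere.
#'
#' @param model a \linkS4class{ProteinModel}.
#' @param probe probe radius, Angstrom (water 1.4).
#' @param n_points sphere quadrature points per atom.
#' @return numeric vector of per-atom areas (Angstrom^2) in atom order.
#' @export
sasa <- function(model, probe = 1.4, n_points = 240) {
  a <- model@atoms
  na <- nrow(a)
  radii <- unname(VDW_RADII[a$element])
  radii[is.na(radii)] <- VDW_RADII[["C"]]
  R <- radii + probe
  xyz <- as.matrix(a[, c("x", "y", "z")])
  sp <- spherePoints(n_points)
  dm <- as.matrix(stats::dist(xyz))
  out <- numeric(na)
  for (i in seq_len(na)) {
    nb <- which(dm[i, ] < R[i] + R & seq_len(na) != i)
    pts <- sweep(sp * R[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- rowSums(sweep(pts, 2, xyz[j, ])^2)
      free <- free & d2 > R[j]^2
      if (!any(free)) break
    }
    out[i] <- 4 * pi * R[i]^2 * sum(free) / n_points
  }
  out
}

odaAtomClass <- function(atom, restype) {
  cls <- residueClass(restype)
  ifelse(atom == "N", "N_backbone",
  ifelse(atom == "O", "O_backbone",
  ifelse(atom == "CB" & cls %in% c("pos", "neg"), "CB_charged",
  ifelse(cls == "hyd", "C_apolar", "C_polar"))))
}

#' Desolvation-ranked surface patches (optimal-docking-area style)
#'
#' Every surface atom (SASA > \code{sasa_min}) seeds a candidate patch of
#' the surface atoms within \code{patch_radius}; the patch score is the
#' SASA-weighted sum of per-atom-class atomic solvation parameters
#' (octanol/water-style: apolar carbon favorable to desolvate = negative,
#' polar/charged unfavorable = positive). Patches are ranked ascending
#' (most favorable first) and greedily pruned: a patch whose center lies
#' inside an already-kept patch is dropped. Low-ranked patches mark
#' candidate protein-protein interface regions.
#'
#' @param model a \linkS4class{ProteinModel}.
#' @param patch_radius patch radius in Angstrom.
#' @param probe,n_points forwarded to \code{\link{sasa}}.
#' @param sasa_min surface-atom threshold, Angstrom^2.
#' @param asp named atomic solvation parameter table.
#' @return data.frame with one row per kept patch: \code{center} (atom
#'   index), \code{center_resno}, \code{n_atoms}, \code{oda_score},
#'   \code{rank}, \code{members} (comma-separated atom indices).
#' @export
odaPatches <- function(model, patch_radius = 10, probe = 1.4,
                       n_points = 240, sasa_min = 1, asp = ASP_TABLE) {
  a <- model@atoms
  area <- sasa(model, probe = probe, n_points = n_points)
  surf <- which(area > sasa_min)
  if (!length(surf)) {
    return(data.frame(center = integer(0), center_resno = integer(0),
                      n_atoms = integer(0), oda_score = numeric(0),
                      rank = integer(0), members = character(0)))
  }
  cls <- odaAtomClass(a$atom, a$restype)
  w <- unname(asp[cls]) * area
  xyz <- as.matrix(a[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz[surf, , drop = FALSE]))
  score <- vapply(seq_along(surf), function(k) {
    sum(w[surf[dm[k, ] <= patch_radius]])
  }, numeric(1))
  ord <- order(score)
  kept <- integer(0)
  rows <- list()
  for (k in ord) {
    ctr <- surf[k]
    inside_kept <- any(vapply(kept, function(kk) {
      dm[k, kk] <= patch_radius
    }, logical(1)))
    if (inside_kept) next
    kept <- c(kept, k)
    memb <- surf[dm[k, ] <= patch_radius]
    rows[[length(rows) + 1]] <- data.frame(
      center = ctr, center_resno = a$resno[ctr],
      n_atoms = length(memb), oda_score = score[k],
      rank = length(rows) + 1L,
      members = paste(memb, collapse = ","), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Residue composition of a sequence
#'
#' @param sequence one-letter codes (string or vector).
#' @return named integer vector of counts over the 20 canonical residues;
#'   sums to the sequence length.
#' @export
residueComposition <- function(sequence) {
  s <- seqChars(sequence)
  if (!all(s %in% AA20)) stop("non-canonical residue in sequence")
  table(factor(s, levels = AA20))
}

#' Sequence-based molecular-weight estimate
#'
#' Average-isotope chain mass: sum of residue masses plus one water, times
#' the number of copies (no inter-chain bonds), so a dimer estimate is
#' exactly twice the monomer estimate.
#'
#' @param sequence one-letter codes (string or vector).
#' @param n_copies oligomeric state (1 = monomer, 2 = dimer, ...).
#' @return mass in Da.
#' @export
estimateMw <- function(sequence, n_copies = 1) {
  stopifnot(n_copies >= 1)
  s <- seqChars(sequence)
  if (!all(s %in% AA20)) stop("non-canonical residue in sequence")
  n_copies * (sum(unname(RESIDUE_MASS[s])) + WATER_MASS)
}

#' Assign the heptad-repeat (a-g) register of annotated helices
#'
#' For each helix, evaluates the 7 possible frames and keeps the one
#' maximizing the mean hydrophobicity at positions a and d; the margin is
#' that mean minus the helix-wide mean hydrophobicity. Helices shorter
#' than 14 residues (two heptads) get an undefined register (NA row).
#'
#' @param sequence one-letter codes (string or vector).
#' @param helices data.frame with \code{start}, \code{end} columns.
#' @param scale named hydrophobicity scale.
#' @return data.frame with one row per helix: \code{start}, \code{end},
#'   \code{frame} (0-6: offset of position "a" from the helix start),
#'   \code{margin}; NA frame/margin where undefined.
#' @export
detectHeptadRepeats <- function(sequence, helices, scale = EISENBERG) {
  s <- seqChars(sequence)
  out <- lapply(seq_len(nrow(helices)), function(hx) {
    lo <- helices$start[hx]
    hi <- helices$end[hx]
    len <- hi - lo + 1
    if (len < 14) {
      return(data.frame(start = lo, end = hi, frame = NA_integer_,
                        margin = NA_real_))
    }
    h <- unname(scale[s[lo:hi]])
    pos <- seq_len(len) - 1
    stats_ <- vapply(0:6, function(f) {
      ad <- ((pos - f) %% 7) %in% c(0, 3)
      mean(h[ad])
    }, numeric(1))
    best <- which.max(stats_) - 1L
    data.frame(start = lo, end = hi, frame = best,
               margin = max(stats_) - mean(h))
  })
  do.call(rbind, out)
}
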