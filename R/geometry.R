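# Core geometry: superposition, dihedrals, secondary-structure assignment,
# and construction of idealized chains from torsions.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' equal-length coordinate sets (SVD formulation with reflection
#' sign-correction) and returns the minimized RMSD.
#'
#' @param coords_a,coords_b numeric n x 3 matrices, n >= 3.
#' @return list with \code{rotation} (3 x 3, determinant +1),
#'   \code{translation} (length 3), and \code{rmsd} in Angstrom; the
#'   transform maps \code{coords_b} onto \code{coords_a} as
#'   \code{coords_b \%*\% t(rotation) + translation}.
#' @export
kabschSuperimpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b))) {
    stop("coordinate sets must have identical dimensions")
  }
  n <- nrow(coords_a)
  if (n < 3) stop("need at least 3 points")
  ca <- colMeans(coords_a)
  cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca)
  B <- sweep(coords_b, 2, cb)
  H <- t(B) %*% A
  sv <- svd(H)
  if (min(sv$d) < 1e-10 && sv$d[2] < 1e-10) {
    stop("degenerate (collinear) point sets")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  Brot <- B %*% t(R)
  rmsd <- sqrt(sum((Brot - A)^2) / n)
  list(rotation = R, translation = as.numeric(ca - cb %*% t(R)), rmsd = rmsd)
}

#' Superimpose two equal-length residue ranges of one model
#'
#' Calpha-only Kabsch superposition of two closed residue intervals, the
#' operation used to compare the two trihelical repeats of a helical-hairpin
#' protein. No alignment is attempted: the intervals define the
#' equivalence.
#'
#' @param model a \linkS4class{ProteinModel}.
#' @param range_a,range_b integer vectors \code{c(start, end)}, 1-based
#'   closed intervals of equal length.
#' @return list with \code{rmsd} (Angstrom) and \code{n_atoms} equivalenced.
#' @export
superimposeRepeats <- function(model, range_a, range_b) {
  ia <- seq(range_a[1], range_a[2])
  ib <- seq(range_b[1], range_b[2])
  if (length(ia) != length(ib)) {
    stop("residue intervals must have equal length")
  }
  ca <- caCoords(model)
  if (max(ia, ib) > nrow(ca)) stop("interval outside the chain")
  fit <- kabschSuperimpose(ca[ia, , drop = FALSE], ca[ib, , drop = FALSE])
  list(rmsd = fit$rmsd, n_atoms = length(ia))
}

# Signed dihedral angle (degrees, (-180, 180]) of four points.
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- n1 / sqrt(sum(n1^2))
  m2 <- n2 / sqrt(sum(n2^2))
  b2u <- b2 / sqrt(sum(b2^2))
  x <- sum(m1 * m2)
  y <- sum(c(m1[2] * b2u[3] - m1[3] * b2u[2],
             m1[3] * b2u[1] - m1[1] * b2u[3],
             m1[1] * b2u[2] - m1[2] * b2u[1]) * m2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Matrix of one backbone atom per residue (NA rows where absent).
backboneAtomMatrix <- function(model, name) {
  n <- nResidues(model)
  out <- matrix(NA_real_, n, 3)
  a <- model@atoms[model@atoms$atom == name, , drop = FALSE]
  out[a$resno, ] <- as.matrix(a[, c("x", "y", "z")])
  out
}

#' Backbone phi/psi torsion angles
#'
#' Standard dihedral convention: \code{phi_i = C(i-1)-N(i)-CA(i)-C(i)},
#' \code{psi_i = N(i)-CA(i)-C(i)-N(i+1)}. Angles undefined at the chain
#' termini or where a backbone atom is missing are returned as \code{NA}
#' (flagged, never fabricated).
#'
#' @param model a \linkS4class{ProteinModel} with N, CA, C backbone atoms.
#' @return data.frame with columns \code{resno}, \code{phi}, \code{psi}
#'   (degrees in (-180, 180]).
#' @export
backboneTorsions <- function(model) {
  n <- nResidues(model)
  N <- backboneAtomMatrix(model, "N")
  CA <- backboneAtomMatrix(model, "CA")
  C <- backboneAtomMatrix(model, "C")
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1 && !anyNA(c(C[i - 1, ], N[i, ], CA[i, ], C[i, ]))) {
      phi[i] <- dihedralAngle(C[i - 1, ], N[i, ], CA[i, ], C[i, ])
    }
    if (i < n && !anyNA(c(N[i, ], CA[i, ], C[i, ], N[i + 1, ]))) {
      psi[i] <- dihedralAngle(N[i, ], CA[i, ], C[i, ], N[i + 1, ])
    }
  }
  data.frame(resno = seq_len(n), phi = phi, psi = psi)
}

#' Fraction of residues in alpha-helical conformation
#'
#' A residue is counted helical iff its torsions fall in the alpha window
#' (phi within \code{-57 +/- 30} degrees, psi within \code{-47 +/- 30}) and
#' it belongs to a run of at least \code{min_run} consecutive qualifying
#' residues. Residues with undefined torsions (termini, missing atoms)
#' count as non-helical but stay in the denominator.
#'
#' @param model a \linkS4class{ProteinModel}.
#' @param window half-width of the torsion window in degrees.
#' @param min_run minimum consecutive qualifying residues.
#' @return fraction in [0, 1].
#' @export
helixFraction <- function(model, window = 30, min_run = 3) {
  tt <- backboneTorsions(model)
  ok <- !is.na(tt$phi) & !is.na(tt$psi) &
    abs(tt$phi - HELIX_PHI) <= window & abs(tt$psi - HELIX_PSI) <= window
  ok[is.na(ok)] <- FALSE
  r <- rle(ok)
  r$values <- r$values & r$lengths >= min_run
  helical <- inverse.rle(r)
  sum(helical) / nResidues(model)
}

#' Apply a rigid transform to a model
#'
#' @param model a \linkS4class{ProteinModel}.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @return the transformed model.
#' @export
transformModel <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  xyz <- coords(model) %*% t(rotation)
  model@atoms$x <- xyz[, 1] + translation[1]
  model@atoms$y <- xyz[, 2] + translation[2]
  model@atoms$z <- xyz[, 3] + translation[3]
  model
}

# Atom bookkeeping for the NeRF layout (N, CA, C, O [, CB] per residue).
nerfAtomTable <- function(sequence) {
  has_cb <- sequence != "G"
  per <- ifelse(has_cb, 5L, 4L)
  atom <- unlist(lapply(seq_along(sequence), function(i) {
    if (has_cb[i]) c("N", "CA", "C", "O", "CB") else c("N", "CA", "C", "O")
  }))
  resno <- rep(seq_along(sequence), per)
  data.frame(atom = atom, element = elementOf(atom), resno = resno,
             restype = sequence[resno], stringsAsFactors = FALSE)
}

# Build a backbone+CB ProteinModel from per-residue torsions with ideal
# covalent geometry. phi[1] and psi[n] only orient terminal O placement.
modelFromTorsions <- function(sequence, phi, psi, label = "built") {
  has_cb <- sequence != "G"
  xyz <- .nerf_chain(phi, psi, has_cb)
  tab <- nerfAtomTable(sequence)
  tab$x <- xyz[, 1]
  tab$y <- xyz[, 2]
  tab$z <- xyz[, 3]
  proteinModel(sequence, tab, label = label)
}

#' Calpha RMSD between two models after optimal superposition
#'
#' @param model_a,model_b models sharing residue count.
#' @return RMSD in Angstrom.
#' @export
caRmsd <- function(model_a, model_b) {
  kabschSuperimpose(caCoords(model_a), caCoords(model_b))$rmsd
}
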