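#' @import methods
NULL

#' All-atom (or coarse-grained) coordinate model of one protein chain
#'
#' A \code{ProteinModel} holds the one-letter sequence of a single chain and
#' an ordered atom table with 1-based residue numbering. It is the unit the
#' refinement pipeline scores, filters and clusters.
#'
#' @slot sequence character vector of one-letter residue codes (one element
#'   per residue, canonical 20-letter alphabet).
#' @slot atoms data.frame with columns \code{atom} (PDB atom name),
#'   \code{element}, \code{resno} (1-based integer), \code{restype}
#'   (one-letter code) and Cartesian coordinates \code{x}, \code{y},
#'   \code{z} in Angstrom.
#' @slot label free-text identifier.
#'
#' @exportClass ProteinModel
setClass("ProteinModel",
         representation(sequence = "character",
                        atoms = "data.frame",
                        label = "character"))

setValidity("ProteinModel", function(object) {
  s <- object@sequence
  a <- object@atoms
  if (length(s) < 1) return("sequence must have length >= 1")
  if (!all(s %in% AA20)) {
    return(paste0("non-canonical residue code(s): ",
                  paste(unique(s[!s %in% AA20]), collapse = ", ")))
  }
  need <- c("atom", "element", "resno", "restype", "x", "y", "z")
  if (!all(need %in% names(a))) {
    return(paste0("atoms must have columns: ", paste(need, collapse = ", ")))
  }
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z))) {
    return("non-finite coordinates")
  }
  if (any(a$resno < 1)) return("residue indices must be >= 1")
  n <- length(s)
  present <- sort(unique(a$resno))
  if (!identical(present, seq_len(n))) {
    return("every residue in the sequence must have at least one atom")
  }
  ca <- unique(a$resno[a$atom == "CA"])
  if (length(ca) != n) {
    missing_ca <- setdiff(seq_len(n), ca)
    return(paste0("missing CA for residue(s): ",
                  paste(utils::head(missing_ca, 5), collapse = ", ")))
  }
  bad <- a$restype != s[a$resno]
  if (any(bad)) return("atom restype inconsistent with sequence")
  TRUE
})

#' Ordered collection of models sharing one sequence and atom naming
#'
#' @slot models list of \linkS4class{ProteinModel} objects with identical
#'   sequence and identical (resno, atom) keys in identical order.
#' @slot sequence the shared one-letter sequence.
#'
#' @exportClass ModelEnsemble
setClass("ModelEnsemble",
         representation(models = "list", sequence = "character"))

setValidity("ModelEnsemble", function(object) {
  ms <- object@models
  if (length(ms) < 1) return("ensemble must contain at least one model")
  if (!all(vapply(ms, is, logical(1), class2 = "ProteinModel"))) {
    return("all members must be ProteinModel objects")
  }
  key0 <- paste(ms[[1]]@atoms$resno, ms[[1]]@atoms$atom)
  for (i in seq_along(ms)) {
    if (!identical(ms[[i]]@sequence, object@sequence)) {
      return(sprintf("model %d sequence differs from ensemble sequence", i))
    }
    if (!identical(paste(ms[[i]]@atoms$resno, ms[[i]]@atoms$atom), key0)) {
      return(sprintf("model %d atom naming differs from model 1", i))
    }
  }
  TRUE
})

#' Binned atom-type-pair distance log-odds table (RAPDF)
#'
#' Trained from a corpus of structures by Bayesian comparison of the
#' distance distribution observed for each reduced atom-type pair against
#' the marginal over all pairs. Scores are \code{-ln[P(bin|pair)/P(bin)]},
#' so lower is more native-like.
#'
#' @slot types reduced atom type labels.
#' @slot pairs character vector of unordered pair keys \code{"t1|t2"}.
#' @slot breaks distance bin edges in Angstrom (half-open bins [lo, hi)).
#' @slot counts integer matrix, pairs x bins, raw observation counts.
#' @slot logOdds numeric matrix, pairs x bins.
#' @slot pseudocount smoothing constant added per (pair, bin).
#' @slot meta list of training metadata (n_structures, labels, min_sep).
#'
#' @exportClass RapdfTable
setClass("RapdfTable",
         representation(types = "character", pairs = "character",
                        breaks = "numeric", counts = "matrix",
                        logOdds = "matrix", pseudocount = "numeric",
                        meta = "list"))

setValidity("RapdfTable", function(object) {
  nb <- length(object@breaks) - 1
  if (nb < 1) return("need at least one distance bin")
  if (any(diff(object@breaks) <= 0)) return("breaks must be increasing")
  if (!all(dim(object@counts) == c(length(object@pairs), nb))) {
    return("counts dimensions must be pairs x bins")
  }
  if (!all(dim(object@logOdds) == dim(object@counts))) {
    return("logOdds dimensions must match counts")
  }
  if (!all(is.finite(object@logOdds))) return("logOdds must be finite")
  # smoothed conditional distributions normalize per pair
  sm <- object@counts + object@pseudocount
  p <- sm / rowSums(sm)
  if (any(abs(rowSums(p) - 1) > 1e-9)) return("P(bin|pair) must sum to 1")
  TRUE
})

#' Compiled consensus distance-constraint set under one distance cutoff
#'
#' @slot cutoff maximal constraint distance in Angstrom (default protocol
#'   uses 12, 16 and 20).
#' @slot constraints data.frame with columns \code{res_i}, \code{atom_i},
#'   \code{res_j}, \code{atom_j}, \code{distance}, \code{support},
#'   \code{rapdf}, \code{weight}; at most one row per residue pair.
#' @slot source identifier of the source ensemble.
#'
#' @exportClass ConstraintSet
setClass("ConstraintSet",
         representation(cutoff = "numeric", constraints = "data.frame",
                        source = "character"))

setValidity("ConstraintSet", function(object) {
  k <- object@constraints
  need <- c("res_i", "atom_i", "res_j", "atom_j",
            "distance", "support", "rapdf", "weight")
  if (!all(need %in% names(k))) {
    return(paste0("constraints must have columns: ",
                  paste(need, collapse = ", ")))
  }
  if (nrow(k)) {
    if (any(k$distance <= 0)) return("constraint distances must be > 0")
    if (any(k$distance > object@cutoff + 1e-9)) {
      return("constraint distance exceeds cutoff")
    }
    if (anyDuplicated(paste(k$res_i, k$res_j))) {
      return("more than one constraint for a residue pair")
    }
    if (any(k$res_i >= k$res_j)) return("require res_i < res_j")
    if (any(k$weight <= 0 | k$weight > 1)) return("weights must lie in (0,1]")
  }
  TRUE
})

#' Ramachandran-like per-residue-class torsion prior
#'
#' Binned (phi, psi) probabilities over 10-degree bins for the residue
#' classes Gly, Pro, pre-Pro and generic, trained from a structure corpus
#' with add-one smoothing; used as the proposal distribution during
#' torsion-space annealing.
#'
#' @slot classes class labels.
#' @slot breaks common bin edges in degrees, -180 to 180.
#' @slot probs list (per class) of phi x psi probability matrices.
#'
#' @exportClass TorsionPrior
setClass("TorsionPrior",
         representation(classes = "character", breaks = "numeric",
                        probs = "list"))

setValidity("TorsionPrior", function(object) {
  if (!identical(names(object@probs), object@classes)) {
    return("probs must be named by class")
  }
  nb <- length(object@breaks) - 1
  for (cl in object@classes) {
    p <- object@probs[[cl]]
    if (!all(dim(p) == c(nb, nb))) return("each class needs an nb x nb matrix")
    if (abs(sum(p) - 1) > 1e-9) return("probabilities must sum to 1 per class")
    if (any(p < 0)) return("negative probability")
  }
  TRUE
})

#' Result of iterative density clustering of a model ensemble
#'
#' @slot assignments integer vector over input models: rank of the cluster
#'   the model belongs to, or \code{NA} for removed outliers.
#' @slot densities neighbour counts (at the RMSD threshold) for the
#'   surviving models, \code{NA} for outliers.
#' @slot sizes cluster sizes in rank order (non-increasing).
#' @slot centroids input-model index of each ranked cluster's centroid.
#' @slot rmsdThreshold neighbourhood / linkage threshold in Angstrom.
#' @slot iterations number of outlier-removal iterations performed.
#'
#' @exportClass ClusterResult
setClass("ClusterResult",
         representation(assignments = "integer", densities = "integer",
                        sizes = "integer", centroids = "integer",
                        rmsdThreshold = "numeric", iterations = "integer"))

setValidity("ClusterResult", function(object) {
  k <- length(object@sizes)
  if (length(object@centroids) != k) return("one centroid per cluster")
  if (k > 1 && any(diff(object@sizes) > 0)) {
    return("cluster sizes must be non-increasing in rank")
  }
  for (r in seq_len(k)) {
    members <- which(!is.na(object@assignments) & object@assignments == r)
    if (length(members) != object@sizes[r]) {
      return("sizes inconsistent with assignments")
    }
    if (!(object@centroids[r] %in% members)) {
      return("centroid must belong to its cluster")
    }
  }
  TRUE
})
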