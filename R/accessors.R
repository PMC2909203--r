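# Accessors and show methods for the core classes.

#' Construct a ProteinModel
#'
#' @param sequence character vector of one-letter codes, or a single string.
#' @param atoms atom data.frame (see \linkS4class{ProteinModel}).
#' @param label free-text label.
#' @return A validated \linkS4class{ProteinModel}.
#' @export
proteinModel <- function(sequence, atoms, label = "model") {
  if (length(sequence) == 1 && nchar(sequence) > 1) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  new("ProteinModel", sequence = sequence, atoms = atoms, label = label)
}

#' Construct a ModelEnsemble
#'
#' @param models list of \linkS4class{ProteinModel} objects.
#' @return A validated \linkS4class{ModelEnsemble}.
#' @export
modelEnsemble <- function(models) {
  new("ModelEnsemble", models = models, sequence = models[[1]]@sequence)
}

#' @describeIn proteinModel Number of residues.
#' @param x a ProteinModel.
#' @export
nResidues <- function(x) length(x@sequence)

#' @describeIn proteinModel Number of atoms.
#' @export
nAtoms <- function(x) nrow(x@atoms)

#' Number of models in an ensemble
#' @param x a \linkS4class{ModelEnsemble}.
#' @export
nModels <- function(x) length(x@models)

#' List of member models
#' @param x a \linkS4class{ModelEnsemble}.
#' @export
models <- function(x) x@models

#' Atom coordinate matrix
#'
#' @param model a \linkS4class{ProteinModel}.
#' @param atom_names optional filter, e.g. \code{"CA"}.
#' @return numeric matrix (n x 3) in Angstrom.
#' @export
coords <- function(model, atom_names = NULL) {
  a <- model@atoms
  if (!is.null(atom_names)) a <- a[a$atom %in% atom_names, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

#' Calpha coordinates in residue order
#' @param model a \linkS4class{ProteinModel}.
#' @return numeric matrix (n_residues x 3).
#' @export
caCoords <- function(model) {
  a <- model@atoms[model@atoms$atom == "CA", , drop = FALSE]
  as.matrix(a[order(a$resno), c("x", "y", "z")])
}

#' Is the model a CA-only (coarse-grained) trace?
#' @param model a \linkS4class{ProteinModel}.
#' @export
isCoarseGrained <- function(model) all(model@atoms$atom == "CA")

#' Constraint table of a ConstraintSet
#' @param x a \linkS4class{ConstraintSet}.
#' @export
constraints <- function(x) x@constraints

#' Ranked cluster sizes
#' @param x a \linkS4class{ClusterResult}.
#' @export
clusterSizes <- function(x) x@sizes

#' Input-model indices of ranked cluster centroids
#' @param x a \linkS4class{ClusterResult}.
#' @export
centroidIndices <- function(x) x@centroids

setMethod("show", "ProteinModel", function(object) {
  cat(sprintf("ProteinModel '%s': %d residues, %d atoms%s\n",
              object@label, nResidues(object), nAtoms(object),
              if (isCoarseGrained(object)) " (CA-only trace)" else ""))
  cat(" sequence: ",
      paste(utils::head(object@sequence, 40), collapse = ""),
      if (nResidues(object) > 40) "..." else "", "\n", sep = "")
})

setMethod("show", "ModelEnsemble", function(object) {
  cat(sprintf("ModelEnsemble: %d models x %d residues\n",
              nModels(object), length(object@sequence)))
})

setMethod("show", "RapdfTable", function(object) {
  cat(sprintf(
    "RapdfTable: %d atom types, %d pairs, %d bins over [%g, %g] A\n",
    length(object@types), length(object@pairs),
    ncol(object@counts), min(object@breaks), max(object@breaks)))
  cat(sprintf(" trained on %s structures, %d pair observations\n",
              object@meta$n_structures %||% "?", sum(object@counts)))
})

setMethod("show", "ConstraintSet", function(object) {
  cat(sprintf("ConstraintSet (cutoff %g A): %d constraints from '%s'\n",
              object@cutoff, nrow(object@constraints), object@source))
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf(
    "ClusterResult: %d cluster(s), %d outlier(s), %d iteration(s), threshold %g A\n",
    length(object@sizes), sum(is.na(object@assignments)),
    object@iterations, object@rmsdThreshold))
  if (length(object@sizes)) {
    cat(" sizes:", paste(object@sizes, collapse = ", "),
        "| centroids:", paste(object@centroids, collapse = ", "), "\n")
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
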