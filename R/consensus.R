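# Consensus distance extraction from a model ensemble, RAPDF weighting,
# and compilation of cutoff-limited constraint sets.

#' Extract consensus interatomic distances from an ensemble
#'
#' For every atom pair (shared naming, residue separation >= 3), if some
#' sliding window of width \code{window} contains the pair's distance in at
#' least \code{min_support} of the models, a constraint is emitted whose
#' representative distance is the mean of the supporting values and whose
#' support is the maximal count achievable by any window placement. Window
#' placement slides freely (evaluated at the observed values as left
#' edges), which maximizes support without imposing a grid origin.
#'
#' @param ensemble a \linkS4class{ModelEnsemble} with at least
#'   \code{min_support} members.
#' @param window window width in Angstrom.
#' @param min_support minimum number of supporting models.
#' @param representative \code{"mean"} (default) or \code{"median"} of the
#'   supporting values.
#' @return data.frame of unweighted constraints: \code{res_i, atom_i,
#'   res_j, atom_j, distance, support}.
#' @export
extractConsensus <- function(ensemble, window = 0.5, min_support = 4,
                             representative = c("mean", "median")) {
  representative <- match.arg(representative)
  M <- nModels(ensemble)
  if (M < min_support) stop("ensemble smaller than min_support")
  a <- ensemble@models[[1]]@atoms
  n <- nrow(a)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sep <- abs(a$resno[ij[, 1]] - a$resno[ij[, 2]])
  ij <- ij[sep >= 3, , drop = FALSE]
  P <- nrow(ij)
  D <- matrix(0, P, M)
  for (m in seq_len(M)) {
    xyz <- as.matrix(ensemble@models[[m]]@atoms[, c("x", "y", "z")])
    D[, m] <- sqrt(rowSums((xyz[ij[, 1], , drop = FALSE] -
                            xyz[ij[, 2], , drop = FALSE])^2))
  }
  S <- matrix(D[order(row(D), D)], ncol = M, byrow = TRUE)  # row-wise sort
  # count of values in [S[,k], S[,k] + window] for each left-edge k
  best_support <- integer(P)
  best_k <- integer(P)
  best_ub <- integer(P)
  for (k in seq_len(M)) {
    ub <- rowSums(S <= S[, k] + window + 1e-12)
    cnt <- ub - (k - 1L)
    better <- cnt > best_support
    best_support[better] <- cnt[better]
    best_k[better] <- k
    best_ub[better] <- ub[better]
  }
  hit <- best_support >= min_support
  if (!any(hit)) {
    return(data.frame(res_i = integer(0), atom_i = character(0),
                      res_j = integer(0), atom_j = character(0),
                      distance = numeric(0), support = integer(0)))
  }
  rep_fun <- if (representative == "mean") mean else stats::median
  hit_idx <- which(hit)
  dist_rep <- vapply(hit_idx, function(p) {
    rep_fun(S[p, best_k[p]:best_ub[p]])
  }, numeric(1))
  # canonical orientation: i < j under (residue, atom-name) ordering
  ii <- ij[hit, 1]
  jj <- ij[hit, 2]
  swap <- (a$resno[ii] > a$resno[jj]) |
    (a$resno[ii] == a$resno[jj] & a$atom[ii] > a$atom[jj])
  tmp <- ii[swap]; ii[swap] <- jj[swap]; jj[swap] <- tmp
  data.frame(res_i = a$resno[ii], atom_i = a$atom[ii],
             res_j = a$resno[jj], atom_j = a$atom[jj],
             distance = dist_rep, support = as.integer(best_support[hit]),
             stringsAsFactors = FALSE)
}

#' Attach RAPDF scores and weights to consensus constraints
#'
#' Each constraint is scored by the table's log-odds at its binned distance
#' and weighted as \code{support_factor * rank_factor}: the support factor
#' is 1.0 for unanimous support (all models) and 0.8 otherwise, and the
#' rank factor maps the RAPDF-score rank within the list linearly onto
#' (0, 1], best (lowest) score first.
#'
#' @param constraints data.frame from \code{\link{extractConsensus}}.
#' @param table a trained \linkS4class{RapdfTable}.
#' @param ensemble_size number of models in the source ensemble.
#' @param restypes one-letter residue types indexed by residue number (used
#'   for the reduced atom typing).
#' @return the constraints data.frame with added \code{rapdf} and
#'   \code{weight} columns.
#' @export
attachRapdfWeights <- function(constraints, table, ensemble_size, restypes) {
  k <- constraints
  if (nrow(k) == 0) {
    k$rapdf <- numeric(0)
    k$weight <- numeric(0)
    return(k)
  }
  t_i <- atomTypeOf(k$atom_i, restypes[k$res_i])
  t_j <- atomTypeOf(k$atom_j, restypes[k$res_j])
  lo <- lookupLogOdds(table, pairKey(t_i, t_j), k$distance)
  lo[is.na(lo)] <- 0  # outside binned range: neutral score
  support_factor <- ifelse(k$support >= ensemble_size, 1.0, 0.8)
  r <- rank(lo, ties.method = "average")
  n <- nrow(k)
  rank_factor <- (n - r + 1) / n
  k$rapdf <- lo
  k$weight <- support_factor * rank_factor
  k
}

#' Compile cutoff-limited constraint sets
#'
#' Per cutoff, constraints with larger distances are dropped and, where a
#' residue pair carries several atom-pair constraints, the one with the
#' most favorable (lowest) RAPDF score is kept (ties: larger support, then
#' shorter distance, then lexicographic atom names), yielding at most one
#' constraint per residue pair.
#'
#' @param weighted_constraints data.frame from
#'   \code{\link{attachRapdfWeights}}.
#' @param cutoffs maximal-distance cutoffs in Angstrom.
#' @param score_direction \code{"favorable"} keeps the lowest RAPDF score
#'   per residue pair (default); \code{"largest"} keeps the numerically
#'   largest.
#' @param source label recorded on the resulting sets.
#' @return list of \linkS4class{ConstraintSet}, one per cutoff.
#' @export
compileConstraintSets <- function(weighted_constraints,
                                  cutoffs = c(12, 16, 20),
                                  score_direction = c("favorable", "largest"),
                                  source = "ensemble") {
  score_direction <- match.arg(score_direction)
  k <- weighted_constraints
  lapply(cutoffs, function(cut) {
    kk <- k[k$distance <= cut, , drop = FALSE]
    if (nrow(kk)) {
      s <- if (score_direction == "favorable") kk$rapdf else -kk$rapdf
      ord <- order(kk$res_i, kk$res_j, s, -kk$support, kk$distance,
                   kk$atom_i, kk$atom_j)
      kk <- kk[ord, , drop = FALSE]
      kk <- kk[!duplicated(paste(kk$res_i, kk$res_j)), , drop = FALSE]
      rownames(kk) <- NULL
    }
    new("ConstraintSet", cutoff = cut, constraints = kk, source = source)
  })
}

#' Write a constraint set as tab-delimited text
#'
#' @param set a \linkS4class{ConstraintSet}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeConstraintSet <- function(set, path) {
  k <- set@constraints
  hdr <- c(sprintf("#cutoff\t%.17g", set@cutoff),
           sprintf("#source\t%s", set@source),
           "#res_i\tatom_i\tres_j\tatom_j\tdistance\tsupport\trapdf\tweight")
  rows <- sprintf("%d\t%s\t%d\t%s\t%.17g\t%d\t%.17g\t%.17g",
                  k$res_i, k$atom_i, k$res_j, k$atom_j,
                  k$distance, k$support, k$rapdf, k$weight)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a constraint set written by \code{\link{writeConstraintSet}}
#'
#' @param path input path.
#' @return A \linkS4class{ConstraintSet}.
#' @export
readConstraintSet <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  cutoff <- as.numeric(sub("^#cutoff\t", "", hdr[startsWith(hdr, "#cutoff")]))
  source <- sub("^#source\t", "", hdr[startsWith(hdr, "#source")])
  if (!length(body)) {
    k <- data.frame(res_i = integer(0), atom_i = character(0),
                    res_j = integer(0), atom_j = character(0),
                    distance = numeric(0), support = integer(0),
                    rapdf = numeric(0), weight = numeric(0))
  } else {
    f <- strsplit(body, "\t", fixed = TRUE)
    k <- data.frame(res_i = as.integer(vapply(f, `[`, "", 1)),
                    atom_i = vapply(f, `[`, "", 2),
                    res_j = as.integer(vapply(f, `[`, "", 3)),
                    atom_j = vapply(f, `[`, "", 4),
                    distance = as.numeric(vapply(f, `[`, "", 5)),
                    support = as.integer(vapply(f, `[`, "", 6)),
                    rapdf = as.numeric(vapply(f, `[`, "", 7)),
                    weight = as.numeric(vapply(f, `[`, "", 8)),
                    stringsAsFactors = FALSE)
  }
  new("ConstraintSet", cutoff = cutoff, constraints = k, source = source)
}

#' Write CYANA-style upper/lower distance limit lists
#'
#' Writes \code{<stem>.upl} and \code{<stem>.lol} with limits
#' \code{distance +/- window/2}, for interoperability with torsion-angle
#' dynamics programs.
#'
#' @param set a \linkS4class{ConstraintSet}.
#' @param stem output path stem.
#' @param sequence one-letter residue codes indexed by residue number.
#' @param window consensus window width used for the limits.
#' @return invisibly, the two paths.
#' @export
writeCyanaLimits <- function(set, stem, sequence, window = 0.5) {
  if (length(sequence) == 1 && nchar(sequence) > 1) {
    sequence <- strsplit(sequence, "")[[1]]
  }
  k <- set@constraints
  res3 <- vapply(sequence, bio3d::aa123, character(1))
  fmt <- function(lim) {
    sprintf("%4d %-4s %-4s %4d %-4s %-4s %8.2f",
            k$res_i, res3[k$res_i], k$atom_i,
            k$res_j, res3[k$res_j], k$atom_j, lim)
  }
  upl <- paste0(stem, ".upl")
  lol <- paste0(stem, ".lol")
  writeLines(fmt(k$distance + window / 2), upl)
  writeLines(fmt(pmax(k$distance - window / 2, 0)), lol)
  invisible(c(upl, lol))
}
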