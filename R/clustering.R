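# Iterative density clustering of conformation ensembles: cycle between a
# neighbour-count density calculation and removal of low-density outliers,
# then group the survivors by single linkage at the same RMSD threshold
# and pick the densest member of each ranked cluster as its centroid.

#' Pairwise Calpha RMSD matrix of an ensemble
#'
#' @param ensemble a \linkS4class{ModelEnsemble} with >= 2 members.
#' @return symmetric numeric matrix with zero diagonal (Angstrom).
#' @export
pairwiseRmsdMatrix <- function(ensemble) {
  M <- nModels(ensemble)
  if (M < 2) stop("need at least 2 models")
  cas <- lapply(ensemble@models, caCoords)
  out <- matrix(0, M, M)
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      r <- kabschSuperimpose(cas[[i]], cas[[j]])$rmsd
      out[i, j] <- r
      out[j, i] <- r
    }
  }
  out
}

# connected components of the (rmsd <= threshold) graph == single-linkage
# clusters cut at the threshold
linkageComponents <- function(D, threshold) {
  n <- nrow(D)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(D[v, ] <= threshold & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Iterative density clustering with outlier removal
#'
#' Density of a model is its count of neighbours within
#' \code{rmsd_threshold} (itself excluded). All models with density below
#' \code{min_density} are removed, densities are recomputed on the
#' survivors, and the cycle repeats until stable (or \code{max_iter}).
#' Survivors are then clustered by single linkage at the same threshold;
#' clusters are ranked by size (ties: lower mean intra-cluster RMSD, then
#' lowest member index) and each cluster's centroid is its maximal-density
#' member (ties: lowest mean RMSD to the cluster, then lowest index).
#'
#' @param ensemble a \linkS4class{ModelEnsemble} with >= 2 members.
#' @param rmsd_threshold neighbourhood / linkage threshold in Angstrom.
#' @param min_density minimum neighbour count to survive.
#' @param max_iter maximum removal iterations.
#' @param rmsd_matrix optional precomputed matrix from
#'   \code{\link{pairwiseRmsdMatrix}}.
#' @return A \linkS4class{ClusterResult}; when every model is removed the
#'   result has zero clusters (not an error).
#' @export
iterativeDensityCluster <- function(ensemble, rmsd_threshold = 2.0,
                                    min_density = 2, max_iter = 50,
                                    rmsd_matrix = NULL) {
  M <- nModels(ensemble)
  D <- if (is.null(rmsd_matrix)) pairwiseRmsdMatrix(ensemble) else rmsd_matrix
  alive <- seq_len(M)
  iter <- 0L
  repeat {
    if (iter >= max_iter || length(alive) == 0) break
    Dv <- D[alive, alive, drop = FALSE]
    dens <- rowSums(Dv <= rmsd_threshold) - 1L
    drop_ <- dens < min_density
    if (!any(drop_)) break
    alive <- alive[!drop_]
    iter <- iter + 1L
  }
  assignments <- rep(NA_integer_, M)
  densities <- rep(NA_integer_, M)
  if (length(alive) == 0) {
    return(new("ClusterResult", assignments = assignments,
               densities = densities, sizes = integer(0),
               centroids = integer(0), rmsdThreshold = rmsd_threshold,
               iterations = iter))
  }
  Dv <- D[alive, alive, drop = FALSE]
  dens <- as.integer(rowSums(Dv <= rmsd_threshold) - 1L)
  comp <- linkageComponents(Dv, rmsd_threshold)
  ids <- unique(comp)
  size <- vapply(ids, function(c_) sum(comp == c_), integer(1))
  mean_intra <- vapply(ids, function(c_) {
    members <- which(comp == c_)
    if (length(members) < 2) return(0)
    mean(Dv[members, members][upper.tri(matrix(0, length(members),
                                               length(members)))])
  }, numeric(1))
  first_member <- vapply(ids, function(c_) min(alive[comp == c_]), integer(1))
  rank_order <- order(-size, mean_intra, first_member)
  sizes <- size[rank_order]
  centroids <- integer(length(ids))
  for (r in seq_along(rank_order)) {
    c_ <- ids[rank_order[r]]
    members <- which(comp == c_)
    assignments[alive[members]] <- r
    cand_d <- dens[members]
    best <- members[cand_d == max(cand_d)]
    if (length(best) > 1) {
      mr <- vapply(best, function(b) {
        mean(Dv[b, members[members != b], drop = TRUE])
      }, numeric(1))
      best <- best[mr == min(mr)]
    }
    centroids[r] <- alive[min(best)]
  }
  densities[alive] <- dens
  new("ClusterResult", assignments = assignments, densities = densities,
      sizes = as.integer(sizes), centroids = centroids,
      rmsdThreshold = rmsd_threshold, iterations = iter)
}

#' Centroid models of the largest clusters
#'
#' @param result a \linkS4class{ClusterResult}.
#' @param ensemble the clustered \linkS4class{ModelEnsemble}.
#' @param k number of centroids wanted (protocol default 5); fewer are
#'   returned when fewer clusters exist.
#' @return list of centroid \linkS4class{ProteinModel}s in rank order.
#' @export
selectTop <- function(result, ensemble, k = 5) {
  take <- utils::head(result@centroids, k)
  ensemble@models[take]
}

#' Serialize a ClusterResult as tab-delimited text
#'
#' Assignment rows (model, cluster, density) followed by a summary block
#' of ranked sizes and centroid indices.
#'
#' @param result a \linkS4class{ClusterResult}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeClusterResult <- function(result, path) {
  hdr <- c(sprintf("#rmsd_threshold\t%.17g", result@rmsdThreshold),
           sprintf("#iterations\t%d", result@iterations),
           sprintf("#sizes\t%s", paste(result@sizes, collapse = ",")),
           sprintf("#centroids\t%s", paste(result@centroids, collapse = ",")),
           "#model\tcluster\tdensity")
  rows <- sprintf("%d\t%s\t%s", seq_along(result@assignments),
                  ifelse(is.na(result@assignments), "outlier",
                         result@assignments),
                  ifelse(is.na(result@densities), "NA", result@densities))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
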