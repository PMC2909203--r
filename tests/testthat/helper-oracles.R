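# Independent reference implementations used as oracles, plus small
# fixture builders. Everything here is deliberately brute-force and
# separate from the package's code paths.

# Horn/Kearsley quaternion RMSD: independent of the SVD Kabsch path.
quaternionRmsd <- function(X, Y) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- t(Xc) %*% Yc
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(Xc^2) + sum(Yc^2) - 2 * lam) / n))
}

# Exhaustive sliding-window consensus for one pair's distances.
windowOracle <- function(d, window, min_support) {
  best_support <- 0
  best <- NULL
  s <- sort(d)
  for (v in s) {
    inw <- s[s >= v & s <= v + window + 1e-12]
    if (length(inw) > best_support) {
      best_support <- length(inw)
      best <- inw
    }
  }
  if (best_support >= min_support) {
    list(distance = mean(best), support = best_support)
  } else NULL
}

# Full brute-force consensus over an ensemble (all atom pairs, residue
# separation >= 3).
consensusOracle <- function(ensemble, window = 0.5, min_support = 4) {
  a <- ensemble@models[[1]]@atoms
  n <- nrow(a)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(a$resno[i] - a$resno[j]) < 3) next
      d <- vapply(ensemble@models, function(m) {
        sqrt(sum((as.numeric(m@atoms[i, c("x", "y", "z")]) -
                  as.numeric(m@atoms[j, c("x", "y", "z")]))^2))
      }, numeric(1))
      hit <- windowOracle(d, window, min_support)
      if (!is.null(hit)) {
        rows[[length(rows) + 1]] <- data.frame(
          res_i = a$resno[i], atom_i = a$atom[i],
          res_j = a$resno[j], atom_j = a$atom[j],
          distance = hit$distance, support = hit$support,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(res_i = integer(0), atom_i = character(0),
               res_j = integer(0), atom_j = character(0),
               distance = numeric(0), support = integer(0))
}

# Literal-recompute reference for iterative density clustering on a
# distance matrix.
clusterOracle <- function(D, threshold, min_density = 2, max_iter = 50) {
  M <- nrow(D)
  alive <- seq_len(M)
  iter <- 0
  repeat {
    if (iter >= max_iter || length(alive) == 0) break
    dens <- sapply(alive, function(i) {
      sum(D[i, alive] <= threshold) - 1
    })
    if (all(dens >= min_density)) break
    alive <- alive[dens >= min_density]
    iter <- iter + 1
  }
  if (length(alive) == 0) {
    return(list(alive = integer(0), clusters = list(), centroids = integer(0)))
  }
  dens <- sapply(alive, function(i) sum(D[i, alive] <= threshold) - 1)
  # single linkage components by repeated expansion
  comp <- rep(0, length(alive))
  cur <- 0
  for (s in seq_along(alive)) {
    if (comp[s] > 0) next
    cur <- cur + 1
    comp[s] <- cur
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (u in which(comp == cur)) {
        for (v in seq_along(alive)) {
          if (comp[v] == 0 && D[alive[u], alive[v]] <= threshold) {
            comp[v] <- cur
            changed <- TRUE
          }
        }
      }
    }
  }
  clusters <- lapply(seq_len(cur), function(c_) alive[comp == c_])
  size <- lengths(clusters)
  mintra <- sapply(clusters, function(m) {
    if (length(m) < 2) return(0)
    mean(D[m, m][upper.tri(D[m, m])])
  })
  firstm <- sapply(clusters, min)
  ord <- order(-size, mintra, firstm)
  clusters <- clusters[ord]
  centroids <- sapply(clusters, function(m) {
    dd <- sapply(m, function(i) sum(D[i, alive] <= threshold) - 1)
    cand <- m[dd == max(dd)]
    if (length(cand) > 1) {
      mr <- sapply(cand, function(b) mean(D[b, setdiff(m, b)]))
      cand <- cand[mr == min(mr)]
    }
    min(cand)
  })
  list(alive = alive, clusters = clusters, centroids = centroids)
}

# Brute-force soft-sphere clash penalty (double loop).
vdwOracle <- function(xyz, radii, resno) {
  e <- 0
  n <- nrow(xyz)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(resno[i] - resno[j]) < 2) next
      s <- 0.9 * (radii[i] + radii[j])
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d < s) e <- e + (s - d)^2
    }
  }
  e
}

# CA-only model with given per-residue coordinates.
caModel <- function(xyz, restype = NULL, label = "ca") {
  n <- nrow(xyz)
  if (is.null(restype)) restype <- rep("A", n)
  proteinModel(restype,
               data.frame(atom = "CA", element = "C",
                          resno = seq_len(n), restype = restype,
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                          stringsAsFactors = FALSE),
               label = label)
}

# Ensemble of CA-only models with per-model coordinate list.
caEnsemble <- function(xyz_list, restype = NULL) {
  modelEnsemble(lapply(seq_along(xyz_list), function(i) {
    caModel(xyz_list[[i]], restype, label = sprintf("m%d", i))
  }))
}

# Random rigid transform.
randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c_ <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d), 2 * (b * d + a * c_),
           2 * (b * c_ + a * d), a^2 - b^2 + c_^2 - d^2, 2 * (c_ * d - a * b),
           2 * (b * d - a * c_), 2 * (c_ * d + a * b), a^2 - b^2 - c_^2 + d^2),
         3, 3, byrow = TRUE)
}

# Uniform flat RAPDF table (all log-odds zero) over the package's typing.
flatRapdfTable <- function() {
  tr <- makeRapdfTraining(5, seed = 1)
  tab <- trainRapdf(tr[1])
  tab@logOdds[] <- 0
  tab
}
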