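# RAPDF: residue-specific all-atom probability discriminatory function,
# plus the three auxiliary decoy-filter terms (soft-sphere van der Waals,
# hydrophobic compactness, screened electrostatics).
#
# Atom typing is reduced: backbone N/CA/C/O, CB typed by residue class,
# and any further sidechain atom typed by residue class. This keeps the
# table trainable from a miniature corpus while preserving the residue
# specificity that gives the score its discriminatory power.

RAPDF_CLASSES <- c("hyd", "pol", "pos", "neg")
RAPDF_TYPES <- c("N", "CA", "C", "O",
                 paste0("CB_", RAPDF_CLASSES), paste0("SC_", RAPDF_CLASSES))

atomTypeOf <- function(atom_name, restype) {
  cls <- residueClass(restype)
  ifelse(atom_name %in% c("N", "CA", "C", "O"), atom_name,
         ifelse(atom_name == "CB", paste0("CB_", cls), paste0("SC_", cls)))
}

pairKey <- function(t1, t2) {
  paste(pmin(t1, t2), pmax(t1, t2), sep = "|")
}

allPairKeys <- function(types = RAPDF_TYPES) {
  idx <- which(upper.tri(matrix(0, length(types), length(types)), diag = TRUE),
               arr.ind = TRUE)
  sort(unique(pairKey(types[idx[, 1]], types[idx[, 2]])))
}

# Qualifying atom pairs of one model: residue separation >= min_sep and
# distance within [r_min, r_max). Returns pair keys and distances.
modelPairObservations <- function(model, r_min, r_max, min_sep = 3) {
  a <- model@atoms
  n <- nrow(a)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sep <- abs(a$resno[ij[, 1]] - a$resno[ij[, 2]])
  ij <- ij[sep >= min_sep, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- sqrt(rowSums((xyz[ij[, 1], , drop = FALSE] -
                     xyz[ij[, 2], , drop = FALSE])^2))
  inr <- d >= r_min & d < r_max
  ij <- ij[inr, , drop = FALSE]
  d <- d[inr]
  ty <- atomTypeOf(a$atom, a$restype)
  list(key = pairKey(ty[ij[, 1]], ty[ij[, 2]]), dist = d)
}

# Bayesian log-odds from a pair x bin count matrix:
# -ln[ P(bin|pair) / P(bin) ] with additive smoothing on both the
# conditional and the marginal.
rapdfLogOdds <- function(counts, pseudocount) {
  sm <- counts + pseudocount
  p_cond <- sm / rowSums(sm)
  marg <- colSums(sm)
  p_marg <- marg / sum(marg)
  -log(sweep(p_cond, 2, p_marg, "/"))
}

#' Train a RAPDF distance log-odds table
#'
#' Accumulates atom-pair distance counts (residue separation >= 3) over a
#' training corpus, smooths with an additive pseudocount, and stores
#' \code{log_odds(pair, bin) = -ln[P(bin|pair) / P(bin)]} where
#' \code{P(bin)} is the marginal over all pairs. Lower scores are more
#' native-like.
#'
#' @param structures list of \linkS4class{ProteinModel} objects.
#' @param bin_width distance bin width in Angstrom.
#' @param r_min,r_max distance range (half-open bins over [r_min, r_max)).
#' @param pseudocount additive smoothing constant per (pair, bin).
#' @return A \linkS4class{RapdfTable}.
#' @export
trainRapdf <- function(structures, bin_width = 1.0, r_min = 3.0,
                       r_max = 20.0, pseudocount = 1) {
  if (length(structures) < 1) stop("empty training set")
  breaks <- seq(r_min, r_max, by = bin_width)
  nb <- length(breaks) - 1
  pairs <- allPairKeys()
  counts <- matrix(0L, length(pairs), nb,
                   dimnames = list(pairs, NULL))
  for (s in structures) {
    obs <- modelPairObservations(s, r_min, r_max)
    if (!length(obs$dist)) next
    bin <- pmin(floor((obs$dist - r_min) / bin_width) + 1, nb)
    tab <- table(factor(obs$key, levels = pairs), factor(bin, levels = 1:nb))
    counts <- counts + unclass(tab)
  }
  storage.mode(counts) <- "integer"
  log_odds <- rapdfLogOdds(counts, pseudocount)
  new("RapdfTable", types = RAPDF_TYPES, pairs = pairs, breaks = breaks,
      counts = counts, logOdds = log_odds, pseudocount = pseudocount,
      meta = list(n_structures = length(structures),
                  labels = vapply(structures, function(s) s@label,
                                  character(1)),
                  min_sep = 3))
}

# log-odds value for given pair keys and distances (NA outside range).
lookupLogOdds <- function(table, key, dist) {
  r_min <- table@breaks[1]
  r_max <- table@breaks[length(table@breaks)]
  bw <- table@breaks[2] - table@breaks[1]
  bin <- floor((dist - r_min) / bw) + 1
  bin[dist < r_min | dist >= r_max] <- NA
  pi <- match(key, table@pairs)
  out <- rep(NA_real_, length(key))
  ok <- !is.na(bin) & !is.na(pi)
  out[ok] <- table@logOdds[cbind(pi[ok], bin[ok])]
  out
}

#' Score a model with a RAPDF table and the auxiliary filter terms
#'
#' @param model a \linkS4class{ProteinModel}.
#' @param table a trained \linkS4class{RapdfTable}.
#' @return list with elements \code{rapdf_raw} (sum of log-odds over
#'   qualifying pairs), \code{rapdf_normalized} (\code{100 * raw /
#'   n_contacts}; \code{NA} when no contacts), \code{n_contacts},
#'   \code{vdw_energy}, \code{compactness}, \code{electrostatics}.
#' @export
scoreModel <- function(model, table) {
  r_min <- table@breaks[1]
  r_max <- table@breaks[length(table@breaks)]
  obs <- modelPairObservations(model, r_min, r_max,
                               min_sep = table@meta$min_sep %||% 3)
  lo <- lookupLogOdds(table, obs$key, obs$dist)
  lo <- lo[!is.na(lo)]
  n <- length(lo)
  raw <- sum(lo)
  list(rapdf_raw = raw,
       rapdf_normalized = if (n > 0) 100 * raw / n else NA_real_,
       n_contacts = n,
       vdw_energy = vdwTerm(model),
       compactness = compactnessTerm(model),
       electrostatics = electrostaticsTerm(model))
}

#' Correct-topology flag from the normalized RAPDF score
#'
#' Scores strictly better (lower) than -55 have been associated with
#' correct overall topology; the absolute calibration depends on the
#' normalization and training corpus, so treat the flag as indicative.
#'
#' @param rapdf_normalized normalized RAPDF score.
#' @param threshold decision threshold (default -55).
#' @return logical; \code{TRUE} iff score < threshold (strict).
#' @export
flagCorrectTopology <- function(rapdf_normalized, threshold = -55) {
  if (is.na(rapdf_normalized)) stop("normalized score undefined")
  rapdf_normalized < threshold
}

#' Soft-sphere van der Waals clash penalty
#'
#' \code{sum over pairs with residue separation >= 2 of
#' max(0, 0.9 * (r_i + r_j) - d_ij)^2} with element radii C 1.70, N 1.55,
#' O 1.52 Angstrom.
#'
#' @param model a \linkS4class{ProteinModel}.
#' @return non-negative penalty (dimensionless).
#' @export
vdwTerm <- function(model) {
  a <- model@atoms
  radii <- unname(VDW_RADII[a$element])
  radii[is.na(radii)] <- VDW_RADII[["C"]]
  .soft_vdw(as.matrix(a[, c("x", "y", "z")]), radii, as.integer(a$resno))
}

#' Hydrophobic compactness factor
#'
#' Radius of gyration of hydrophobic-residue CB atoms divided by the radius
#' of gyration of all CA atoms; a buried hydrophobic core gives a low
#' ratio.
#'
#' @param model a \linkS4class{ProteinModel}.
#' @return positive ratio, or \code{NA} when the model has no hydrophobic
#'   CB atoms.
#' @export
compactnessTerm <- function(model) {
  a <- model@atoms
  hyd <- a[a$atom == "CB" & a$restype %in% HYDROPHOBIC_AA, , drop = FALSE]
  if (nrow(hyd) == 0) return(NA_real_)
  rg <- function(m) {
    m <- as.matrix(m[, c("x", "y", "z")])
    ctr <- colMeans(m)
    sqrt(mean(rowSums(sweep(m, 2, ctr)^2)))
  }
  rg(hyd) / rg(a[a$atom == "CA", , drop = FALSE])
}

#' Screened electrostatics term
#'
#' Unit charges (+1 on K/R, -1 on D/E) placed on CB atoms, with a
#' distance-dependent dielectric (epsilon = 4d):
#' \code{sum q_i q_j / (4 d_ij^2)} over charged residue pairs.
#'
#' @param model a \linkS4class{ProteinModel}.
#' @return energy (dimensionless); 0 when fewer than two charged residues.
#' @export
electrostaticsTerm <- function(model) {
  a <- model@atoms
  ch <- a[a$atom == "CB" &
            a$restype %in% c(POSITIVE_AA, NEGATIVE_AA), , drop = FALSE]
  if (nrow(ch) < 2) return(0)
  q <- ifelse(ch$restype %in% POSITIVE_AA, 1, -1)
  xyz <- as.matrix(ch[, c("x", "y", "z")])
  ij <- which(upper.tri(matrix(0, nrow(ch), nrow(ch))), arr.ind = TRUE)
  d2 <- rowSums((xyz[ij[, 1], , drop = FALSE] -
                 xyz[ij[, 2], , drop = FALSE])^2)
  sum(q[ij[, 1]] * q[ij[, 2]] / (4 * d2))
}

#' Write a RAPDF table as tab-delimited text
#'
#' Header lines (\code{#key value}) carry the training metadata; data rows
#' are \code{pair, bin_lo, bin_hi, count, log_odds}. Numeric fields use
#' full precision so the round-trip through \code{\link{readRapdfTable}}
#' is bit-exact.
#'
#' @param table a \linkS4class{RapdfTable}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeRapdfTable <- function(table, path) {
  hdr <- c(sprintf("#n_structures\t%d", table@meta$n_structures),
           sprintf("#pseudocount\t%.17g", table@pseudocount),
           sprintf("#min_sep\t%d", table@meta$min_sep %||% 3),
           sprintf("#labels\t%s", paste(table@meta$labels, collapse = ",")),
           "#pair\tbin_lo\tbin_hi\tcount\tlog_odds")
  nb <- ncol(table@counts)
  rows <- character(length(table@pairs) * nb)
  k <- 1
  for (p in seq_along(table@pairs)) {
    for (b in seq_len(nb)) {
      rows[k] <- sprintf("%s\t%.17g\t%.17g\t%d\t%.17g",
                         table@pairs[p], table@breaks[b], table@breaks[b + 1],
                         table@counts[p, b], table@logOdds[p, b])
      k <- k + 1
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a RAPDF table written by \code{\link{writeRapdfTable}}
#'
#' @param path input path.
#' @return A \linkS4class{RapdfTable}.
#' @export
readRapdfTable <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  getmeta <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, "\t"))]
    sub(paste0("^#", key, "\t"), "", ln[1])
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  pair <- vapply(f, `[`, character(1), 1)
  lo <- as.numeric(vapply(f, `[`, character(1), 2))
  hi <- as.numeric(vapply(f, `[`, character(1), 3))
  cnt <- as.integer(vapply(f, `[`, character(1), 4))
  lod <- as.numeric(vapply(f, `[`, character(1), 5))
  pairs <- unique(pair)
  breaks <- c(sort(unique(lo)), max(hi))
  nb <- length(breaks) - 1
  counts <- matrix(0L, length(pairs), nb, dimnames = list(pairs, NULL))
  logOdds <- matrix(0, length(pairs), nb, dimnames = list(pairs, NULL))
  pi <- match(pair, pairs)
  bi <- match(lo, breaks[-length(breaks)])
  counts[cbind(pi, bi)] <- cnt
  logOdds[cbind(pi, bi)] <- lod
  new("RapdfTable", types = RAPDF_TYPES, pairs = pairs, breaks = breaks,
      counts = counts, logOdds = logOdds,
      pseudocount = as.numeric(getmeta("pseudocount")),
      meta = list(n_structures = as.integer(getmeta("n_structures")),
                  labels = strsplit(getmeta("labels"), ",")[[1]],
                  min_sep = as.integer(getmeta("min_sep"))))
}
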