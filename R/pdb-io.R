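# PDB-dialect and FASTA input/output.
#
# The dialect is deliberately narrow: single-chain ATOM records only
# (wwPDB v3.3 fixed columns). HETATM records, insertion codes and
# multi-chain files are rejected with a clear error, since the pipeline
# operates on single protein chains.

#' Read a single-chain PDB file into a ProteinModel
#'
#' Parsing is backed by \code{bio3d::read.pdb}. Alternate locations keep the
#' highest-occupancy copy (tie: first listed). Residue numbering must be
#' contiguous; files not starting at 1 are shifted so the first residue is 1.
#' A CA-only trace is accepted and can be detected with
#' \code{\link{isCoarseGrained}}.
#'
#' @param path path to a PDB file containing ATOM records.
#' @param label model label; defaults to the file name.
#' @return A \linkS4class{ProteinModel}.
#' @export
readPdbModel <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                          rm.alt = FALSE, verbose = FALSE))
  at <- pdb$atom
  if (any(at$type == "HETATM")) stop("HETATM records are not supported")
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  if (length(unique(at$chain[!is.na(at$chain)])) > 1) {
    stop("multi-chain files are not supported")
  }
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes are not supported")
  }
  # alternate locations: keep highest occupancy, tie -> first listed
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$resno, at$elety)
  keep <- !logical(nrow(at))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    best <- idx[which.max(occ[idx])]
    keep[setdiff(idx, best)] <- FALSE
  }
  at <- at[keep, , drop = FALSE]
  resno <- at$resno
  ures <- unique(resno)
  if (!all(diff(ures) == 1)) {
    stop("non-contiguous residue numbering")
  }
  shift <- ures[1] - 1L
  resno <- resno - shift
  ures <- ures - shift
  aa1 <- suppressWarnings(bio3d::aa321(at$resid[match(ures, resno)]))
  if (any(aa1 == "X" | is.na(aa1))) {
    bad <- unique(at$resid[match(ures, resno)][aa1 == "X" | is.na(aa1)])
    stop("unknown residue type(s): ", paste(bad, collapse = ", "))
  }
  no_ca <- setdiff(ures, resno[at$elety == "CA"])
  if (length(no_ca)) {
    stop("missing CA for residue(s): ", paste(utils::head(no_ca, 5),
                                              collapse = ", "))
  }
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- elementOf(at$elety[is.na(elem) | elem == ""])
  tab <- data.frame(atom = at$elety, element = elem, resno = resno,
                    restype = aa1[match(resno, ures)],
                    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE)
  proteinModel(aa1, tab, label = label)
}

formatAtomLines <- function(model, serial_offset = 0L) {
  a <- model@atoms
  n <- nrow(a)
  serial <- seq_len(n) + serial_offset
  if (max(serial) > 99999) {
    stop("atom serial number overflow (> 99999)")
  }
  name4 <- ifelse(nchar(a$atom) >= 4, sprintf("%-4s", a$atom),
                  sprintf(" %-3s", a$atom))
  res3 <- vapply(a$restype, bio3d::aa123, character(1))
  sprintf("ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, res3, "A", a$resno, a$x, a$y, a$z, 1, 0,
          a$element)
}

#' Write a ProteinModel as fixed-column PDB ATOM records
#'
#' Coordinates are written to 3 decimals (columns 31-54), occupancy 1.00 and
#' B-factor 0.00; chain identifier A. Round-trips through
#' \code{\link{readPdbModel}} exactly at that precision.
#'
#' @param model a \linkS4class{ProteinModel}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writePdbModel <- function(model, path) {
  lines <- c(formatAtomLines(model), "TER", "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a ModelEnsemble as a multi-model PDB (MODEL/ENDMDL)
#'
#' @param ensemble a \linkS4class{ModelEnsemble}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeEnsemblePdb <- function(ensemble, path) {
  blocks <- lapply(seq_len(nModels(ensemble)), function(i) {
    c(sprintf("MODEL     %4d", i),
      formatAtomLines(ensemble@models[[i]]),
      "ENDMDL")
  })
  writeLines(c(unlist(blocks), "END"), path)
  invisible(path)
}

#' Read a multi-model PDB file into a ModelEnsemble
#'
#' @param path path to a MODEL/ENDMDL multi-model PDB file.
#' @return A \linkS4class{ModelEnsemble}.
#' @export
readEnsemblePdb <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0) {
    return(modelEnsemble(list(readPdbModel(path))))
  }
  if (length(starts) != length(ends)) stop("unbalanced MODEL/ENDMDL records")
  models <- lapply(seq_along(starts), function(i) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp))
    writeLines(c(lines[(starts[i] + 1):(ends[i] - 1)], "END"), tmp)
    readPdbModel(tmp, label = sprintf("%s#%d", basename(path), i))
  })
  modelEnsemble(models)
}

#' Read the first sequence of a FASTA file
#'
#' @param path FASTA file path.
#' @return one-letter sequence as a single character string.
#' @export
readFastaSequence <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) < 1) stop("no sequences in ", path)
  as.character(ss[[1]])
}

#' Write a sequence to FASTA
#'
#' @param sequence character string or vector of one-letter codes.
#' @param path output path.
#' @param name FASTA header.
#' @return invisibly, the path.
#' @export
writeFastaSequence <- function(sequence, path, name = "seq") {
  if (length(sequence) > 1) sequence <- paste(sequence, collapse = "")
  ss <- Biostrings::AAStringSet(sequence)
  names(ss) <- name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' The 212-residue PDCD10 (CCM3) sequence packaged with ConsensusFold
#'
#' Returns the full-length PDCD10 protein sequence (212 amino acids; 21
#' lysines, 21 glutamates; the alpha5/loop lysine cluster at positions
#' 169, 172, 179, 183 and 186) shipped under \code{inst/extdata}.
#'
#' @return one-letter sequence string of length 212.
#' @export
pdcd10Sequence <- function() {
  readFastaSequence(system.file("extdata", "pdcd10.fasta",
                                package = "ConsensusFold", mustWork = TRUE))
}
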