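# End-to-end orchestration of the two-round consensus refinement protocol:
# consensus distances -> RAPDF weighting -> three cutoff constraint sets ->
# restrained torsion-space building -> sequential four-term filter ->
# relaxation -> iterative density clustering -> top-5 centroids, then a
# second consensus round seeded by those centroids.

#' Pipeline configuration
#'
#' Houses every protocol parameter: the 0.5 Angstrom consensus window,
#' 4-of-5 support quorum, 12/16/20 Angstrom cutoffs, 50 rounds of 20
#' models per constraint set (3000 conformations per consensus round),
#' the keep-half filter, clustering threshold, 5 centroids, and 2
#' consensus rounds.
#'
#' @param window consensus window width, Angstrom.
#' @param min_support consensus support quorum (capped at ensemble size).
#' @param cutoffs maximal-distance cutoffs, Angstrom.
#' @param rounds build rounds per constraint set.
#' @param models_per_round models per build round.
#' @param keep_fraction filter survivor fraction.
#' @param cluster_threshold clustering RMSD threshold, Angstrom.
#' @param min_density minimum neighbour count for a model to survive
#'   outlier removal during clustering.
#' @param top_k centroids carried forward.
#' @param consensus_rounds number of consensus rounds (>= 1).
#' @param steps basin-hopping steps per model.
#' @param t_start,t_end hop-acceptance temperature schedule.
#' @param iters_hop,iters_final gradient-minimization budgets per hop and
#'   for the final polish.
#' @param relax_steps Cartesian relaxation steps per surviving model.
#' @param seed master seed; every stage derives its stream from it.
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(window = 0.5, min_support = 4,
                           cutoffs = c(12, 16, 20), rounds = 50,
                           models_per_round = 20, keep_fraction = 0.5,
                           cluster_threshold = 2.0, min_density = 2,
                           top_k = 5,
                           consensus_rounds = 2, steps = 30,
                           t_start = 30, t_end = 1, iters_hop = 50,
                           iters_final = 300, relax_steps = 30,
                           seed = 1) {
  stopifnot(window > 0, min_support >= 1, length(cutoffs) >= 1,
            rounds >= 1, models_per_round >= 1,
            keep_fraction > 0, keep_fraction <= 1, top_k >= 0,
            consensus_rounds >= 1)
  structure(list(window = window, min_support = min_support,
                 cutoffs = cutoffs, rounds = rounds,
                 models_per_round = models_per_round,
                 keep_fraction = keep_fraction,
                 cluster_threshold = cluster_threshold,
                 min_density = min_density, top_k = top_k,
                 consensus_rounds = consensus_rounds, steps = steps,
                 t_start = t_start, t_end = t_end, iters_hop = iters_hop,
                 iters_final = iters_final,
                 relax_steps = relax_steps, seed = seed),
            class = "pipelineConfig")
}

#' Planned stage counts without building any model
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return list of class \code{"pipelineReport"} with
#'   \code{conformations_per_round} (= number of cutoffs x rounds x
#'   models per round), \code{filtered_per_round}, and totals over the
#'   configured consensus rounds.
#' @export
dryRun <- function(config = pipelineConfig()) {
  gen <- length(config$cutoffs) * config$rounds * config$models_per_round
  filt <- ceiling(gen * config$keep_fraction)
  structure(list(dry_run = TRUE,
                 conformations_per_round = gen,
                 filtered_per_round = filt,
                 total_conformations = gen * config$consensus_rounds,
                 consensus_rounds = config$consensus_rounds,
                 config = config),
            class = "pipelineReport")
}

stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full consensus refinement protocol
#'
#' Per consensus round: extract consensus distances from the current
#' ensemble, weight them by RAPDF score and support, compile one
#' constraint set per cutoff, build \code{rounds x models_per_round}
#' models per set by restrained annealing, filter half with the
#' sequential four-term filter, relax the survivors, cluster them by
#' iterative density clustering, and carry the top-\code{top_k} cluster
#' centroids into the next round. The final round's centroids are the
#' tertiary structure predictions.
#'
#' @param initial_ensemble a \linkS4class{ModelEnsemble} of candidate
#'   models for one sequence (server models or equivalents).
#' @param config a \code{\link{pipelineConfig}}.
#' @param table a trained \linkS4class{RapdfTable}; by default trained on
#'   the packaged synthetic corpus (deterministic in \code{seed}).
#' @param prior a \linkS4class{TorsionPrior}; same default.
#' @param n_training corpus size for the default table/prior.
#' @return list of class \code{"pipelineReport"}: \code{final_models}
#'   (list of ProteinModel), \code{rounds} (per-round stage counts),
#'   \code{centroid_scores}, \code{config}, \code{seed}.
#' @export
runPipeline <- function(initial_ensemble, config = pipelineConfig(),
                        table = NULL, prior = NULL, n_training = 12) {
  if (is.null(table) || is.null(prior)) {
    training <- makeRapdfTraining(n_training, seed = config$seed)
    if (is.null(table)) table <- trainRapdf(training)
    if (is.null(prior)) prior <- trainTorsionPrior(training)
  }
  ens <- initial_ensemble
  round_reports <- list()
  for (cr in seq_len(config$consensus_rounds)) {
    ms <- min(config$min_support, nModels(ens))
    cons <- extractConsensus(ens, window = config$window, min_support = ms)
    if (nrow(cons) == 0) stop("consensus stage produced no constraints")
    stageLog("consensus", "round %d: %d consensus distances (quorum %d/%d)",
             cr, nrow(cons), ms, nModels(ens))
    weighted <- attachRapdfWeights(cons, table, nModels(ens), ens@sequence)
    sets <- compileConstraintSets(weighted, cutoffs = config$cutoffs,
                                  source = sprintf("round%d", cr))
    set_sizes <- vapply(sets, function(s) nrow(s@constraints), integer(1))
    stageLog("constraints", "set sizes at cutoffs %s: %s",
             paste(config$cutoffs, collapse = "/"),
             paste(set_sizes, collapse = "/"))
    built <- list()
    for (si in seq_along(sets)) {
      bc <- buildConfig(rounds = config$rounds,
                        models_per_round = config$models_per_round,
                        t_start = config$t_start, t_end = config$t_end,
                        steps = config$steps,
                        iters_hop = config$iters_hop,
                        iters_final = config$iters_final,
                        seed = (config$seed * 131071 + cr * 257 + si) %%
                          2147483647L)
      be <- buildConformations(ens@sequence, sets[[si]], prior, bc)
      built <- c(built, models(be))
    }
    generated <- modelEnsemble(built)
    stageLog("build", "round %d: %d conformations", cr, nModels(generated))
    filtered <- sequentialFilter(generated, table,
                                 keep_fraction = config$keep_fraction)
    stageLog("filter", "round %d: %d survive (%s removed)", cr,
             nModels(filtered),
             paste(attr(filtered, "removed_per_stage"), collapse = "+"))
    relaxed <- modelEnsemble(lapply(models(filtered), relaxModel,
                                    steps = config$relax_steps))
    clus <- iterativeDensityCluster(relaxed,
                                    rmsd_threshold = config$cluster_threshold,
                                    min_density = config$min_density)
    if (length(clus@sizes) == 0) {
      stop("clustering stage removed every conformation")
    }
    stageLog("cluster", "round %d: %d cluster(s), sizes %s", cr,
             length(clus@sizes), paste(clus@sizes, collapse = ","))
    cents <- selectTop(clus, relaxed, k = config$top_k)
    if (length(cents) == 0) stop("centroid selection produced no models")
    round_reports[[cr]] <- list(
      consensus_distances = nrow(cons),
      constraints_per_set = set_sizes,
      conformations_generated = nModels(generated),
      conformations_filtered = nModels(filtered),
      clusters = length(clus@sizes),
      cluster_sizes = clus@sizes,
      centroids = length(cents))
    ens <- modelEnsemble(cents)
  }
  scores <- lapply(models(ens), scoreModel, table = table)
  structure(list(dry_run = FALSE,
                 final_models = models(ens),
                 rounds = round_reports,
                 centroid_scores = scores,
                 conformations_per_round =
                   length(config$cutoffs) * config$rounds *
                     config$models_per_round,
                 config = config, seed = config$seed),
            class = "pipelineReport")
}

#' @export
print.pipelineReport <- function(x, ...) {
  if (isTRUE(x$dry_run)) {
    cat(sprintf(
      "Pipeline dry run: %d conformations per consensus round (%d rounds, %d total), %d kept per round\n",
      x$conformations_per_round, x$consensus_rounds,
      x$total_conformations, x$filtered_per_round))
    return(invisible(x))
  }
  cat(sprintf("Pipeline report (seed %d): %d consensus round(s)\n",
              x$seed, length(x$rounds)))
  for (cr in seq_along(x$rounds)) {
    r <- x$rounds[[cr]]
    cat(sprintf(
      " round %d: %d consensus distances; sets %s; built %d; filtered %d; %d cluster(s); %d centroid(s)\n",
      cr, r$consensus_distances,
      paste(r$constraints_per_set, collapse = "/"),
      r$conformations_generated, r$conformations_filtered,
      r$clusters, r$centroids))
  }
  cat(sprintf(" final models: %d\n", length(x$final_models)))
  invisible(x)
}

#' Write a pipeline report as tab-delimited text
#'
#' @param report a \code{"pipelineReport"}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writePipelineReport <- function(report, path) {
  lines <- c(sprintf("seed\t%d", report$seed %||% report$config$seed))
  for (cr in seq_along(report$rounds)) {
    r <- report$rounds[[cr]]
    lines <- c(lines,
               sprintf("round%d.consensus_distances\t%d", cr,
                       r$consensus_distances),
               sprintf("round%d.constraints_per_set\t%s", cr,
                       paste(r$constraints_per_set, collapse = ",")),
               sprintf("round%d.generated\t%d", cr,
                       r$conformations_generated),
               sprintf("round%d.filtered\t%d", cr,
                       r$conformations_filtered),
               sprintf("round%d.clusters\t%d", cr, r$clusters))
  }
  writeLines(lines, path)
  invisible(path)
}
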