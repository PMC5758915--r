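#' Pipeline configuration
#'
#' Collects every tunable of the SHAPE-directed folding pipeline. The
#' reactivity-estimation sample defaults to 10000 structures and the
#' clustering sample to 1000. The two samples are drawn fresh with
#' independent seeds derived from \code{seed} (recorded in the result).
#'
#' @param restraint a \linkS4class{RestraintParams}.
#' @param params a \linkS4class{NearestNeighborParams}.
#' @param consts a \linkS4class{ThermoConstants}.
#' @param dists a \linkS4class{ReactivityDistributions}.
#' @param reactivitySample Boltzmann sample size for reactivity
#'   estimation.
#' @param clusterSample Boltzmann sample size for clustering.
#' @param kMax largest number of clusters considered.
#' @param mode "ensemble" (clusters, centroids, populations) or "single"
#'   (maximum expected accuracy structure).
#' @param rcalcMode reactivity estimation mode, "expectation" or
#'   "montecarlo".
#' @param gamma MEA pair weight (single mode).
#' @param minPopulation flagging floor for small clusters.
#' @param seed base RNG seed; the reactivity sample uses \code{seed} and
#'   the clustering sample \code{seed + 1}.
#' @return a validated configuration list.
#' @export
foldConfig <- function(restraint = restraintParams(),
                       params = loadParams(),
                       consts = thermoConstants(),
                       dists = reactivityDistributions(),
                       reactivitySample = 10000L,
                       clusterSample = 1000L,
                       kMax = 10L,
                       mode = c("ensemble", "single"),
                       rcalcMode = c("expectation", "montecarlo"),
                       gamma = 1,
                       minPopulation = 0.02,
                       seed = 1L) {
  if (reactivitySample < 1L || clusterSample < 1L)
    stop("sample sizes must be >= 1")
  structure(list(restraint = restraint, params = params, consts = consts,
                 dists = dists,
                 reactivitySample = as.integer(reactivitySample),
                 clusterSample = as.integer(clusterSample),
                 kMax = as.integer(kMax), mode = match.arg(mode),
                 rcalcMode = match.arg(rcalcMode), gamma = gamma,
                 minPopulation = minPopulation, seed = as.integer(seed),
                 seeds = c(reactivity = as.integer(seed),
                           cluster = as.integer(seed) + 1L)),
            class = "foldConfig")
}

#' SHAPE-directed ensemble prediction
#'
#' Runs the full refinement procedure exactly once (a single pass; a
#' second refinement pass over-fits the probing data and degrades
#' accuracy, so no iteration option exists):
#' \enumerate{
#'   \item unrestrained partition function;
#'   \item Boltzmann sample of \code{reactivitySample} structures;
#'   \item per-nucleotide estimated reactivities Rcalc from the sample;
#'   \item pseudo-free-energy bonuses from the Rexp/Rcalc mismatch and a
#'     restrained partition function;
#'   \item (single mode) maximum expected accuracy structure; or
#'   \item restrained Boltzmann sample of \code{clusterSample} structures;
#'   \item clustering with automatic choice of the number of clusters;
#'   \item centroid structures with populations.
#' }
#' With \code{shape = NULL}, or a profile that is entirely missing, the
#' restraint is zero and the run reduces to the no-data control
#' (stochastic sampling followed by clustering).
#'
#' @param seq RNA sequence string (or a single-record FASTA path).
#' @param shape a \linkS4class{ReactivityProfile}, a SHAPE file path, or
#'   NULL for the no-data control.
#' @param config a \code{\link{foldConfig}}.
#' @return an \linkS4class{EnsembleModel} (ensemble mode) or a
#'   \linkS4class{SecondaryStructure} (single mode), with attribute
#'   \code{"pipeline"} carrying the resolved seeds, the bonus vector, the
#'   restrained pair probabilities and the free energies.
#' @export
foldEnsemble <- function(seq, shape = NULL, config = foldConfig()) {
  if (length(seq) == 1L && file.exists(seq) &&
      !grepl("^[ACGUTacgut]+$", seq))
    seq <- readFasta(seq)
  seq <- normalizeSequence(seq)
  n <- nchar(seq)
  if (is.character(shape)) shape <- readShape(shape, n)
  if (!is.null(shape) && length(reactivities(shape)) != n)
    stop("SHAPE profile length (", length(reactivities(shape)),
         ") does not match sequence (", n, ")")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ## step 1: unrestrained partition function
  pf0 <- stage("partition", partitionFunction(seq, config$params,
                                              config$consts))
  bonus <- NULL
  if (!is.null(shape)) {
    ## steps 2-4: sample, estimate Rcalc, restrain
    ens1 <- stage("sample", stochasticSample(seq, config$reactivitySample,
                                             seed = config$seeds[["reactivity"]],
                                             params = config$params,
                                             consts = config$consts))
    rcalc <- stage("rcalc", estimateRcalc(ens1, config$dists,
                                          mode = config$rcalcMode,
                                          seed = config$seeds[["reactivity"]]))
    bonus <- stage("restraint", computeBonus(shape, rcalc, config$restraint))
  }
  pf1 <- if (is.null(bonus) || all(bonus == 0)) pf0 else
    stage("partition-restrained",
          partitionFunction(seq, config$params, config$consts, bonus))

  meta <- list(seeds = config$seeds, bonus = bonus,
               pairProbs = pf1$probs,
               freeEnergy = c(unrestrained = pf0$freeEnergy,
                              restrained = pf1$freeEnergy),
               rcalc = if (!is.null(shape)) rcalc else NULL)

  if (config$mode == "single") {
    ## step 5: MEA structure under the restrained ensemble
    out <- stage("mea", meaStructure(pf1$probs, gamma = config$gamma,
                                     minHairpin = config$params@minHairpin))
  } else {
    ## steps 6-8: restrained sample, clustering, centroids
    ens2 <- stage("sample-cluster",
                  stochasticSample(seq, config$clusterSample,
                                   seed = config$seeds[["cluster"]],
                                   params = config$params,
                                   consts = config$consts, bonus = bonus))
    clus <- stage("cluster",
                  clusterStructures(ens2, kMax = config$kMax,
                                    minClusterFrac = config$minPopulation))
    out <- stage("model",
                 buildEnsembleModel(ens2, clus,
                                    entropy = shannonEntropy(pf1$probs),
                                    minPopulation = config$minPopulation))
    meta$clusterResult <- clus
  }
  attr(out, "pipeline") <- meta
  out
}

#' Write pipeline results to a directory
#'
#' Writes per-conformation CT and dot-bracket files, a populations/CH
#' report, the Shannon entropy, and a manifest listing every output file
#' with its MD5 checksum.
#'
#' @param result the return value of \code{\link{foldEnsemble}}.
#' @param seq the RNA sequence used.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
writeEnsembleResults <- function(result, seq, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0L)
  addFile <- function(f) files <<- c(files, f)
  if (is(result, "EnsembleModel")) {
    for (i in seq_along(result@centroids)) {
      ct <- file.path(dir, sprintf("conformation%d.ct", i))
      db <- file.path(dir, sprintf("conformation%d.db", i))
      writeCT(ct, seq, result@centroids[[i]],
              title = sprintf("conformation %d population %.4f", i,
                              result@populations[i]))
      writeDotBracket(db, seq, result@centroids[[i]],
                      description = sprintf("conformation %d", i))
      addFile(ct); addFile(db)
    }
    rep_ <- file.path(dir, "ensemble_report.tsv")
    utils::write.table(
      data.frame(conformation = seq_along(result@centroids),
                 population = result@populations,
                 low_population = result@lowPopulation,
                 n_pairs = vapply(result@centroids,
                                  function(s) nrow(s@pairs), integer(1L))),
      rep_, sep = "\t", quote = FALSE, row.names = FALSE)
    addFile(rep_)
    ch <- file.path(dir, "ch_curve.tsv")
    utils::write.table(
      data.frame(k = names(result@chScores), CH = result@chScores),
      ch, sep = "\t", quote = FALSE, row.names = FALSE)
    addFile(ch)
    ent <- file.path(dir, "shannon_entropy.txt")
    writeLines(sprintf("%.6f", result@shannonEntropy), ent)
    addFile(ent)
  } else {
    ct <- file.path(dir, "mea_structure.ct")
    writeCT(ct, seq, result, title = "MEA structure")
    db <- file.path(dir, "mea_structure.db")
    writeDotBracket(db, seq, result, description = "MEA structure")
    addFile(ct); addFile(db)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(dir, "MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
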