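#' Full-pipeline configuration
#'
#' Collects the per-stage options of [runPanHRD()]: synthetic-cohort
#' generation (or pre-built inputs), scoring, shadow-feature selection,
#' model tuning, SHAP explanation and enrichment. The global seed
#' deterministically derives every stage seed.
#'
#' @param synthetic a [syntheticConfig()], or NULL when `exposures` and
#'   `omics` are supplied directly.
#' @param exposures optional [ExposureSet-class] (real-data route).
#' @param omics optional [OmicsBundle-class] (real-data route).
#' @param score a [scoreConfig()].
#' @param borutaMaxIter,borutaAlpha,borutaTrees shadow-feature selection
#'   options (see [borutaSelect()]).
#' @param searchDraws random-search candidates for [tuneCV()].
#' @param cvFolds cross-validation folds (default 5).
#' @param trainFraction stratified training fraction (default 0.8).
#' @param bootstrapB bootstrap resamples for the clustering stage.
#' @param ablationGrid top-N grid for the ablation stage.
#' @param gmtPath optional GMT file for the enrichment stage; when NULL a
#'   seeded synthetic collection over the selected features is built so
#'   the stage still runs end to end.
#' @param nPerm GSEA permutations.
#' @param seed global integer seed.
#' @return a list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(synthetic = syntheticConfig(),
                           exposures = NULL, omics = NULL,
                           score = scoreConfig(),
                           borutaMaxIter = 50L, borutaAlpha = 0.01,
                           borutaTrees = 100L, searchDraws = 4L,
                           cvFolds = 5L, trainFraction = 0.8,
                           bootstrapB = 100L,
                           ablationGrid = c(1L, 5L, 10L, 20L, 50L),
                           gmtPath = NULL, nPerm = 500L, seed = 1L) {
  if (is.null(synthetic) && (is.null(exposures) || is.null(omics)))
    stop("either a synthetic config or both exposures and omics are required")
  structure(as.list(environment()), class = "PipelineConfig")
}

# deterministic stage seeds derived from the global seed (kept < 2^31)
.stageSeed <- function(seed, stage) (seed * 97L + stage * 1009L) %% 2000000000L

#' Run the full HRD analysis pipeline
#'
#' Executes the stages in order — simulate (or ingest), score, select,
#' train, explain, enrich — persisting every intermediate artifact as TSV
#' under `outDir` and returning a manifest with stage timings, seeds,
#' metrics and md5 checksums. Re-running with the same config and seed
#' reproduces all artifacts bit-exactly.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if absent).
#' @return the manifest, invisibly written to `manifest.json` as well.
#' @export
runPanHRD <- function(config = pipelineConfig(), outDir = tempfile("panhrd")) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(), files = list())
  stamp <- function(stage, t0, ...) {
    manifest$stages[[stage]] <<- c(list(
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2)),
      list(...))
    message(sprintf("[%s] done in %ss", stage,
                    manifest$stages[[stage]]$seconds))
  }

  # stage 1: simulate or ingest
  t0 <- Sys.time()
  if (!is.null(config$synthetic)) {
    sc <- config$synthetic
    sc$seed <- .stageSeed(config$seed, 1L)
    cohort <- generateCohort(sc)
    exposures <- cohort$exposures; omics <- cohort$omics
    truth <- cohort$truth
  } else {
    exposures <- config$exposures; omics <- config$omics; truth <- NULL
  }
  writeExposures(exposures, file.path(outDir, "exposures.tsv"))
  stamp("simulate", t0, nSamples = length(sampleIds(exposures)))

  # stage 2: score
  t0 <- Sys.time()
  scores <- panhrdScores(exposures, config$score)
  scores <- discretizeByMedian(scores)
  writeScores(scores, tumorLabels(exposures),
              file.path(outDir, "panhrd_scores.tsv"))
  stamp("score", t0, medianCutoff = scores@cutoff)

  # stage 3: transform + split + select
  t0 <- Sys.time()
  omics <- transformBundle(omics)
  split <- stratifiedSplit(sampleIds(exposures), tumorLabels(exposures),
                           config$trainFraction,
                           seed = .stageSeed(config$seed, 3L))
  sel <- selectPerLayer(omics, scores, sampleSubset = split$train,
                        maxIterations = config$borutaMaxIter,
                        alpha = config$borutaAlpha,
                        numTrees = config$borutaTrees,
                        seed = .stageSeed(config$seed, 33L))
  utils::write.table(sel$summary, file.path(outDir, "boruta_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stamp("select", t0, confirmed = sum(sel$summary$confirmed))

  # stage 4: assemble, scale, tune, fit, evaluate
  t0 <- Sys.time()
  feats <- assembleFeatures(omics, sel$selected)
  if (!ncol(feats)) stop("select stage confirmed no features; cannot train")
  scaled <- zScale(feats, split$train)
  X <- scaled$values
  y <- hrdScores(scores)[rownames(X)]
  tuned <- tuneCV(X[split$train, , drop = FALSE], y[split$train],
                  candidates = makeSearchSpace(config$searchDraws,
                    seed = .stageSeed(config$seed, 4L)),
                  nfolds = config$cvFolds,
                  seed = .stageSeed(config$seed, 44L))
  model <- fitFinal(X[split$train, , drop = FALSE], y[split$train],
                    tuned$params, tuned$nrounds, cutoff = scores@cutoff,
                    seed = .stageSeed(config$seed, 45L))
  evalRep <- evaluateModel(model, X[split$test, , drop = FALSE],
                           y[split$test],
                           tumorLabels = tumorLabels(exposures)[
                             match(split$test, sampleIds(exposures))])
  utils::write.table(evalRep$overall, file.path(outDir, "eval_overall.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(evalRep$perTumor, file.path(outDir, "eval_per_tumor.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stamp("train", t0, cvRMSE = tuned$cvRMSE, r2 = evalRep$overall$r2,
        auc = evalRep$overall$auc)

  # stage 5: explain
  t0 <- Sys.time()
  Xtest <- X[split$test, , drop = FALSE]
  shap <- shapMatrix(model, Xtest)
  writeMatrixTSV(shapValues(shap), file.path(outDir, "shap_values.tsv"))
  imp <- shapImportance(shap)
  testLabels <- tumorLabels(exposures)[match(split$test,
                                             sampleIds(exposures))]
  heat <- shapFeatureCorrelation(shap, testLabels)
  hm <- clusterWithBootstrap(heat, B = config$bootstrapB,
                             seed = .stageSeed(config$seed, 5L))
  writeMatrixTSV(heat, file.path(outDir, "shap_correlation.tsv"))
  dendrogramNewick(hm, file.path(outDir, "tumor_dendrogram.nwk"))
  abl <- topnAblation(model, Xtest, y[split$test],
                      nGrid = unique(c(config$ablationGrid, ncol(Xtest))),
                      importance = imp)
  utils::write.table(abl, file.path(outDir, "ablation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stamp("explain", t0, nFeatures = ncol(Xtest))

  # stage 6: enrich
  t0 <- Sys.time()
  ranked <- rankFeatures(shap, importance = imp)
  ranks <- stats::setNames(ranked$rank, ranked$feature)
  if (!is.null(config$gmtPath)) {
    sets <- loadGMT(config$gmtPath)
  } else {
    # seeded stand-in collection over the selected features so the
    # enrichment stage runs without external gene-set files
    set.seed(.stageSeed(config$seed, 6L))
    univ <- names(ranks)
    nset <- max(2L, min(10L, floor(length(univ) / 5)))
    sets <- lapply(seq_len(nset), function(i)
      sample(univ, min(length(univ), max(5, rpois(1, 8)))))
    names(sets) <- sprintf("SYNTHETIC_SET_%02d", seq_len(nset))
  }
  enr <- gseaPreranked(ranks, sets, nPerm = config$nPerm,
                       minSize = min(5L, length(ranks)),
                       seed = .stageSeed(config$seed, 66L))
  utils::write.table(enr, file.path(outDir, "enrichment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  stamp("enrich", t0, nSets = nrow(enr))

  files <- list.files(outDir, full.names = TRUE)
  files <- files[!grepl("manifest[.]json$", files)]
  manifest$files <- as.list(tools::md5sum(files))
  manifest$metrics <- list(medianPanHRD = scores@cutoff,
                           r2 = evalRep$overall$r2,
                           auc = evalRep$overall$auc,
                           kappa = evalRep$overall$kappa,
                           confirmedFeatures = sum(sel$summary$confirmed))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
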