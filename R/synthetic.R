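#' Configuration for the synthetic HRD cohort generator
#'
#' Bundles and validates all knobs of the simulator. The generator draws a
#' latent per-sample HRD level from a bimodal Beta mixture (a deficient and
#' a proficient component), plants that signal in the HRD-linked biomarkers
#' (SBS3, ID6, CN17, scarHRD, with CN1 depleted) and in a chosen number of
#' informative genes per omics layer, and fills everything else with
#' latent-independent noise.
#'
#' @param nSamples number of samples (genomes) in the cohort.
#' @param nTumorTypes number of tumor-type labels.
#' @param tumorProportions probability vector over tumor types (defaults to
#'   uniform); must sum to 1.
#' @param nGenesPerLayer named integer vector: genes per omics layer
#'   (`CNV`, `EXP`, `MET`, `MUT`).
#' @param nInformativePerLayer named integer vector: planted HRD-informative
#'   genes per layer (each at most the layer's gene count).
#' @param effectSize non-negative strength of the association between the
#'   latent HRD level and planted biomarkers/genes; 0 plants no signal.
#' @param noiseSd positive noise scale for the Gaussian omics layers.
#' @param mixWeight mixing weight of the HR-deficient (high-latent) Beta
#'   component.
#' @param seed integer seed; the same config and seed always reproduce the
#'   same cohort bit-exactly.
#' @return a validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nSamples = 2000L, nTumorTypes = 3L,
                            tumorProportions = NULL,
                            nGenesPerLayer = c(CNV = 300L, EXP = 300L,
                                               MET = 300L, MUT = 300L),
                            nInformativePerLayer = c(CNV = 10L, EXP = 10L,
                                                     MET = 10L, MUT = 10L),
                            effectSize = 2, noiseSd = 0.5,
                            mixWeight = 0.35, seed = 1L) {
  if (nSamples < 1 || nTumorTypes < 1)
    stop("nSamples and nTumorTypes must be positive")
  if (is.null(tumorProportions))
    tumorProportions <- rep(1 / nTumorTypes, nTumorTypes)
  if (length(tumorProportions) != nTumorTypes ||
      abs(sum(tumorProportions) - 1) > 1e-9)
    stop("tumorProportions must have length nTumorTypes and sum to 1")
  if (!all(names(nGenesPerLayer) %in% .OMICS_LAYERS) ||
      !all(names(nInformativePerLayer) %in% .OMICS_LAYERS))
    stop("layer names must be among CNV, EXP, MET, MUT")
  if (any(nGenesPerLayer < 1))
    stop("gene counts must be positive")
  common <- intersect(names(nInformativePerLayer), names(nGenesPerLayer))
  if (any(nInformativePerLayer[common] > nGenesPerLayer[common]) ||
      any(nInformativePerLayer < 0))
    stop("informative counts must be between 0 and the layer gene count")
  if (effectSize < 0 || noiseSd <= 0)
    stop("effectSize must be >= 0 and noiseSd > 0")
  structure(list(nSamples = as.integer(nSamples),
                 nTumorTypes = as.integer(nTumorTypes),
                 tumorProportions = tumorProportions,
                 nGenesPerLayer = nGenesPerLayer,
                 nInformativePerLayer = nInformativePerLayer,
                 effectSize = effectSize, noiseSd = noiseSd,
                 mixWeight = mixWeight, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

# biomarker name panels matching the exposure classes of the score
.biomarkerPanel <- function() {
  list(SBS = paste0("SBS", 1:30), ID = paste0("ID", 1:23),
       CN = paste0("CN", 1:21), scarHRD = "scarHRD")
}

#' Generate synthetic signature exposures with a latent HRD signal
#'
#' Draws a latent HRD level per sample from a two-component Beta mixture
#' (Beta(2, 8) proficient, Beta(8, 2) deficient) and emits four exposure
#' classes. Exposures are Gamma-distributed; for SBS3, ID6, CN17 and
#' scarHRD the Gamma mean increases linearly with the latent level scaled
#' by `effectSize`, CN1's mean decreases with it, and every other
#' biomarker's mean is latent-independent. All exposures are non-negative.
#'
#' @param config a [syntheticConfig()] object.
#' @return list with elements `exposures` (an [ExposureSet-class]) and
#'   `truth` (a [CohortTruth-class]; `informativeGenes` is empty until
#'   [generateOmics()] fills it).
#' @export
generateExposures <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  n <- config$nSamples
  hi <- stats::runif(n) < config$mixWeight
  latent <- ifelse(hi, stats::rbeta(n, 8, 2), stats::rbeta(n, 2, 8))
  tumors <- factor(sample(paste0("T", seq_len(config$nTumorTypes)), n,
                          replace = TRUE, prob = config$tumorProportions))
  ids <- sprintf("S%04d", seq_len(n))
  panel <- .biomarkerPanel()
  es <- config$effectSize

  # Gamma noise: shape 12 (moderate overdispersion) on planted channels so
  # the latent signal dominates; shape 2 on background signatures.
  planted <- function(mult) stats::rgamma(n, shape = 12,
                                          scale = 50 * mult / 12)
  background <- function() stats::rgamma(n, shape = 2, scale = 25)
  mats <- lapply(names(panel), function(k) {
    bm <- panel[[k]]
    m <- matrix(0, n, length(bm), dimnames = list(ids, bm))
    for (b in bm) {
      m[, b] <- switch(b,
        SBS3    = planted(0.3 + es * latent),
        ID6     = planted(0.3 + es * latent),
        CN17    = planted(0.3 + es * latent),
        scarHRD = planted(0.3 + es * latent),
        CN1     = planted(0.3 + es * (1 - latent)),
        background())
    }
    m
  })
  names(mats) <- names(panel)
  exposures <- new("ExposureSet", exposures = mats, sampleIds = ids,
                   tumorLabels = tumors)
  truth <- new("CohortTruth", latentHRD = latent,
               informativeGenes = list(), tumorLabels = tumors)
  list(exposures = exposures, truth = truth)
}

#' Generate synthetic gene-level omics layers
#'
#' Emits the four omics layers consumed by the prediction model, planting
#' the cohort's latent HRD level in `nInformativePerLayer` genes per layer:
#' copy-number scores centered at 2 (informative genes shifted by
#' `effectSize * latent`), log-normal TPM expression (informative log-means
#' shifted), Beta-distributed methylation in \[0, 1\] (informative means
#' shifted, precision fixed), and Poisson mutation counts (informative
#' rates scaled by the latent level).
#'
#' @param config a [syntheticConfig()] object.
#' @param truth the [CohortTruth-class] returned by [generateExposures()].
#' @return list with elements `omics` (an [OmicsBundle-class]) and `truth`
#'   (the input truth with `informativeGenes` filled in).
#' @export
generateOmics <- function(config, truth) {
  stopifnot(inherits(config, "SyntheticConfig"), is(truth, "CohortTruth"))
  n <- config$nSamples
  if (length(truth@latentHRD) != n)
    stop("truth sample count does not match config")
  set.seed(config$seed + 1L)
  latent <- truth@latentHRD
  es <- config$effectSize
  sd0 <- config$noiseSd
  ids <- sprintf("S%04d", seq_len(n))
  layers <- list(); info <- list()
  for (nm in names(config$nGenesPerLayer)) {
    p <- config$nGenesPerLayer[[nm]]
    k <- config$nInformativePerLayer[[nm]]
    genes <- sprintf("%s_G%04d", nm, seq_len(p))
    infoIdx <- seq_len(k)
    m <- switch(nm,
      CNV = {
        x <- matrix(2 + stats::rnorm(n * p, sd = sd0), n, p)
        for (j in infoIdx) x[, j] <- x[, j] + es * latent
        pmax(x, 0)
      },
      EXP = {
        mu <- matrix(rep(stats::runif(p, 0.5, 2.5), each = n), n, p)
        for (j in infoIdx) mu[, j] <- mu[, j] + es * latent
        exp(mu + stats::rnorm(n * p, sd = sd0))
      },
      MET = {
        mu <- matrix(0.3, n, p)
        for (j in infoIdx)
          mu[, j] <- pmin(pmax(0.3 + 0.25 * es * latent, 0.02), 0.98)
        phi <- 20
        matrix(stats::rbeta(n * p, mu * phi, (1 - mu) * phi), n, p)
      },
      MUT = {
        lambda <- matrix(0.3, n, p)
        for (j in infoIdx) lambda[, j] <- 0.3 * (1 + 3 * es * latent)
        matrix(stats::rpois(n * p, lambda), n, p)
      })
    dimnames(m) <- list(ids, genes)
    layers[[nm]] <- m
    info[[nm]] <- genes[infoIdx]
  }
  truth@informativeGenes <- info
  omics <- new("OmicsBundle", layers = layers, sampleIds = ids,
               state = stats::setNames(rep("raw", length(layers)),
                                       names(layers)))
  list(omics = omics, truth = truth)
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper chaining [generateExposures()] and [generateOmics()].
#'
#' @param config a [syntheticConfig()] object.
#' @return list with `exposures`, `omics` and `truth`.
#' @export
generateCohort <- function(config) {
  e <- generateExposures(config)
  o <- generateOmics(config, e$truth)
  list(exposures = e$exposures, omics = o$omics, truth = o$truth)
}
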