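#' @import methods
NULL

#' ExposureSet: per-class mutational-signature exposure matrices
#'
#' Container for the four exposure classes used by the aggregated HRD score:
#' single-base-substitution signatures (`SBS`, 30 biomarkers), indel
#' signatures (`ID`, 23), copy-number signatures (`CN`, 21) and the scalar
#' genomic-scar index (`scarHRD`, 1). Each class is a samples x biomarkers
#' matrix of non-negative exposures; samples carry a tumor-type label.
#'
#' @slot exposures named list of numeric matrices (one per class), each with
#'   one row per sample and biomarker names as column names.
#' @slot sampleIds character vector of unique sample identifiers.
#' @slot tumorLabels factor of tumor types, one per sample.
#' @export
setClass("ExposureSet",
  slots = c(exposures = "list", sampleIds = "character",
            tumorLabels = "factor"))

setValidity("ExposureSet", function(object) {
  msg <- character()
  cls <- names(object@exposures)
  if (!identical(cls, c("SBS", "ID", "CN", "scarHRD")))
    msg <- c(msg, "exposure classes must be SBS, ID, CN, scarHRD in order")
  g <- length(object@sampleIds)
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "sample ids must be unique")
  if (length(object@tumorLabels) != g)
    msg <- c(msg, "tumorLabels length must match sampleIds")
  for (k in cls) {
    m <- object@exposures[[k]]
    if (!is.matrix(m) || !is.numeric(m))
      msg <- c(msg, sprintf("class %s is not a numeric matrix", k))
    else {
      if (nrow(m) != g)
        msg <- c(msg, sprintf("class %s has %d rows, expected %d", k, nrow(m), g))
      if (any(m < 0, na.rm = TRUE))
        msg <- c(msg, sprintf("class %s has negative exposures", k))
      if (is.null(colnames(m)))
        msg <- c(msg, sprintf("class %s lacks biomarker names", k))
    }
  }
  if ("scarHRD" %in% cls && is.matrix(object@exposures[["scarHRD"]]) &&
      ncol(object@exposures[["scarHRD"]]) != 1L)
    msg <- c(msg, "scarHRD class must have exactly one biomarker")
  if (length(msg)) msg else TRUE
})

#' CohortTruth: ground truth of a synthetic cohort
#'
#' @slot latentHRD per-sample latent HRD level in \[0, 1\].
#' @slot informativeGenes named list (per omics layer) of planted gene ids.
#' @slot tumorLabels factor of tumor types per sample.
#' @export
setClass("CohortTruth",
  slots = c(latentHRD = "numeric", informativeGenes = "list",
            tumorLabels = "factor"))

setValidity("CohortTruth", function(object) {
  if (length(object@latentHRD) != length(object@tumorLabels))
    return("latentHRD and tumorLabels lengths differ")
  if (any(object@latentHRD < 0 | object@latentHRD > 1))
    return("latentHRD must lie in [0, 1]")
  TRUE
})

#' OmicsBundle: aligned gene-level omics matrices
#'
#' Four samples x genes matrices tagged `CNV` (copy-number scores, diploid
#' = 2), `EXP` (TPM), `MET` (methylation beta values) and `MUT`
#' (protein-altering mutation counts), plus a per-layer transformation
#' state (`raw`, `transformed` or `scaled`).
#'
#' @slot layers named list of numeric matrices with sample row names and
#'   gene column names.
#' @slot sampleIds character vector of sample ids (row order of each layer).
#' @slot state named character vector, one state per layer.
#' @export
setClass("OmicsBundle",
  slots = c(layers = "list", sampleIds = "character", state = "character"))

.OMICS_LAYERS <- c("CNV", "EXP", "MET", "MUT")

setValidity("OmicsBundle", function(object) {
  msg <- character()
  if (!all(names(object@layers) %in% .OMICS_LAYERS))
    msg <- c(msg, "layer names must be among CNV, EXP, MET, MUT")
  if (!identical(sort(names(object@state)), sort(names(object@layers))))
    msg <- c(msg, "state must name every layer")
  for (nm in names(object@layers)) {
    m <- object@layers[[nm]]
    # a layer may lack some samples (masked at assembly), never add extras
    if (!is.null(rownames(m)) && !all(rownames(m) %in% object@sampleIds))
      msg <- c(msg, sprintf("layer %s has samples outside sampleIds", nm))
    if (is.null(rownames(m)) && nrow(m) != length(object@sampleIds))
      msg <- c(msg, sprintf("layer %s row count mismatch", nm))
    st <- object@state[[nm]]
    if (!st %in% c("raw", "transformed", "scaled"))
      msg <- c(msg, sprintf("unknown state '%s' for layer %s", st, nm))
    if (identical(st, "raw")) {
      if (nm == "MET" && any(m < 0 | m > 1, na.rm = TRUE))
        msg <- c(msg, "raw MET layer must lie in [0, 1]")
      if (nm == "MUT" && any(m < 0 | m != round(m), na.rm = TRUE))
        msg <- c(msg, "raw MUT layer must hold non-negative integer counts")
    }
  }
  if (length(msg)) msg else TRUE
})

#' ScoreResult: aggregated HRD scores and intermediates
#'
#' @slot scores numeric per-sample panHRD score in \[0, 1\].
#' @slot normalizedExposures samples x 4 matrix of the selected normalized
#'   channels (SBS3, ID6, combined CN1/CN17, scarHRD).
#' @slot rawWeights tumor-type x 4 matrix of supra-epsilon fractions.
#' @slot weights tumor-type x 4 matrix of rescaled weights (rows sum to 1).
#' @slot labels integer 0/1 HRD labels after discretization (may be empty).
#' @slot cutoff numeric cutoff used for discretization (may be NA).
#' @slot epsilon the exposure threshold used for the weights.
#' @export
setClass("ScoreResult",
  slots = c(scores = "numeric", normalizedExposures = "matrix",
            rawWeights = "matrix", weights = "matrix",
            labels = "integer", cutoff = "numeric", epsilon = "numeric"))

setValidity("ScoreResult", function(object) {
  if (any(object@scores < -1e-12 | object@scores > 1 + 1e-12))
    return("scores must lie in [0, 1]")
  TRUE
})

#' BorutaResult: all-relevant feature selection outcome
#'
#' @slot decision factor per feature with levels confirmed / tentative /
#'   rejected.
#' @slot hits integer hit counts per feature (importance above the shadow
#'   maximum).
#' @slot importanceHistory iterations x features matrix of forest
#'   importances (NA once a feature is dropped).
#' @slot iterations number of iterations actually run.
#' @export
setClass("BorutaResult",
  slots = c(decision = "factor", hits = "integer",
            importanceHistory = "matrix", iterations = "integer"))

setValidity("BorutaResult", function(object) {
  if (!all(levels(object@decision) == c("confirmed", "tentative", "rejected")))
    return("decision levels must be confirmed, tentative, rejected")
  if (length(object@hits) != length(object@decision))
    return("hits and decision lengths differ")
  if (any(object@hits > object@iterations))
    return("hit counts cannot exceed iterations run")
  TRUE
})

#' TrainedModel: fitted gradient-boosted regression ensemble
#'
#' @slot booster the fitted xgboost booster.
#' @slot params list of tuned hyperparameters.
#' @slot nrounds number of boosting rounds of the final fit.
#' @slot featureNames feature order the model expects.
#' @slot cutoff score cutoff used to discretize HRD status.
#' @slot baseValue expected model output (bias term of the attributions).
#' @export
setClass("TrainedModel",
  slots = c(booster = "ANY", params = "list", nrounds = "integer",
            featureNames = "character", cutoff = "numeric",
            baseValue = "numeric"))

#' ShapMatrix: per-sample additive feature attributions
#'
#' @slot values samples x features matrix of SHAP values.
#' @slot baseValue expected model output added to each row sum.
#' @slot featureValues the feature matrix the attributions explain.
#' @export
setClass("ShapMatrix",
  slots = c(values = "matrix", baseValue = "numeric",
            featureValues = "matrix"))

setValidity("ShapMatrix", function(object) {
  if (!identical(dim(object@values), dim(object@featureValues)))
    return("values and featureValues dimensions differ")
  TRUE
})

#' CorrelationHeatmap: per-tumor SHAP/feature correlations with clustering
#'
#' @slot matrix tumors x features matrix of correlations (NA where
#'   undefined).
#' @slot rowDendrogram hclust of the rows (tumor types).
#' @slot colDendrogram hclust of the columns (features), or NULL.
#' @slot support named numeric bootstrap support per internal row-tree node.
#' @export
setClass("CorrelationHeatmap",
  slots = c(matrix = "matrix", rowDendrogram = "ANY",
            colDendrogram = "ANY", support = "numeric"))
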