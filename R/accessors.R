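#' @describeIn ExposureSet-class list of per-class exposure matrices.
#' @export
setMethod("exposures", "ExposureSet", function(x) x@exposures)

#' @describeIn ExposureSet-class sample identifiers.
#' @export
setMethod("sampleIds", "ExposureSet", function(x) x@sampleIds)

#' @describeIn ExposureSet-class tumor-type labels.
#' @export
setMethod("tumorLabels", "ExposureSet", function(x) x@tumorLabels)

#' @describeIn OmicsBundle-class sample identifiers.
#' @export
setMethod("sampleIds", "OmicsBundle", function(x) x@sampleIds)

#' @describeIn OmicsBundle-class named list of layer matrices.
#' @export
setMethod("layers", "OmicsBundle", function(x) x@layers)

#' @describeIn OmicsBundle-class per-layer transformation state.
#' @export
setMethod("layerState", "OmicsBundle", function(x) x@state)

#' @describeIn ScoreResult-class per-sample panHRD scores.
#' @export
setMethod("hrdScores", "ScoreResult", function(x) x@scores)

#' @describeIn ScoreResult-class tumor-type x class rescaled weight matrix.
#' @export
setMethod("scoreWeights", "ScoreResult", function(x) x@weights)

#' @describeIn BorutaResult-class names of confirmed features.
#' @export
setMethod("confirmedFeatures", "BorutaResult", function(x)
  names(x@decision)[x@decision == "confirmed"])

#' @describeIn ShapMatrix-class the SHAP value matrix.
#' @export
setMethod("shapValues", "ShapMatrix", function(x) x@values)

#' @describeIn ShapMatrix-class the expected model output (bias).
#' @export
setMethod("baseValue", "ShapMatrix", function(x) x@baseValue)

setMethod("show", "ExposureSet", function(object) {
  cat("ExposureSet with", length(object@sampleIds), "samples,",
      nlevels(object@tumorLabels), "tumor types\n")
  for (k in names(object@exposures))
    cat("  ", k, ": ", ncol(object@exposures[[k]]), " biomarkers\n", sep = "")
})

setMethod("show", "OmicsBundle", function(object) {
  cat("OmicsBundle with", length(object@sampleIds), "samples\n")
  for (nm in names(object@layers))
    cat("  ", nm, ": ", ncol(object@layers[[nm]]), " genes [",
        object@state[[nm]], "]\n", sep = "")
})

setMethod("show", "ScoreResult", function(object) {
  cat("ScoreResult:", length(object@scores), "panHRD scores",
      sprintf("(epsilon = %g)\n", object@epsilon))
  cat("  range:", sprintf("%.4f .. %.4f", min(object@scores),
      max(object@scores)), "\n")
  if (length(object@labels))
    cat("  discretized at cutoff", sprintf("%.4f", object@cutoff), "->",
        sum(object@labels), "HRD-positive\n")
})

setMethod("show", "BorutaResult", function(object) {
  tab <- table(object@decision)
  cat("BorutaResult after", object@iterations, "iterations:\n")
  cat(sprintf("  confirmed %d | tentative %d | rejected %d\n",
      tab[["confirmed"]], tab[["tentative"]], tab[["rejected"]]))
})

setMethod("show", "TrainedModel", function(object) {
  cat("TrainedModel:", length(object@featureNames), "features,",
      object@nrounds, "boosting rounds\n")
  cat("  cutoff:", sprintf("%.4f", object@cutoff),
      " base value:", sprintf("%.4f", object@baseValue), "\n")
})

setMethod("show", "ShapMatrix", function(object) {
  cat("ShapMatrix:", nrow(object@values), "samples x",
      ncol(object@values), "features; base value",
      sprintf("%.4f", object@baseValue), "\n")
})

setMethod("show", "CorrelationHeatmap", function(object) {
  cat("CorrelationHeatmap:", nrow(object@matrix), "tumor types x",
      ncol(object@matrix), "features\n")
  if (length(object@support))
    cat("  bootstrap support on", length(object@support),
        "internal nodes (min", sprintf("%.2f", min(object@support)), ")\n")
})
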