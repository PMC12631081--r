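#' @rdname ExposureSet-class
#' @param object,x an object.
#' @export
setGeneric("exposures", function(x) standardGeneric("exposures"))

#' @rdname ExposureSet-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname ExposureSet-class
#' @export
setGeneric("tumorLabels", function(x) standardGeneric("tumorLabels"))

#' @rdname ScoreResult-class
#' @export
setGeneric("hrdScores", function(x) standardGeneric("hrdScores"))

#' @rdname ScoreResult-class
#' @export
setGeneric("scoreWeights", function(x) standardGeneric("scoreWeights"))

#' @rdname OmicsBundle-class
#' @export
setGeneric("layers", function(x) standardGeneric("layers"))

#' @rdname OmicsBundle-class
#' @export
setGeneric("layerState", function(x) standardGeneric("layerState"))

#' @rdname BorutaResult-class
#' @export
setGeneric("confirmedFeatures", function(x) standardGeneric("confirmedFeatures"))

#' @rdname ShapMatrix-class
#' @export
setGeneric("shapValues", function(x) standardGeneric("shapValues"))

#' @rdname ShapMatrix-class
#' @export
setGeneric("baseValue", function(x) standardGeneric("baseValue"))
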