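#' Configuration of the aggregated HRD score
#'
#' @param epsilon exposure threshold in (0, 1) used for the tumor-type
#'   weights; 0.1 by default, the value that minimizes prediction MSE for
#'   the regression model in the analyses this score was designed for.
#' @param selected named list giving the HRD-linked biomarker subset per
#'   exposure class. The `CN` entry must name exactly two biomarkers (the
#'   anti-correlated pair combined into a single channel, CN1 and CN17 by
#'   default).
#' @return a list of class `ScoreConfig`.
#' @export
scoreConfig <- function(epsilon = 0.1,
                        selected = list(SBS = "SBS3", ID = "ID6",
                                        CN = c("CN1", "CN17"),
                                        scarHRD = "scarHRD")) {
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must lie in (0, 1)")
  if (!identical(names(selected), c("SBS", "ID", "CN", "scarHRD")))
    stop("selected must name SBS, ID, CN, scarHRD")
  if (length(selected$CN) != 2L)
    stop("the CN selection must be a pair of biomarkers")
  structure(list(epsilon = epsilon, selected = selected),
            class = "ScoreConfig")
}

#' Row-normalize signature exposures within a sample
#'
#' Divides each sample's exposures by its total exposure in that class, so
#' each biomarker becomes the proportion of the sample's mutational load it
#' explains. Applies to the SBS, ID and CN classes. Rows whose total
#' exposure is zero are returned as all-zero rows: such a sample carries no
#' signal in that class.
#'
#' @param classMatrix non-negative samples x biomarkers matrix.
#' @return matrix of the same shape with entries in \[0, 1\]; nonzero rows
#'   sum to 1.
#' @export
normalizeSignatureExposures <- function(classMatrix) {
  if (any(classMatrix < 0)) stop("exposures must be non-negative")
  rs <- rowSums(classMatrix)
  out <- classMatrix / ifelse(rs == 0, 1, rs)
  out[rs == 0, ] <- 0
  out
}

#' Normalize the scarHRD index by its cohort-wide maximum
#'
#' @param values non-negative scarHRD values, one per sample.
#' @return values divided by `max(values)` (all zero if every input is 0).
#' @export
normalizeScarHRD <- function(values) {
  if (any(values < 0)) stop("scarHRD values must be non-negative")
  mx <- max(values)
  if (mx == 0) return(values * 0)
  values / mx
}

#' Combine the normalized CN1 and CN17 exposures into one HRD channel
#'
#' CN17 marks HRD directly while CN1 is strongly anti-correlated with it,
#' so the combined channel averages the CN1 complement with CN17:
#' `((1 - cn1) + cn17) / 2`.
#'
#' @param cn1,cn17 normalized exposures in \[0, 1\] (vectors of equal
#'   length).
#' @return combined exposure in \[0, 1\].
#' @export
combineCN <- function(cn1, cn17) {
  if (any(cn1 < 0 | cn1 > 1) || any(cn17 < 0 | cn17 > 1))
    stop("inputs must be normalized to [0, 1]")
  ((1 - cn1) + cn17) / 2
}

# selected, normalized exposure channels: samples x 4 matrix
.selectedChannels <- function(es, config) {
  ex <- exposures(es)
  sel <- config$selected
  chk <- function(k, b) {
    miss <- setdiff(b, colnames(ex[[k]]))
    if (length(miss))
      stop(sprintf("selected biomarker(s) %s absent from class %s",
                   paste(miss, collapse = ", "), k))
  }
  chk("SBS", sel$SBS); chk("ID", sel$ID); chk("CN", sel$CN)
  nsbs <- normalizeSignatureExposures(ex$SBS)[, sel$SBS]
  nid  <- normalizeSignatureExposures(ex$ID)[, sel$ID]
  ncn  <- normalizeSignatureExposures(ex$CN)
  cn   <- combineCN(ncn[, sel$CN[1]], ncn[, sel$CN[2]])
  scar <- normalizeScarHRD(ex$scarHRD[, 1])
  m <- cbind(SBS = nsbs, ID = nid, CN = cn, scarHRD = scar)
  rownames(m) <- sampleIds(es)
  m
}

#' Tumor-type exposure weights (supra-epsilon sample fractions)
#'
#' For each tumor type and each selected channel, the weight is the
#' fraction of that tumor's samples whose normalized exposure is at least
#' `epsilon` (inclusive threshold).
#'
#' @param channels samples x channels matrix of normalized selected
#'   exposures (post CN combination).
#' @param tumorLabels factor of tumor types per sample.
#' @param epsilon threshold in (0, 1).
#' @return tumor-types x channels matrix of raw weights in \[0, 1\].
#' @export
computeWeights <- function(channels, tumorLabels, epsilon) {
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must lie in (0, 1)")
  tumorLabels <- as.factor(tumorLabels)
  counts <- table(tumorLabels)
  if (any(counts == 0))
    stop("tumor type(s) with zero samples: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  out <- matrix(NA_real_, nlevels(tumorLabels), ncol(channels),
                dimnames = list(levels(tumorLabels), colnames(channels)))
  for (tt in levels(tumorLabels))
    out[tt, ] <- colMeans(channels[tumorLabels == tt, , drop = FALSE] >=
                            epsilon)
  out
}

#' Rescale tumor-type weights to sum to one per tumor
#'
#' Divides each tumor's weights by their sum so every tumor type is scored
#' on the same scale. A tumor whose weights are all zero (no sample exceeds
#' epsilon in any channel) falls back to uniform weights with a warning.
#'
#' @param raw tumor-types x channels matrix from [computeWeights()].
#' @return matrix of the same shape; every row sums to 1.
#' @export
rescaleWeights <- function(raw) {
  rs <- rowSums(raw)
  zero <- rs == 0
  if (any(zero)) {
    warning("tumor type(s) with all-zero weights fall back to uniform: ",
            paste(rownames(raw)[zero], collapse = ", "))
    raw[zero, ] <- 1
    rs[zero] <- ncol(raw)
  }
  raw / rs
}

#' Aggregated panHRD score
#'
#' Full scoring chain: row-normalize the SBS, ID and CN exposures,
#' max-normalize scarHRD, combine CN1/CN17 into one channel, compute
#' tumor-type weights at `epsilon`, rescale them to sum to one per tumor,
#' and return the weighted sum of the four selected channels per sample.
#' Scores are guaranteed to lie in \[0, 1\].
#'
#' @param es an [ExposureSet-class].
#' @param config a [scoreConfig()].
#' @param weights optional pre-computed rescaled weight matrix (tumor types
#'   x 4), e.g. computed on a training cohort only; by default weights are
#'   computed on the cohort being scored.
#' @return a [ScoreResult-class].
#' @export
panhrdScores <- function(es, config = scoreConfig(), weights = NULL) {
  stopifnot(is(es, "ExposureSet"), inherits(config, "ScoreConfig"))
  channels <- .selectedChannels(es, config)
  labels <- tumorLabels(es)
  raw <- computeWeights(channels, labels, config$epsilon)
  if (is.null(weights)) weights <- rescaleWeights(raw)
  scores <- rowSums(channels * weights[as.character(labels), , drop = FALSE])
  names(scores) <- sampleIds(es)
  new("ScoreResult", scores = scores, normalizedExposures = channels,
      rawWeights = raw, weights = weights, labels = integer(),
      cutoff = NA_real_, epsilon = config$epsilon)
}

#' Discretize panHRD scores at the cohort median
#'
#' Labels a sample HRD-positive when its score strictly exceeds the cutoff
#' (ties at the cutoff are negative, keeping positives the "high" half).
#' The default cutoff is the median of the supplied scores; an external
#' cutoff (e.g. a full-cohort median applied to a subset) may be given.
#'
#' @param scores numeric panHRD scores, or a [ScoreResult-class].
#' @param cutoff optional externally supplied cutoff.
#' @return for numeric input, a list with `labels` (integer 0/1) and
#'   `cutoff`; for a `ScoreResult`, the object with `labels`/`cutoff`
#'   filled.
#' @export
discretizeByMedian <- function(scores, cutoff = NULL) {
  if (is(scores, "ScoreResult")) {
    d <- discretizeByMedian(hrdScores(scores), cutoff)
    scores@labels <- d$labels
    scores@cutoff <- d$cutoff
    return(scores)
  }
  if (!length(scores)) stop("empty score vector")
  if (is.null(cutoff)) cutoff <- stats::median(scores)
  list(labels = as.integer(scores > cutoff), cutoff = cutoff)
}
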