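#' Exact per-sample SHAP attributions for the boosted-tree model
#'
#' Computes the samples x features matrix of SHAP values via the exact
#' polynomial-time tree-path algorithm (TreeSHAP) on the raw margin scale
#' of the regressor, where additivity is exact: each row of SHAP values
#' plus the base (expected) value reproduces the raw model prediction.
#'
#' @param model a [TrainedModel-class].
#' @param X samples x features matrix in the model's feature space.
#' @return a [ShapMatrix-class].
#' @export
shapMatrix <- function(model, X) {
  miss <- setdiff(model@featureNames, colnames(X))
  if (length(miss))
    stop("missing feature column(s): ", paste(utils::head(miss, 5),
                                              collapse = ", "))
  m <- X[, model@featureNames, drop = FALSE]
  contrib <- predict(model@booster, xgboost::xgb.DMatrix(m, missing = NA),
                     predcontrib = TRUE)
  base <- unname(contrib[1, ncol(contrib)])
  vals <- contrib[, -ncol(contrib), drop = FALSE]
  dimnames(vals) <- dimnames(m)
  new("ShapMatrix", values = vals, baseValue = base, featureValues = m)
}

#' Global SHAP importance: mean absolute attribution per feature
#'
#' @param shap a [ShapMatrix-class].
#' @return named numeric vector of importances (all >= 0), in the
#'   matrix's column order; use [order()] for the ranking.
#' @export
shapImportance <- function(shap) {
  stopifnot(is(shap, "ShapMatrix"))
  if (!nrow(shap@values)) stop("empty SHAP matrix")
  colMeans(abs(shap@values))
}

#' Per-tumor correlation between feature values and their SHAP values
#'
#' For each tumor type with at least `minSamples` samples and each
#' feature, correlates the feature's values with its SHAP values over
#' that tumor's samples. A positive entry means higher feature values
#' push the prediction toward HRD within that tumor. Constant columns
#' give NA (missing), not 0; under-sized tumors give an all-NA row.
#'
#' @param shap a [ShapMatrix-class].
#' @param tumorLabels factor of tumor types, one per SHAP row.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param minSamples minimum samples per tumor (default 3).
#' @return tumors x features correlation matrix.
#' @export
shapFeatureCorrelation <- function(shap, tumorLabels, method = "pearson",
                                   minSamples = 3L) {
  stopifnot(is(shap, "ShapMatrix"))
  tumorLabels <- as.factor(tumorLabels)
  if (length(tumorLabels) != nrow(shap@values))
    stop("tumorLabels length must match SHAP rows")
  out <- matrix(NA_real_, nlevels(tumorLabels), ncol(shap@values),
                dimnames = list(levels(tumorLabels),
                                colnames(shap@values)))
  for (tt in levels(tumorLabels)) {
    idx <- tumorLabels == tt
    if (sum(idx) < minSamples) {
      warning("tumor ", tt, " has fewer than ", minSamples,
              " samples; row left missing")
      next
    }
    s <- shap@values[idx, , drop = FALSE]
    v <- shap@featureValues[idx, , drop = FALSE]
    out[tt, ] <- vapply(seq_len(ncol(s)), function(j) {
      if (stats::sd(s[, j]) == 0 || stats::sd(v[, j], na.rm = TRUE) == 0 ||
          sum(stats::complete.cases(v[, j])) < minSamples)
        return(NA_real_)
      stats::cor(v[, j], s[, j], method = method,
                 use = "pairwise.complete.obs")
    }, numeric(1))
  }
  out
}

# leaf sets of every internal node of an hclust tree, as canonical strings
.clades <- function(hc, labels) {
  n <- nrow(hc$merge) + 1L
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    m <- hc$merge[i, ]
    get <- function(x) if (x < 0) labels[-x] else members[[x]]
    members[[i]] <- sort(c(get(m[1]), get(m[2])))
  }
  vapply(members, paste, character(1), collapse = "\r")
}

#' Hierarchical clustering of heatmap rows with bootstrap support
#'
#' Clusters the rows of a correlation heatmap (average linkage, Euclidean
#' distance, missing entries imputed by column median), then resamples
#' the columns with replacement `B` times and records, for every internal
#' node of the original dendrogram, the fraction of bootstrap dendrograms
#' containing the same leaf set (ordinary bootstrap proportion). Ties in
#' the distance matrix are broken by `hclust`'s deterministic merge order.
#'
#' @param heatmap tumors x features numeric matrix (NAs allowed).
#' @param B number of bootstrap resamples (default 100).
#' @param seed integer seed.
#' @return a [CorrelationHeatmap-class] with row/column dendrograms and
#'   per-node support.
#' @export
clusterWithBootstrap <- function(heatmap, B = 100L, seed = 1L) {
  if (B < 1) stop("B must be at least 1")
  if (nrow(heatmap) < 2) stop("need at least 2 rows to cluster")
  imp <- heatmap
  for (j in seq_len(ncol(imp))) {
    na <- is.na(imp[, j])
    if (any(na))
      imp[na, j] <- if (all(na)) 0 else stats::median(imp[, j], na.rm = TRUE)
  }
  hc <- stats::hclust(stats::dist(imp), method = "average")
  colHc <- if (ncol(imp) >= 2)
    stats::hclust(stats::dist(t(imp)), method = "average") else NULL
  orig <- .clades(hc, rownames(imp))
  counts <- stats::setNames(numeric(length(orig)), orig)
  set.seed(seed)
  for (b in seq_len(B)) {
    idx <- sample(ncol(imp), replace = TRUE)
    hb <- stats::hclust(stats::dist(imp[, idx, drop = FALSE]),
                        method = "average")
    hit <- orig %in% .clades(hb, rownames(imp))
    counts[hit] <- counts[hit] + 1
  }
  support <- counts / B
  names(support) <- gsub("\r", "+", names(support), fixed = TRUE)
  new("CorrelationHeatmap", matrix = heatmap, rowDendrogram = hc,
      colDendrogram = colHc, support = support)
}

#' Export a dendrogram as a newick string
#'
#' @param hm a [CorrelationHeatmap-class].
#' @param file optional path to write to.
#' @param which `"row"` (default) or `"col"`.
#' @return the newick string, invisibly when written to a file.
#' @export
dendrogramNewick <- function(hm, file = NULL, which = c("row", "col")) {
  which <- match.arg(which)
  hc <- if (which == "row") hm@rowDendrogram else hm@colDendrogram
  if (is.null(hc)) stop("no ", which, " dendrogram available")
  nw <- ape::write.tree(ape::as.phylo(hc))
  if (!is.null(file)) { writeLines(nw, file); return(invisible(nw)) }
  nw
}

#' Re-evaluate the model keeping only the top-N features by SHAP rank
#'
#' For each N in the grid, the values of all but the N most important
#' features (by mean absolute SHAP, ties broken by feature name) are
#' replaced by the missing marker and the SAME trained model re-predicts,
#' exploiting the learner's native default-direction routing of missing
#' values. N equal to the feature count reproduces the full model's
#' predictions exactly; N = 0 yields the all-missing default-path output.
#'
#' @param model a [TrainedModel-class].
#' @param X held-out feature matrix.
#' @param y held-out true panHRD scores.
#' @param nGrid integer vector of N values (values above the feature count
#'   are clamped with a warning).
#' @param cutoff score cutoff for the kappa metric (defaults to the
#'   model's stored cutoff).
#' @param importance optional importance vector (defaults to SHAP
#'   importance computed on `X`).
#' @return data.frame with columns n, kappa, r2, rmse.
#' @export
topnAblation <- function(model, X, y, nGrid = c(0L, 1L, 5L, 10L, 50L,
                                                100L, ncol(X)),
                         cutoff = NULL, importance = NULL) {
  if (is.null(cutoff)) cutoff <- model@cutoff
  if (is.null(importance))
    importance <- shapImportance(shapMatrix(model, X))
  importance <- importance[model@featureNames]
  ranked <- model@featureNames[order(-importance, model@featureNames)]
  if (any(nGrid > length(ranked))) {
    warning("N above the feature count clamped to ", length(ranked))
    nGrid[nGrid > length(ranked)] <- length(ranked)
  }
  nGrid <- unique(as.integer(nGrid))
  truth <- y > cutoff
  out <- lapply(nGrid, function(N) {
    Xm <- X[, model@featureNames, drop = FALSE]
    if (N < ncol(Xm))
      Xm[, setdiff(colnames(Xm), ranked[seq_len(N)])] <- NA_real_
    pred <- predict(model, Xm)
    ssTot <- sum((y - mean(y))^2)
    data.frame(n = N,
               kappa = cohenKappa(truth, pred > cutoff),
               r2 = if (ssTot == 0) NA_real_ else
                 1 - sum((y - pred)^2) / ssTot,
               rmse = sqrt(mean((y - pred)^2)))
  })
  do.call(rbind, out)
}

#' Ordered waterfall table of one sample's SHAP contributions
#'
#' @param shap a [ShapMatrix-class].
#' @param sample row index or sample id.
#' @param topK number of named features to keep; the remainder is
#'   aggregated into an `"other"` row. Features with zero attribution are
#'   omitted.
#' @return data.frame with feature, value, contribution; contributions sum
#'   to prediction minus base value.
#' @export
waterfallExport <- function(shap, sample, topK = 10L) {
  stopifnot(is(shap, "ShapMatrix"))
  s <- shap@values[sample, ]
  v <- shap@featureValues[sample, ]
  nz <- which(s != 0)
  ord <- nz[order(-abs(s[nz]), names(s)[nz])]
  keep <- utils::head(ord, topK)
  rest <- setdiff(ord, keep)
  out <- data.frame(feature = names(s)[keep], value = unname(v[keep]),
                    contribution = unname(s[keep]))
  if (length(rest) || length(nz) > length(keep))
    out <- rbind(out, data.frame(feature = "other", value = NA_real_,
                                 contribution = sum(s[rest])))
  out
}
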