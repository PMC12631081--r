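#' Stratified train/test split by tumor type
#'
#' Splits samples at the given fraction within each tumor type so the
#' tumor composition of train and test match; every per-tumor train count
#' is within one sample of `fraction * n`. Tumor types with a single
#' sample go to the training set.
#'
#' @param sampleIds character sample ids.
#' @param tumorLabels factor (or coercible) of tumor types per sample.
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed integer seed.
#' @return list with `train`, `test` (character id vectors), `fraction`
#'   and `seed`.
#' @export
stratifiedSplit <- function(sampleIds, tumorLabels, fraction = 0.8,
                            seed = 1L) {
  if (!length(sampleIds)) stop("empty cohort")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  tumorLabels <- as.factor(tumorLabels)
  set.seed(seed)
  train <- character()
  for (tt in levels(tumorLabels)) {
    ids <- sampleIds[tumorLabels == tt]
    n <- length(ids)
    nTrain <- if (n == 1L) 1L else max(1L, min(n, round(fraction * n)))
    train <- c(train, sample(ids)[seq_len(nTrain)])
  }
  list(train = sort(train), test = sort(setdiff(sampleIds, train)),
       fraction = fraction, seed = as.integer(seed))
}

#' Random hyperparameter search space for the boosted-tree regressor
#'
#' Draws candidates over learning rate (log-uniform 0.01-0.3), tree depth
#' (3-8), minimum child weight (1-10) and row/column subsampling
#' (0.6-1.0); boosting rounds are chosen by early stopping during
#' cross-validation up to `maxRounds`.
#'
#' @param nDraws number of random candidates (default 20).
#' @param maxRounds boosting-round ceiling per candidate (default 1000).
#' @param seed integer seed.
#' @return data.frame of candidates, one row each.
#' @export
makeSearchSpace <- function(nDraws = 20L, maxRounds = 1000L, seed = 1L) {
  set.seed(seed)
  data.frame(
    eta = 10 ^ stats::runif(nDraws, log10(0.01), log10(0.3)),
    max_depth = sample(3:8, nDraws, replace = TRUE),
    min_child_weight = sample(1:10, nDraws, replace = TRUE),
    subsample = stats::runif(nDraws, 0.6, 1),
    colsample_bytree = stats::runif(nDraws, 0.6, 1),
    max_rounds = as.integer(maxRounds))
}

#' Tune boosted-tree hyperparameters by five-fold cross-validation on RMSE
#'
#' Evaluates each candidate with k-fold cross-validation (folds drawn once
#' under the seed and shared by all candidates), using early stopping on
#' the CV RMSE to pick the boosting-round count. The candidate with the
#' lowest mean CV RMSE wins; exact ties go to the candidate with fewer
#' boosting rounds, then to the earlier candidate index.
#'
#' @param X training feature matrix (NA = missing, routed natively).
#' @param y numeric training target.
#' @param candidates data.frame from [makeSearchSpace()] (or a single-row
#'   data.frame for a fixed configuration).
#' @param nfolds number of CV folds (default 5).
#' @param earlyStoppingRounds patience for early stopping (default 25).
#' @param seed integer seed controlling fold assignment.
#' @return list with `params` (winning xgboost parameter list), `nrounds`,
#'   `cvRMSE`, and the per-candidate `log` data.frame.
#' @export
tuneCV <- function(X, y, candidates = makeSearchSpace(), nfolds = 5L,
                   earlyStoppingRounds = 25L, seed = 1L) {
  if (stats::var(y) == 0) stop("degenerate target: zero variance")
  if (length(y) < nfolds) stop("need at least one sample per fold")
  set.seed(seed)
  foldId <- sample(rep(seq_len(nfolds), length.out = length(y)))
  folds <- split(seq_along(y), foldId)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, missing = NA)
  log <- data.frame()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    params <- list(objective = "reg:squarederror", eta = cand$eta,
                   max_depth = cand$max_depth,
                   min_child_weight = cand$min_child_weight,
                   subsample = cand$subsample,
                   colsample_bytree = cand$colsample_bytree,
                   nthread = 1)
    set.seed(seed + i)
    cv <- xgboost::xgb.cv(params = params, data = dtrain,
                          nrounds = cand$max_rounds, folds = folds,
                          early_stopping_rounds = earlyStoppingRounds,
                          metrics = "rmse", verbose = 0)
    best <- cv$early_stop$best_iteration
    if (is.null(best)) best <- cv$niter
    rmse <- cv$evaluation_log$test_rmse_mean[best]
    log <- rbind(log, data.frame(candidate = i, nrounds = best,
                                 cvRMSE = rmse))
  }
  ord <- order(log$cvRMSE, log$nrounds, log$candidate)
  win <- log[ord[1], ]
  cand <- candidates[win$candidate, ]
  list(params = list(objective = "reg:squarederror", eta = cand$eta,
                     max_depth = cand$max_depth,
                     min_child_weight = cand$min_child_weight,
                     subsample = cand$subsample,
                     colsample_bytree = cand$colsample_bytree,
                     nthread = 1),
       nrounds = win$nrounds, cvRMSE = win$cvRMSE, log = log)
}

#' Fit the final boosted-tree model on the full training set
#'
#' @param X training feature matrix with column names (NA = missing).
#' @param y numeric training target (panHRD score).
#' @param params xgboost parameter list (e.g. from [tuneCV()]).
#' @param nrounds boosting rounds.
#' @param cutoff score cutoff stored with the model for discretized
#'   evaluation (e.g. the cohort median panHRD).
#' @param seed integer seed.
#' @return a [TrainedModel-class].
#' @export
fitFinal <- function(X, y, params, nrounds, cutoff = NA_real_, seed = 1L) {
  if (nrow(X) != length(y)) stop("feature/target row mismatch")
  if (is.null(colnames(X))) stop("feature matrix must have column names")
  params$nthread <- 1
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, missing = NA)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = nrounds, verbose = 0)
  contrib <- predict(booster, dtrain, predcontrib = TRUE)
  new("TrainedModel", booster = booster, params = params,
      nrounds = as.integer(nrounds), featureNames = colnames(X),
      cutoff = cutoff, baseValue = unname(contrib[1, ncol(contrib)]))
}

#' Predict panHRD scores with a trained model
#'
#' @param object a [TrainedModel-class].
#' @param newdata samples x features matrix containing (at least) the
#'   model's features; columns are reordered to the training order and
#'   NA entries follow the learner's native default directions.
#' @return numeric predictions named by row.
#' @export
setMethod("predict", "TrainedModel", function(object, newdata) {
  miss <- setdiff(object@featureNames, colnames(newdata))
  if (length(miss))
    stop("missing feature column(s): ", paste(utils::head(miss, 5),
                                              collapse = ", "))
  m <- newdata[, object@featureNames, drop = FALSE]
  p <- predict(object@booster, xgboost::xgb.DMatrix(m, missing = NA))
  names(p) <- rownames(newdata)
  p
})

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' @param pred numeric ranking scores.
#' @param truth logical (or 0/1) class labels.
#' @return AUC in \[0, 1\], or NA with a warning when only one class is
#'   present.
#' @export
aucRank <- function(pred, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(pred)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cohen's kappa for two binary label vectors
#'
#' @param a,b 0/1 or logical label vectors of equal length.
#' @return chance-corrected agreement in \[-1, 1\] (0 when expected
#'   agreement is 1).
#' @export
cohenKappa <- function(a, b) {
  a <- as.integer(as.logical(a)); b <- as.integer(as.logical(b))
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + (1 - mean(a)) * (1 - mean(b))
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' Evaluate a trained model on held-out data
#'
#' Reports regression metrics (R^2, RMSE) on the continuous score and
#' classification metrics after discretizing: the binary truth is the TRUE
#' panHRD thresholded at `cutoff`, predictions serve as the AUC ranking
#' statistic, and kappa/sensitivity/specificity/precision apply the same
#' cutoff to the predictions. A per-tumor breakdown (n, positive fraction,
#' AUC) is included when labels are given; strata with a single truth
#' class report NA AUC with a warning.
#'
#' @param model a [TrainedModel-class].
#' @param X held-out feature matrix.
#' @param y held-out true panHRD scores.
#' @param cutoff score cutoff (defaults to the model's stored cutoff).
#' @param tumorLabels optional factor for the per-tumor breakdown.
#' @return list with `overall` (one-row data.frame) and `perTumor`
#'   (data.frame or NULL).
#' @export
evaluateModel <- function(model, X, y, cutoff = NULL, tumorLabels = NULL) {
  if (!nrow(X)) stop("empty test set")
  if (is.null(cutoff)) cutoff <- model@cutoff
  pred <- predict(model, X)
  ssRes <- sum((y - pred)^2)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot == 0) NA_real_ else 1 - ssRes / ssTot
  rmse <- sqrt(mean((y - pred)^2))
  truth <- y > cutoff
  predLab <- pred > cutoff
  auc <- aucRank(pred, truth)
  kap <- cohenKappa(truth, predLab)
  tp <- sum(truth & predLab); tn <- sum(!truth & !predLab)
  fp <- sum(!truth & predLab); fn <- sum(truth & !predLab)
  overall <- data.frame(
    n = length(y), r2 = r2, rmse = rmse, auc = auc, kappa = kap,
    sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp) tn / (tn + fp) else NA_real_,
    precision = if (tp + fp) tp / (tp + fp) else NA_real_,
    positiveFraction = mean(truth), cutoff = cutoff)
  perTumor <- NULL
  if (!is.null(tumorLabels)) {
    tumorLabels <- as.factor(tumorLabels)
    perTumor <- do.call(rbind, lapply(levels(tumorLabels), function(tt) {
      idx <- tumorLabels == tt
      data.frame(tumor = tt, n = sum(idx),
                 positiveFraction = mean(truth[idx]),
                 auc = aucRank(pred[idx], truth[idx]))
    }))
  }
  list(overall = overall, perTumor = perTumor)
}
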