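#' All-relevant feature selection with shadow features
#'
#' Shadow-feature (Boruta-style) selection in regression mode. Each
#' iteration appends a shuffled copy of every still-active feature
#' (breaking its association with the target), fits a random-forest
#' regressor on the extended matrix, and scores a "hit" for every real
#' feature whose impurity importance exceeds the maximum importance among
#' the shadows. A two-sided binomial test of the hit count against
#' Binomial(iterations, 0.5), corrected across all presented features
#' (Bonferroni by default; the correction scope stays constant over
#' iterations), confirms features hitting significantly more than half
#' the time and rejects those hitting significantly less.
#' Rejected features are dropped from later iterations, but shadows are
#' drawn from every original feature throughout: shrinking the shadow
#' ensemble alongside the rejected features would weaken the null maximum
#' and let features with persistent spurious correlations win by
#' attrition. The loop stops when no feature is left undecided or after
#' `maxIterations`, with unresolved features returned as tentative.
#'
#' @param X samples x features numeric matrix with column names.
#' @param y numeric target (the panHRD score in this pipeline).
#' @param maxIterations iteration cap (default 100).
#' @param alpha significance level of the binomial test (default 0.01).
#' @param correction multiple-testing correction passed to
#'   [stats::p.adjust()] (default `"bonferroni"`).
#' @param numTrees trees per random forest (default 100).
#' @param maxDepth depth cap of the forest trees (default 8; keeps the
#'   importance race cheap without changing its ranking behavior).
#' @param minIterations earliest iteration at which decisions are taken
#'   (default 5).
#' @param seed integer seed for shuffles and forests.
#' @return a [BorutaResult-class].
#' @export
borutaSelect <- function(X, y, maxIterations = 100L, alpha = 0.01,
                         correction = "bonferroni", numTrees = 100L,
                         maxDepth = 8L, minIterations = 5L, seed = 1L) {
  if (!is.matrix(X) || ncol(X) < 1L) stop("X must have at least one feature")
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  p <- ncol(X)
  feats <- colnames(X)
  hits <- stats::setNames(integer(p), feats)
  decision <- stats::setNames(rep("tentative", p), feats)
  history <- matrix(NA_real_, maxIterations, p,
                    dimnames = list(NULL, feats))
  set.seed(seed)
  iter <- 0L
  while (iter < maxIterations && any(decision == "tentative")) {
    iter <- iter + 1L
    active <- names(decision)[decision != "rejected"]
    Xa <- X[, active, drop = FALSE]
    shadows <- apply(X, 2, sample)
    colnames(shadows) <- paste0(".shadow.", feats)
    fit <- ranger::ranger(x = cbind(Xa, shadows), y = y,
                          num.trees = numTrees, max.depth = maxDepth,
                          importance = "impurity", num.threads = 1L,
                          seed = seed + iter)
    imp <- fit$variable.importance
    shadowMax <- max(imp[colnames(shadows)])
    realImp <- imp[active]
    history[iter, active] <- realImp
    hits[active] <- hits[active] + as.integer(realImp > shadowMax)
    if (iter >= minIterations) {
      tent <- names(decision)[decision == "tentative"]
      praw <- vapply(hits[tent], function(h)
        stats::binom.test(h, iter, 0.5)$p.value, numeric(1))
      padj <- stats::p.adjust(praw, method = correction, n = p)
      decision[tent[padj < alpha & hits[tent] > iter / 2]] <- "confirmed"
      decision[tent[padj < alpha & hits[tent] < iter / 2]] <- "rejected"
    }
  }
  new("BorutaResult",
      decision = factor(decision,
                        levels = c("confirmed", "tentative", "rejected")),
      hits = hits, importanceHistory = history[seq_len(iter), , drop = FALSE],
      iterations = iter)
}

#' Run shadow-feature selection independently on each omics layer
#'
#' Applies [borutaSelect()] to every layer of a (transformed) bundle with
#' the panHRD score as the regression target, and summarizes how many
#' features each layer presented and retained.
#'
#' @param bundle an [OmicsBundle-class] aligned with the scores.
#' @param scores a [ScoreResult-class] or numeric score vector named by
#'   sample id.
#' @param sampleSubset optional sample ids to restrict the selection to
#'   (e.g. training samples only, avoiding test-set leakage; pass all ids
#'   to mimic full-cohort selection).
#' @param includeTentative if TRUE, tentative features are returned along
#'   with confirmed ones (default FALSE).
#' @param ... forwarded to [borutaSelect()].
#' @return list with `selected` (named list layer -> character features),
#'   `results` (per-layer [BorutaResult-class]) and `summary` (data.frame
#'   with layer, presented, confirmed, percent).
#' @export
selectPerLayer <- function(bundle, scores, sampleSubset = NULL,
                           includeTentative = FALSE, ...) {
  stopifnot(is(bundle, "OmicsBundle"))
  sc <- if (is(scores, "ScoreResult")) hrdScores(scores) else scores
  ids <- sampleIds(bundle)
  if (is.null(sampleSubset)) sampleSubset <- ids
  sampleSubset <- intersect(sampleSubset, intersect(ids, names(sc)))
  if (!length(sampleSubset)) stop("no samples shared by bundle and scores")
  res <- list(); sel <- list()
  for (nm in names(layers(bundle))) {
    m <- layers(bundle)[[nm]][sampleSubset, , drop = FALSE]
    r <- borutaSelect(m, sc[sampleSubset], ...)
    res[[nm]] <- r
    keep <- confirmedFeatures(r)
    if (includeTentative)
      keep <- c(keep, names(r@decision)[r@decision == "tentative"])
    sel[[nm]] <- keep
  }
  summary <- data.frame(
    layer = names(res),
    presented = vapply(layers(bundle), ncol, integer(1))[names(res)],
    confirmed = vapply(sel, length, integer(1)),
    row.names = NULL)
  summary$percent <- 100 * summary$confirmed / summary$presented
  list(selected = sel, results = res, summary = summary)
}
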