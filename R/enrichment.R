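#' Rank features by signed SHAP correlation weighted by importance
#'
#' The rank statistic combines, per feature, the correlation between the
#' feature's values and its SHAP values (the direction of its association
#' with predicted HRD) with its global SHAP importance:
#' `rank = corr * 10^importance` (the default `"exponent"` reading; the
#' `"linear"` alternative `corr * 10 * importance` is available). Either
#' way the sign of the rank is the sign of the correlation. Features with
#' an undefined correlation (constant SHAP or value column) are dropped
#' with a warning.
#'
#' @param shap a [ShapMatrix-class].
#' @param importance optional named importance vector (defaults to
#'   [shapImportance()] of `shap`).
#' @param reading `"exponent"` (default) or `"linear"`.
#' @param method correlation type (`"pearson"` default).
#' @return data.frame (feature, corr, importance, rank) sorted by
#'   decreasing rank.
#' @export
rankFeatures <- function(shap, importance = NULL,
                         reading = c("exponent", "linear"),
                         method = "pearson") {
  stopifnot(is(shap, "ShapMatrix"))
  reading <- match.arg(reading)
  if (!ncol(shap@values)) stop("empty SHAP matrix")
  if (is.null(importance)) importance <- shapImportance(shap)
  corr <- vapply(seq_len(ncol(shap@values)), function(j) {
    s <- shap@values[, j]; v <- shap@featureValues[, j]
    if (stats::sd(s) == 0 || stats::sd(v, na.rm = TRUE) == 0)
      return(NA_real_)
    stats::cor(v, s, method = method, use = "pairwise.complete.obs")
  }, numeric(1))
  names(corr) <- colnames(shap@values)
  drop <- is.na(corr)
  if (any(drop))
    warning(sum(drop), " feature(s) with undefined correlation dropped")
  corr <- corr[!drop]
  imp <- importance[names(corr)]
  rank <- if (reading == "exponent") corr * 10 ^ imp else corr * 10 * imp
  out <- data.frame(feature = names(corr), corr = unname(corr),
                    importance = unname(imp), rank = unname(rank))
  out[order(-out$rank), ]
}

#' Parse a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB
#' gene TAB gene ...`. Duplicate genes within a set are deduplicated;
#' a line with fewer than three fields, an empty gene list, or a
#' duplicated set name is an error reported with its line number.
#'
#' @param path path to the GMT file.
#' @return named list of character gene vectors, with a `description`
#'   attribute.
#' @export
loadGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, ": expected name, description, genes")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("empty gene list at GMT line ", i)
    if (f[1] %in% names(sets)) stop("duplicate set name at GMT line ", i,
                                    ": ", f[1])
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  attr(sets, "description") <- desc
  sets
}

# weighted Kolmogorov-Smirnov running-sum enrichment score.
# ranks: named statistic vector; set: gene ids; p: weight exponent.
# Returns list(es, leadingEdge).
.gseaES <- function(ranks, set, p = 1) {
  ord <- order(ranks, decreasing = TRUE)
  ranks <- ranks[ord]
  hit <- names(ranks) %in% set
  nh <- sum(hit)
  # set spanning the whole universe: no misses to balance the running
  # sum, enrichment relative to nothing is zero by convention
  if (nh == length(ranks)) return(list(es = 0, leadingEdge = 0L))
  w <- abs(ranks) ^ p
  sumW <- sum(w[hit])
  # all hit weights zero: fall back to unweighted steps
  stepHit <- if (sumW == 0) hit / nh else (w * hit) / sumW
  nMiss <- length(ranks) - nh
  stepMiss <- if (nMiss == 0) rep(0, length(ranks)) else (!hit) / nMiss
  running <- cumsum(stepHit - stepMiss)
  peak <- which.max(abs(running))
  es <- running[peak]
  leading <- if (es >= 0) sum(hit[seq_len(peak)])
             else sum(hit[seq(peak, length(hit))])
  list(es = unname(es), leadingEdge = leading)
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running-sum GSEA on a preranked
#' list. For each gene set (filtered to `minSize`..`maxSize` genes after
#' intersection with the ranked universe) the enrichment score is the
#' signed maximum deviation of the running sum with hit increments
#' proportional to `|rank|^weightExponent`. The null distribution draws
#' `nPerm` random same-size gene sets from the universe; the p-value is
#' `(1 + #(same-sign |ES_null| >= |ES|)) / (1 + nPerm)` and
#' `NES = ES / mean(|ES_null| of matching sign)`. P-values are BH-adjusted
#' across the tested sets.
#'
#' @param ranks named numeric rank statistics (e.g. [rankFeatures()]'s
#'   `rank` column named by feature), one per gene.
#' @param sets named list of gene-set character vectors (see [loadGMT()]).
#' @param nPerm permutations for the null (default 1000).
#' @param minSize,maxSize inclusive size filter after intersecting the
#'   universe (defaults 5 and 500).
#' @param weightExponent running-sum weight exponent (1 = classic
#'   weighted, 0 = unweighted Kolmogorov-Smirnov).
#' @param seed integer seed for the permutation draws.
#' @return data.frame with pathway, size, es, nes, pval, padj,
#'   leadingEdge; skipped sets are reported via message.
#' @export
gseaPreranked <- function(ranks, sets, nPerm = 1000L, minSize = 5L,
                          maxSize = 500L, weightExponent = 1,
                          seed = 1L) {
  if (!length(ranks)) stop("empty ranked list")
  if (is.null(names(ranks))) stop("ranks must be named by gene")
  universe <- names(ranks)
  sets <- lapply(sets, intersect, universe)
  sizes <- vapply(sets, length, integer(1))
  skip <- sizes < minSize | sizes > maxSize
  if (any(sizes == 0))
    message(sum(sizes == 0), " set(s) with no genes in the universe skipped")
  sets <- sets[!skip]
  if (!length(sets))
    return(data.frame(pathway = character(), size = integer(),
                      es = numeric(), nes = numeric(), pval = numeric(),
                      padj = numeric(), leadingEdge = integer()))
  obs <- lapply(sets, function(s) .gseaES(ranks, s, weightExponent))
  set.seed(seed)
  sizesKept <- vapply(sets, length, integer(1))
  nullBySize <- list()
  for (s in unique(sizesKept)) {
    nullBySize[[as.character(s)]] <- vapply(seq_len(nPerm), function(b)
      .gseaES(ranks, sample(universe, s), weightExponent)$es, numeric(1))
  }
  out <- data.frame(pathway = names(sets), size = sizesKept,
                    es = vapply(obs, `[[`, numeric(1), "es"),
                    nes = NA_real_, pval = NA_real_,
                    leadingEdge = vapply(obs, `[[`, integer(1),
                                         "leadingEdge"),
                    row.names = NULL)
  for (i in seq_len(nrow(out))) {
    nullEs <- nullBySize[[as.character(out$size[i])]]
    same <- if (out$es[i] >= 0) nullEs[nullEs >= 0] else nullEs[nullEs < 0]
    out$pval[i] <- (1 + sum(abs(same) >= abs(out$es[i]))) / (1 + nPerm)
    denom <- mean(abs(same))
    out$nes[i] <- if (length(same) && denom > 0) out$es[i] / denom
                  else NA_real_
  }
  out$padj <- stats::p.adjust(out$pval, method = "BH")
  out[order(out$pval), c("pathway", "size", "es", "nes", "pval", "padj",
                         "leadingEdge")]
}

#' Partition genes by gene-set collection membership
#'
#' Marks, for every gene, whether it belongs to each collection (the
#' union of that collection's sets); genes in no collection form the
#' exclusive "Complementary" group. Intersection counts over membership
#' patterns (UpSet-style) are attached as an attribute.
#'
#' @param genes character gene universe (e.g. the selected features).
#' @param collections named list of collections, each a named list of
#'   gene sets (see [loadGMT()]).
#' @return data.frame with one logical column per collection plus
#'   `Complementary`; attribute `intersections` holds the pattern counts.
#' @export
partitionByCollections <- function(genes, collections) {
  member <- vapply(collections, function(coll)
    genes %in% unique(unlist(coll)), logical(length(genes)))
  member <- matrix(member, nrow = length(genes),
                   dimnames = list(genes, names(collections)))
  out <- data.frame(gene = genes, member, row.names = NULL,
                    check.names = FALSE)
  out$Complementary <- rowSums(member) == 0
  pattern <- apply(cbind(member, Complementary = out$Complementary), 1,
                   function(r) paste(names(r)[r], collapse = "&"))
  attr(out, "intersections") <- sort(table(pattern), decreasing = TRUE)
  out
}

#' Per-tumor association between panHRD and mutation carrier status
#'
#' Within each tumor type, compares the panHRD scores of carriers (at
#' least one qualifying mutation in the gene) and non-carriers by a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test, then adjusts the
#' p-values across tumors with Benjamini-Hochberg. Tumors where either
#' group has fewer than `minGroup` samples are skipped.
#'
#' @param scores numeric panHRD scores.
#' @param mutCounts non-negative mutation counts for the gene, aligned
#'   with `scores`.
#' @param tumorLabels factor of tumor types per sample.
#' @param minGroup minimum group size on each side (default 3).
#' @return data.frame with tumor, nCarrier, nNonCarrier, U (carriers
#'   first), pval, padj.
#' @export
mutationAssociation <- function(scores, mutCounts, tumorLabels,
                                minGroup = 3L) {
  if (length(scores) != length(mutCounts) ||
      length(scores) != length(tumorLabels))
    stop("scores, mutCounts and tumorLabels must be aligned")
  tumorLabels <- as.factor(tumorLabels)
  carrier <- mutCounts >= 1
  rows <- list()
  for (tt in levels(tumorLabels)) {
    idx <- tumorLabels == tt
    n1 <- sum(carrier[idx]); n0 <- sum(idx) - n1
    if (n1 < minGroup || n0 < minGroup) next
    wt <- suppressWarnings(
      stats::wilcox.test(scores[idx & carrier], scores[idx & !carrier],
                         alternative = "two.sided"))
    rows[[tt]] <- data.frame(tumor = tt, nCarrier = n1, nNonCarrier = n0,
                             U = unname(wt$statistic), pval = wt$p.value)
  }
  if (!length(rows))
    return(data.frame(tumor = character(), nCarrier = integer(),
                      nNonCarrier = integer(), U = numeric(),
                      pval = numeric(), padj = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$padj <- stats::p.adjust(out$pval, method = "BH")
  out
}
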