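#' Log-transform TPM expression values
#'
#' Applies the elementwise natural `log(1 + x)` transform used before
#' model fitting. The log base is a documented convention (TPM pipelines
#' vary); base choice does not change tree-model split order.
#'
#' @param tpm non-negative matrix of TPM values.
#' @return transformed matrix.
#' @export
transformExpression <- function(tpm) {
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  log1p(tpm)
}

#' Log-transform gene-level copy-number scores
#'
#' Applies `log2(1 + x / 2)`, mapping a diploid score of 2 to exactly 1
#' and a homozygous deletion (0) to 0.
#'
#' @param scores non-negative matrix of copy-number scores (diploid = 2).
#' @return transformed matrix.
#' @export
transformCNV <- function(scores) {
  if (any(scores < 0, na.rm = TRUE)) stop("CNV scores must be non-negative")
  log2(1 + scores / 2)
}

#' Count protein-altering mutations per gene and sample
#'
#' Keeps only rows whose VEP-style impact is HIGH or MODERATE (the
#' protein-altering classes, e.g. nonsense and missense) and tabulates
#' counts over a declared gene universe, retaining all-zero columns for
#' genes never mutated.
#'
#' @param mutationTable data.frame with columns `sample_id`, `gene`,
#'   `impact`.
#' @param genes character gene universe (column space of the result).
#' @param samples character sample universe (row space of the result).
#' @param strict if TRUE (default), an impact label outside
#'   HIGH/MODERATE/LOW/MODIFIER is an error; if FALSE unknown labels are
#'   dropped with a warning.
#' @return samples x genes integer count matrix.
#' @export
filterAndCountMutations <- function(mutationTable, genes, samples,
                                    strict = TRUE) {
  need <- c("sample_id", "gene", "impact")
  if (!all(need %in% names(mutationTable)))
    stop("mutation table needs columns sample_id, gene, impact")
  known <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
  bad <- setdiff(unique(mutationTable$impact), known)
  if (length(bad)) {
    if (strict) stop("unknown impact label(s): ", paste(bad, collapse = ", "))
    warning("dropping rows with unknown impact label(s): ",
            paste(bad, collapse = ", "))
    mutationTable <- mutationTable[mutationTable$impact %in% known, ]
  }
  keep <- mutationTable$impact %in% c("HIGH", "MODERATE") &
    mutationTable$gene %in% genes & mutationTable$sample_id %in% samples
  m <- matrix(0L, length(samples), length(genes),
              dimnames = list(samples, genes))
  if (any(keep)) {
    tab <- table(factor(mutationTable$sample_id[keep], levels = samples),
                 factor(mutationTable$gene[keep], levels = genes))
    m[] <- as.integer(tab)
  }
  m
}

#' Z-scale features using training-set statistics only
#'
#' Centers and scales every column by the mean and sample SD (n - 1
#' denominator) computed on the training rows alone, then applies those
#' statistics to all rows — held-out samples never influence the scaling.
#' Constant training columns (SD = 0) map to 0 with a warning.
#'
#' @param features samples x features numeric matrix with row names.
#' @param trainIds character ids of the training rows.
#' @return list with `values` (scaled matrix), `center` and `scale`
#'   (named per-feature statistics).
#' @export
zScale <- function(features, trainIds) {
  if (!length(trainIds) || !all(trainIds %in% rownames(features)))
    stop("trainIds must be a non-empty subset of the feature rows")
  tr <- features[trainIds, , drop = FALSE]
  ctr <- colMeans(tr, na.rm = TRUE)
  scl <- apply(tr, 2, stats::sd, na.rm = TRUE)
  const <- !is.na(scl) & scl == 0
  if (any(const)) {
    warning(sum(const), " constant training column(s) scaled to 0")
    scl[const] <- 1
  }
  out <- sweep(sweep(features, 2, ctr, "-"), 2, scl, "/")
  out[, const] <- 0
  list(values = out, center = ctr, scale = scl)
}

#' Assemble a model-ready feature table from omics layers
#'
#' Concatenates the selected genes of each layer column-wise with
#' layer-prefixed feature ids (`CNV:GENE`, `EXP:GENE`, ...). The sample
#' space is the union over layers; a sample absent from a layer gets NA in
#' that layer's columns, which the boosted-tree learner routes natively.
#'
#' @param bundle an [OmicsBundle-class].
#' @param selectedGenes named list: layer -> character vector of gene ids
#'   to keep (an empty vector contributes no columns).
#' @return samples x features numeric matrix.
#' @export
assembleFeatures <- function(bundle, selectedGenes) {
  stopifnot(is(bundle, "OmicsBundle"))
  lay <- layers(bundle)
  allSamples <- unique(unlist(lapply(lay, rownames)))
  if (anyDuplicated(sampleIds(bundle)))
    stop("duplicate sample ids in bundle")
  blocks <- list()
  for (nm in names(selectedGenes)) {
    sel <- selectedGenes[[nm]]
    if (!length(sel)) next
    if (!nm %in% names(lay)) stop("layer absent from bundle: ", nm)
    miss <- setdiff(sel, colnames(lay[[nm]]))
    if (length(miss))
      stop("gene(s) absent from layer ", nm, ": ",
           paste(utils::head(miss, 5), collapse = ", "))
    b <- matrix(NA_real_, length(allSamples), length(sel),
                dimnames = list(allSamples, paste0(nm, ":", sel)))
    present <- intersect(allSamples, rownames(lay[[nm]]))
    b[present, ] <- lay[[nm]][present, sel, drop = FALSE]
    blocks[[nm]] <- b
  }
  out <- do.call(cbind, blocks)
  if (is.null(out)) out <- matrix(numeric(), length(allSamples), 0,
                                  dimnames = list(allSamples, NULL))
  if (anyDuplicated(colnames(out))) stop("duplicate feature ids")
  out
}

#' Apply the standard layer transforms to a raw bundle
#'
#' CNV -> `log2(1 + x/2)`, EXP -> `log(1 + x)`; MET (already in \[0, 1\])
#' and MUT (counts) pass through unchanged. Layers already marked
#' `transformed` are left alone.
#'
#' @param bundle an [OmicsBundle-class] with raw layers.
#' @return the bundle with layers transformed and states updated.
#' @export
transformBundle <- function(bundle) {
  stopifnot(is(bundle, "OmicsBundle"))
  for (nm in names(bundle@layers)) {
    if (bundle@state[[nm]] != "raw") next
    bundle@layers[[nm]] <- switch(nm,
      CNV = transformCNV(bundle@layers[[nm]]),
      EXP = transformExpression(bundle@layers[[nm]]),
      bundle@layers[[nm]])
    bundle@state[[nm]] <- "transformed"
  }
  validObject(bundle)
  bundle
}
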