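#' Write an ExposureSet as a long-format TSV
#'
#' Columns: sample_id, tumor_type, class, biomarker, exposure. The format
#' round-trips through [readExposures()], so synthetic and real exposure
#' tables are interchangeable.
#'
#' @param es an [ExposureSet-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeExposures <- function(es, path) {
  stopifnot(is(es, "ExposureSet"))
  rows <- lapply(names(exposures(es)), function(k) {
    m <- exposures(es)[[k]]
    data.frame(sample_id = rep(sampleIds(es), ncol(m)),
               tumor_type = rep(as.character(tumorLabels(es)), ncol(m)),
               class = k,
               biomarker = rep(colnames(m), each = nrow(m)),
               exposure = as.vector(m))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ExposureSet from a long-format TSV
#'
#' @param path file written by [writeExposures()] (or equivalent columns
#'   sample_id, tumor_type, class, biomarker, exposure).
#' @return an [ExposureSet-class].
#' @export
readExposures <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tumor_type", "class", "biomarker", "exposure")
  if (!all(need %in% names(tab)))
    stop("exposure table needs columns: ", paste(need, collapse = ", "))
  ids <- unique(tab$sample_id)
  labs <- tab$tumor_type[match(ids, tab$sample_id)]
  mats <- lapply(c("SBS", "ID", "CN", "scarHRD"), function(k) {
    sub <- tab[tab$class == k, ]
    bms <- unique(sub$biomarker)
    m <- matrix(NA_real_, length(ids), length(bms),
                dimnames = list(ids, bms))
    m[cbind(match(sub$sample_id, ids), match(sub$biomarker, bms))] <-
      sub$exposure
    m
  })
  names(mats) <- c("SBS", "ID", "CN", "scarHRD")
  new("ExposureSet", exposures = mats, sampleIds = ids,
      tumorLabels = factor(labs))
}

#' Write panHRD scores as a TSV
#'
#' Columns: sample_id, tumor_type, panHRD and (when discretized) label.
#'
#' @param result a [ScoreResult-class].
#' @param tumorLabels factor of tumor types aligned with the scores.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeScores <- function(result, tumorLabels, path) {
  stopifnot(is(result, "ScoreResult"))
  tab <- data.frame(sample_id = names(hrdScores(result)),
                    tumor_type = as.character(tumorLabels),
                    panHRD = unname(hrdScores(result)))
  if (length(result@labels)) tab$label <- result@labels
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a samples x genes matrix as a TSV with a sample_id column
#'
#' @param m numeric matrix with sample row names.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeMatrixTSV <- function(m, path) {
  tab <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a samples x genes matrix written by [writeMatrixTSV()]
#'
#' @param path input file path.
#' @return numeric matrix with sample row names.
#' @export
readMatrixTSV <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}
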