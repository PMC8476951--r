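#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList isEmpty
#' @importFrom SummarizedExperiment SummarizedExperiment rowData colData
#'   rowData<- colData<- assay assays
#' @importFrom BiocGenerics counts
NULL

.META_COLS <- c("tissue", "precursor", "isotope", "replicate")

#' FeatureTable: an LC-MS feature table with sample design
#'
#' The central container of the package: a
#' \linkS4class{SummarizedExperiment} whose rows are mass features
#' (\code{rowData} columns \code{mz} in Th, negative-mode M-H, and
#' \code{rt} in seconds) and whose columns are samples. The sample design
#' lives in \code{colData}: \code{tissue}, \code{precursor} (\code{"Phe"}
#' or \code{"Tyr"}), \code{isotope} (\code{"12C"} or \code{"13C"}) and
#' \code{replicate}; extra columns (e.g. \code{genotype} for unlabeled
#' mutant tables) are carried along. The single assay \code{"counts"}
#' holds non-negative integrated ion counts.
#'
#' Design columns may be \code{NA} (an unlabeled genotype table has no
#' precursor or isotope arm); operations that need a complete labeling
#' design check for it explicitly.
#'
#' @slot rowRanges,colData,assays,NAMES,elementMetadata,metadata Inherited
#'   from \linkS4class{SummarizedExperiment}.
#' @seealso \code{\link{FeatureTable}} for the constructor,
#'   \code{\link{readFeatureTable}} for file input.
#' @aliases FeatureTable-class
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment")

.validFeatureTable <- function(object) {
  msg <- NULL
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  rd <- rowData(object)
  if (!all(c("mz", "rt") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'mz' and 'rt'")
  else {
    if (any(!is.finite(rd$mz)) || any(rd$mz <= 0))
      msg <- c(msg, "all mz must be finite and > 0")
    if (any(!is.finite(rd$rt)) || any(rd$rt < 0))
      msg <- c(msg, "all rt must be finite and >= 0")
  }
  if (is.null(rownames(object)) && nrow(object) > 0)
    msg <- c(msg, "features must be named (feature_id rownames)")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate feature_id")
  if (!all(.META_COLS %in% colnames(colData(object))))
    msg <- c(msg, paste("colData must contain:",
                        paste(.META_COLS, collapse = ", ")))
  else {
    iso <- colData(object)$isotope
    if (!all(is.na(iso) | iso %in% c("12C", "13C")))
      msg <- c(msg, "isotope must be '12C' or '13C' (or NA)")
    pre <- colData(object)$precursor
    if (!all(is.na(pre) | pre %in% c("Phe", "Tyr")))
      msg <- c(msg, "precursor must be 'Phe' or 'Tyr' (or NA)")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample_id")
  if ("counts" %in% names(assays(object))) {
    cts <- assay(object, "counts")
    if (any(!is.finite(cts)) || any(cts < 0))
      msg <- c(msg, "ion counts must be finite and non-negative")
  }
  if (nrow(object) > 0) {
    key <- paste(rowData(object)$mz, rowData(object)$rt)
    if (anyDuplicated(key))
      msg <- c(msg, "two features share identical (mz, rt)")
  }
  if (is.null(msg)) TRUE else msg
}

setValidity("FeatureTable", .validFeatureTable)

#' @describeIn FeatureTable-class compact display of dimensions, RT range
#'   and design cells.
#' @param object A \code{FeatureTable}.
#' @export
setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d features x %d samples\n",
              nrow(object), ncol(object)))
  if (nrow(object) > 0) {
    cat(sprintf("  m/z %.4f-%.4f, RT %.0f-%.0f s\n",
                min(featureMz(object)), max(featureMz(object)),
                min(featureRt(object)), max(featureRt(object))))
  }
  cd <- colData(object)
  cells <- unique(paste(cd$tissue, cd$precursor, cd$isotope, sep = "/"))
  cat("  design cells:", paste(cells, collapse = ", "), "\n")
  filled <- metadata(object)$n_filled
  if (!is.null(filled) && filled > 0)
    cat(sprintf("  %d missing cells read as 0 (peak-fill flag)\n", filled))
  invisible(NULL)
})
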