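#' Construct a FeatureTable
#'
#' Builds a validated \linkS4class{FeatureTable} from an ion-count matrix,
#' per-feature coordinates and a sample-design table. Feature identifiers
#' follow the \code{M<mz>T<rt>} naming convention (see
#' \code{\link{makeFeatureId}}) when not supplied; identifier collisions
#' after rounding get suffixes \code{_2}, \code{_3}, ... in input order.
#'
#' @param counts Numeric matrix of non-negative ion counts, features in
#'   rows, samples in columns.
#' @param mz Numeric vector of feature m/z values (Th, M-H).
#' @param rt Numeric vector of feature retention times (seconds).
#' @param sampleData A data.frame or \link[S4Vectors]{DataFrame} with one
#'   row per sample; must contain \code{sample_id} (or rownames) plus
#'   \code{tissue}, \code{precursor}, \code{isotope}, \code{replicate}
#'   (missing design columns are filled with \code{NA}).
#' @param feature_id Optional character vector of feature identifiers;
#'   auto-generated when \code{NULL}.
#' @param provenance Optional free-text metadata (instrument, polarity...).
#' @return A \code{FeatureTable}.
#' @examples
#' cts <- matrix(c(100, 5, 200, 8), 2, 2,
#'               dimnames = list(NULL, c("s1", "s2")))
#' sd <- data.frame(sample_id = c("s1", "s2"), tissue = "leaf",
#'                  precursor = "Phe", isotope = c("12C", "13C"),
#'                  replicate = 1L)
#' FeatureTable(cts, mz = c(310.0935, 316.1138), rt = c(325, 325),
#'              sampleData = sd)
#' @export
FeatureTable <- function(counts, mz, rt, sampleData, feature_id = NULL,
                         provenance = character()) {
  counts <- as.matrix(counts)
  stopifnot(length(mz) == nrow(counts), length(rt) == nrow(counts))
  sd <- DataFrame(sampleData)
  if ("sample_id" %in% colnames(sd)) {
    rownames(sd) <- sd$sample_id
    sd$sample_id <- NULL
  }
  if (is.null(rownames(sd)) && !is.null(colnames(counts)))
    rownames(sd) <- colnames(counts)
  for (m in .META_COLS)
    if (!m %in% colnames(sd)) sd[[m]] <- NA
  if (is.null(colnames(counts))) colnames(counts) <- rownames(sd)
  counts <- counts[, rownames(sd), drop = FALSE]
  if (is.null(feature_id))
    feature_id <- makeFeatureId(mz, rt)
  rownames(counts) <- feature_id
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(mz = as.numeric(mz), rt = as.numeric(rt),
                        row.names = feature_id),
    colData = sd
  )
  out <- new("FeatureTable", se)
  metadata(out)$provenance <- provenance
  out
}

#' Feature m/z values
#'
#' @param x A \linkS4class{FeatureTable}.
#' @return Numeric vector (Th), named by feature id.
#' @rdname featureMz
#' @export
setMethod("featureMz", "FeatureTable", function(x)
  stats::setNames(rowData(x)$mz, rownames(x)))

#' Feature retention times
#'
#' @param x A \linkS4class{FeatureTable}.
#' @return Numeric vector (seconds), named by feature id.
#' @rdname featureRt
#' @export
setMethod("featureRt", "FeatureTable", function(x)
  stats::setNames(rowData(x)$rt, rownames(x)))

#' Feature identifiers
#'
#' @param x A \linkS4class{FeatureTable}.
#' @return Character vector of feature ids.
#' @rdname featureIds
#' @export
setMethod("featureIds", "FeatureTable", function(x) rownames(x))

#' Sample design table
#'
#' @param x A \linkS4class{FeatureTable}.
#' @return The \code{colData} \link[S4Vectors]{DataFrame} (tissue,
#'   precursor, isotope, replicate, plus any extra columns).
#' @rdname sampleData
#' @export
setMethod("sampleData", "FeatureTable", function(x) colData(x))

#' @describeIn FeatureTable-class ion-count matrix accessor.
#' @param object A \code{FeatureTable}.
#' @export
setMethod("counts", "FeatureTable", function(object) assay(object, "counts"))

#' Deterministic feature identifiers from (m/z, RT)
#'
#' Generates the conventional \code{"M<round(mz)>T<round(rt)>"} names, e.g.
#' the cyanogenic glycoside dhurrin (m/z 310.0935, 325 s) becomes
#' \code{"M310T325"}. The convention is lossy, so collisions get
#' \code{_2}, \code{_3}, ... suffixes in input order.
#'
#' @param mz Numeric vector, m/z in Th (> 0).
#' @param rt Numeric vector, retention time in seconds (>= 0).
#' @return Character vector of unique identifiers.
#' @examples
#' makeFeatureId(310.0935, 325)   # "M310T325"
#' makeFeatureId(121.0298, 468)   # "M121T468"
#' @export
makeFeatureId <- function(mz, rt) {
  if (any(!is.finite(mz)) || any(!is.finite(rt)))
    stop("mz and rt must be finite")
  if (any(mz <= 0) || any(rt < 0))
    stop("mz must be > 0 and rt >= 0")
  ids <- sprintf("M%.0fT%.0f", round(mz), round(rt))
  if (anyDuplicated(ids)) {
    for (dup in unique(ids[duplicated(ids)])) {
      at <- which(ids == dup)
      ids[at[-1]] <- paste0(dup, "_", seq_along(at[-1]) + 1L)
    }
  }
  ids
}

#' Read a feature table and its sample metadata
#'
#' Reads the wide CSV layout produced by standard feature-detection tools:
#' features as rows with columns \code{feature_id} (optional), \code{mz},
#' \code{rt}, then one ion-count column per sample; plus a separate sample
#' metadata CSV with columns \code{sample_id}, \code{tissue},
#' \code{precursor}, \code{isotope}, \code{replicate} (extra columns such
#' as \code{genotype} are kept). Missing intensity cells are read as 0 and
#' counted in \code{metadata(x)$n_filled}, because upstream peak filling
#' makes zeros and small fills indistinguishable.
#'
#' @param path Feature-table CSV path.
#' @param meta_path Sample-metadata CSV path.
#' @return A validated \linkS4class{FeatureTable}.
#' @seealso \code{\link{writeFeatureTable}}
#' @export
readFeatureTable <- function(path, meta_path) {
  stopifnot(file.exists(path), file.exists(meta_path))
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  if (!all(c("mz", "rt") %in% colnames(tab)))
    stop("malformed feature table header: need 'mz' and 'rt' columns")
  if (!"sample_id" %in% colnames(meta))
    stop("malformed metadata header: need 'sample_id'")
  fid <- if ("feature_id" %in% colnames(tab)) tab$feature_id else NULL
  if (!is.null(fid) && anyDuplicated(fid))
    stop("duplicate feature_id in feature table")
  samp_cols <- setdiff(colnames(tab), c("feature_id", "mz", "rt"))
  unknown <- setdiff(samp_cols, meta$sample_id)
  if (length(unknown))
    stop("sample(s) in table absent from metadata: ",
         paste(unknown, collapse = ", "))
  cts <- as.matrix(tab[, samp_cols, drop = FALSE])
  storage.mode(cts) <- "double"
  n_filled <- sum(is.na(cts))
  cts[is.na(cts)] <- 0
  if (any(cts < 0)) stop("negative intensity in feature table")
  meta <- meta[match(samp_cols, meta$sample_id), , drop = FALSE]
  out <- FeatureTable(cts, mz = tab$mz, rt = tab$rt, sampleData = meta,
                      feature_id = fid)
  metadata(out)$n_filled <- n_filled
  out
}

#' Write a feature table and its sample metadata
#'
#' Inverse of \code{\link{readFeatureTable}}; values round-trip to at
#' least 6 decimal places.
#'
#' @param x A \linkS4class{FeatureTable}.
#' @param path Output feature-table CSV path.
#' @param meta_path Output sample-metadata CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeFeatureTable <- function(x, path, meta_path) {
  tab <- data.frame(feature_id = featureIds(x),
                    mz = featureMz(x), rt = featureRt(x),
                    check.names = FALSE)
  tab <- cbind(tab, as.data.frame(counts(x), check.names = FALSE))
  utils::write.csv(tab, path, row.names = FALSE)
  meta <- cbind(sample_id = colnames(x),
                as.data.frame(colData(x)))
  utils::write.csv(meta, meta_path, row.names = FALSE)
  invisible(path)
}

#' Restrict a feature table to a retention-time window
#'
#' Keeps features with \code{lo <= rt <= hi}; the default window of
#' 100-1100 s spans the informative part of the reverse-phase gradient,
#' dropping the void volume and column wash. Samples are unchanged, and
#' the operation is idempotent.
#'
#' @param x A \linkS4class{FeatureTable}.
#' @param lo,hi Window bounds in seconds (\code{lo < hi}).
#' @return The filtered \code{FeatureTable}.
#' @rdname filterRtWindow
#' @export
setMethod("filterRtWindow", "FeatureTable", function(x, lo = 100, hi = 1100) {
  stopifnot(is.numeric(lo), is.numeric(hi), lo < hi)
  keep <- featureRt(x) >= lo & featureRt(x) <= hi
  x[keep, ]
})

#' Remove fed precursor masses from a feature table
#'
#' Drops features whose m/z matches (within \code{tol_ppm}) any mass in
#' the exclusion list — by default the M-H masses of Phe, Tyr and their
#' ring-\eqn{{}^{13}C_6} isotopologues, since the fed substrates dominate
#' their own pools and would distort the labeling analysis.
#'
#' @param x A \linkS4class{FeatureTable}.
#' @param tol_ppm Match tolerance in ppm (> 0).
#' @param masses Numeric vector of exclusion m/z values; empty vector is
#'   the identity.
#' @return The filtered \code{FeatureTable}.
#' @rdname excludeFedPrecursors
#' @export
setMethod("excludeFedPrecursors", "FeatureTable",
          function(x, tol_ppm = 15, masses = fedPrecursorMasses()) {
  stopifnot(tol_ppm > 0)
  if (length(masses) == 0) return(x)
  mz <- featureMz(x)
  hit <- vapply(mz, function(m)
    any(.ppm(m, masses) <= tol_ppm), logical(1))
  x[!hit, ]
})
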