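#' Share of total ion count in precursor-derived features
#'
#' Per tissue, the percent of the total ion count (within the
#' \eqn{{}^{12}C}-fed samples, where pools are unperturbed by label)
#' carried by the unlabeled anchors of library-annotated features — the
#' aggregate footprint of the Phe- and Tyr-derived metabolomes.
#'
#' @param x The labeling \linkS4class{FeatureTable}.
#' @param library Library entries from \code{\link{buildLibrary}}.
#' @param isotope Sample subset to measure in (default \code{"12C"}).
#' @return A \link[S4Vectors]{DataFrame} with \code{tissue}, \code{pct},
#'   \code{n_features}.
#' @export
pctTotalIonLabeled <- function(x, library, isotope = "12C") {
  cd <- colData(x)
  cts <- counts(x)
  anchors <- match(library$anchor_id, featureIds(x))
  out <- list()
  for (ti in unique(cd$tissue[!is.na(cd$tissue)])) {
    samps <- which(!is.na(cd$tissue) & cd$tissue == ti &
                     !is.na(cd$isotope) & cd$isotope == isotope)
    denom <- sum(cts[, samps, drop = FALSE])
    num <- sum(cts[anchors, samps, drop = FALSE])
    out[[length(out) + 1L]] <- data.frame(
      tissue = ti,
      pct = if (denom > 0) 100 * num / denom else NA_real_,
      n_features = length(anchors), stringsAsFactors = FALSE)
  }
  DataFrame(do.call(rbind, out))
}

#' Share of ion count in labeled isotopologues
#'
#' Per tissue and precursor, the percent of the total ion count in the
#' \eqn{{}^{13}C}-fed samples carried by the +6/+12/+18 isotopologue
#' features of the library — how much of the acquired signal is de novo
#' labeled material.
#'
#' @param x The labeling \linkS4class{FeatureTable}.
#' @param library Library entries from \code{\link{buildLibrary}}.
#' @return A \link[S4Vectors]{DataFrame} with \code{tissue},
#'   \code{precursor}, \code{pct}, \code{n_features}.
#' @export
pct13CIon <- function(x, library) {
  cd <- colData(x)
  cts <- counts(x)
  ids <- featureIds(x)
  lab <- stats::na.omit(unique(c(library$labeled_1, library$labeled_2,
                                 library$labeled_3)))
  li <- match(lab, ids)
  out <- list()
  for (ti in unique(cd$tissue[!is.na(cd$tissue)])) {
    for (pre in c("Phe", "Tyr")) {
      samps <- which(!is.na(cd$tissue) & cd$tissue == ti &
                       !is.na(cd$precursor) & cd$precursor == pre &
                       !is.na(cd$isotope) & cd$isotope == "13C")
      if (length(samps) == 0) next
      denom <- sum(cts[, samps, drop = FALSE])
      num <- sum(cts[li, samps, drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        tissue = ti, precursor = pre,
        pct = if (denom > 0) 100 * num / denom else NA_real_,
        n_features = length(li), stringsAsFactors = FALSE)
    }
  }
  DataFrame(do.call(rbind, out))
}

#' Bias versus feature-property table
#'
#' One row per enrichment record pairing the dominant-precursor mol\%
#' with the feature's unlabeled abundance, RT and m/z — the raw material
#' for bias-vs-property scatter plots. \code{signed_bias} is the
#' dominant mol\% signed positive toward Phe and negative toward Tyr; an
#' exact 50/50 feature has dominant \code{"neither"} and bias 50
#' (signed positive by convention).
#'
#' @param records Enrichment records (defined rows) from
#'   \code{\link{quantifyEnrichment}}.
#' @param x The labeling \linkS4class{FeatureTable}.
#' @param isotope Sample arm used for the abundance column.
#' @return A \link[S4Vectors]{DataFrame} with \code{anchor_id},
#'   \code{tissue}, \code{dominant}, \code{bias}, \code{signed_bias},
#'   \code{intensity}, \code{rt}, \code{mz}.
#' @export
biasPropertyTable <- function(records, x, isotope = "12C") {
  cd <- colData(x)
  cts <- counts(x)
  idx <- match(records$anchor_id, featureIds(x))
  dom <- pmax(records$mol_phe, records$mol_tyr)
  dominant <- ifelse(records$mol_phe == records$mol_tyr, "neither",
                     ifelse(records$mol_phe > records$mol_tyr,
                            "Phe", "Tyr"))
  intensity <- vapply(seq_len(nrow(records)), function(i) {
    samps <- which(!is.na(cd$tissue) & cd$tissue == records$tissue[i] &
                     !is.na(cd$isotope) & cd$isotope == isotope)
    mean(cts[idx[i], samps])
  }, numeric(1))
  DataFrame(anchor_id = records$anchor_id, tissue = records$tissue,
            dominant = dominant, bias = dom,
            signed_bias = ifelse(dominant == "Tyr", -dom, dom),
            intensity = intensity,
            rt = featureRt(x)[idx], mz = featureMz(x)[idx])
}

#' Ordinary least squares on log2 intensities
#'
#' Fits \code{log2(y + pseudo) ~ log2(x + pseudo)} by OLS and reports
#' slope, intercept and R-squared — the cross-tissue / cross-feeding
#' comparison used on feature abundances. The pseudo-count offsets
#' zeros created by peak filling.
#'
#' @param x,y Paired non-negative intensity vectors.
#' @param pseudo Pseudo-count added before the log2 transform.
#' @return List with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{n}.
#' @export
log2Regression <- function(x, y, pseudo = 1) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("log2Regression needs >= 3 points")
  lx <- log2(x + pseudo); ly <- log2(y + pseudo)
  fit <- stats::lm(ly ~ lx)
  # R^2 from the fit residuals directly; summary.lm() warns on an exact fit
  tss <- sum((ly - mean(ly))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = 1 - sum(stats::residuals(fit)^2) / tss,
       n = length(x))
}

#' PCA sample scores
#'
#' Centered (not scaled) principal component analysis, via SVD, of
#' samples over log2 feature intensities; returns the scores on the
#' first \code{k} components. Identical samples receive identical
#' scores.
#'
#' @param x A \linkS4class{FeatureTable} or a features-by-samples
#'   numeric matrix of intensities.
#' @param pseudo Pseudo-count before the log2 transform.
#' @param k Number of components to return.
#' @param scale. Scale features to unit variance first?
#' @param log2_transform Apply log2(. + pseudo)? Set \code{FALSE} when
#'   \code{x} is already transformed.
#' @return A samples-by-k score matrix; a warning flags rank-deficient
#'   input with fewer than \code{k} positive singular values.
#' @export
pcaScores <- function(x, pseudo = 1, k = 2, scale. = FALSE,
                      log2_transform = TRUE) {
  mat <- if (is(x, "FeatureTable")) counts(x) else as.matrix(x)
  if (ncol(mat) < 3) stop("pcaScores needs >= 3 samples")
  if (log2_transform) mat <- log2(mat + pseudo)
  keep <- apply(mat, 1, function(z) stats::sd(z) > 0) | !scale.
  pc <- stats::prcomp(t(mat[keep, , drop = FALSE]), center = TRUE,
                      scale. = scale.)
  npos <- sum(pc$sdev > sqrt(.Machine$double.eps) * pc$sdev[1])
  if (npos < k)
    warning("rank-deficient input: only ", npos,
            " non-degenerate component(s)")
  pc$x[, seq_len(min(k, ncol(pc$x))), drop = FALSE]
}
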