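#' Assign precursor-bias bins
#'
#' Sorts dual-quantified features into the five precursor-bias bins by
#' their replicate-mean mol\% and the incorporation t-test:
#' \itemize{
#'   \item bin1 — no bias: dominant mol\% in [50, 60), assigned
#'     regardless of the test;
#'   \item bin2 / bin3 — biased: 60-80 mol\% toward Phe / Tyr, with
#'     \code{p < alpha};
#'   \item bin4 / bin5 — exclusive: >= 80 mol\% toward Phe / Tyr, with
#'     \code{p < alpha}.
#' }
#' Intervals are half-open ([50,60), [60,80), [80,100]) so coverage is
#' exhaustive and non-overlapping; a value of exactly 60 is biased and
#' exactly 80 is exclusive. Features with a bias >= 60 that fail the
#' test are \code{"unbinned"}. With \code{require_test = FALSE} bins come
#' from mol\% alone (the no-filter display mode).
#'
#' @param records Enrichment records from \code{\link{quantifyEnrichment}}
#'   with defined mol values (rows with \code{defined == FALSE} must be
#'   filtered out first).
#' @param alpha Significance level of the t-test filter.
#' @param require_test Apply the t-test filter?
#' @return \code{records} with added columns \code{bin} (\code{"bin1"}..
#'   \code{"bin5"} or \code{"unbinned"}), \code{dominant_precursor}
#'   (\code{"Phe"}, \code{"Tyr"} or \code{"neither"} at an exact 50/50
#'   split) and \code{mol_dominant}.
#' @examples
#' rec <- S4Vectors::DataFrame(anchor_id = "a", tissue = "leaf",
#'   mol_phe = 86, mol_tyr = 14, p_value = 0.01)
#' assignBins(rec)$bin  # "bin4"
#' @export
assignBins <- function(records, alpha = 0.05, require_test = TRUE) {
  if (any(is.na(records$mol_phe)) || any(is.na(records$mol_tyr)))
    stop("undefined mol% in records; filter undefined rows first")
  dom <- pmax(records$mol_phe, records$mol_tyr)
  phe_dom <- records$mol_phe > records$mol_tyr
  tested <- if (require_test)
    !is.na(records$p_value) & records$p_value < alpha else
    rep(TRUE, nrow(records))
  bin <- rep("unbinned", nrow(records))
  bin[dom < 60] <- "bin1"
  bin[dom >= 60 & dom < 80 & tested] <- ifelse(
    phe_dom[dom >= 60 & dom < 80 & tested], "bin2", "bin3")
  bin[dom >= 80 & tested] <- ifelse(
    phe_dom[dom >= 80 & tested], "bin4", "bin5")
  records$bin <- bin
  records$dominant_precursor <- ifelse(
    records$mol_phe == records$mol_tyr, "neither",
    ifelse(phe_dom, "Phe", "Tyr"))
  records$mol_dominant <- dom
  records
}

#' Tabulate the share of labeled features per bin
#'
#' Per tissue, the percent of labeled features falling in each bin. Two
#' denominators are reported: all labeled features including the
#' unbinned ones (\code{pct}) and only the binned ones
#' (\code{pct_of_binned}).
#'
#' @param assignments Output of \code{\link{assignBins}}.
#' @return A \link[S4Vectors]{DataFrame} with columns \code{tissue},
#'   \code{bin}, \code{n}, \code{pct}, \code{pct_of_binned}.
#' @export
binSummary <- function(assignments) {
  stopifnot(nrow(assignments) > 0)
  bins <- c(paste0("bin", 1:5), "unbinned")
  out <- list()
  for (ti in unique(assignments$tissue)) {
    sub <- assignments[assignments$tissue == ti, ]
    cnt <- table(factor(sub$bin, levels = bins))
    n_all <- sum(cnt)
    n_binned <- sum(cnt[paste0("bin", 1:5)])
    out[[length(out) + 1L]] <- data.frame(
      tissue = ti, bin = bins, n = as.integer(cnt),
      pct = 100 * as.integer(cnt) / n_all,
      pct_of_binned = ifelse(bins == "unbinned", NA_real_,
                             100 * as.integer(cnt) / n_binned),
      stringsAsFactors = FALSE)
  }
  DataFrame(do.call(rbind, out))
}

#' Aggregate labeled ion signal per bin
#'
#' Estimates precursor flux partitioning: per tissue and precursor, the
#' \eqn{{}^{13}C}-isotopologue ion counts (summed over that precursor's
#' \eqn{{}^{13}C}-fed replicates) of the features in each bin, as a
#' percent of the labeled ion counts over all library features in that
#' tissue/precursor. Shares over the five bins plus the unbinned
#' remainder sum to 100.
#'
#' @param assignments Output of \code{\link{assignBins}}.
#' @param library Library entries (for the labeled feature ids).
#' @param x The labeling \linkS4class{FeatureTable}.
#' @return A \link[S4Vectors]{DataFrame} with columns \code{tissue},
#'   \code{precursor}, \code{bin}, \code{labeled_ion_count}, \code{pct}.
#' @export
binFlux <- function(assignments, library, x) {
  cd <- colData(x)
  cts <- counts(x)
  ids <- featureIds(x)
  bins <- c(paste0("bin", 1:5), "unbinned")
  lab_ids <- lapply(seq_len(nrow(library)), function(i)
    stats::na.omit(unlist(library[i, c("labeled_1", "labeled_2",
                                       "labeled_3")], use.names = FALSE)))
  names(lab_ids) <- library$anchor_id
  out <- list()
  for (ti in unique(assignments$tissue)) {
    sub <- assignments[assignments$tissue == ti, ]
    for (pre in c("Phe", "Tyr")) {
      samps <- which(!is.na(cd$tissue) & cd$tissue == ti &
                       !is.na(cd$precursor) & cd$precursor == pre &
                       !is.na(cd$isotope) & cd$isotope == "13C")
      sig <- vapply(sub$anchor_id, function(a) {
        li <- lab_ids[[a]]
        if (is.null(li) || length(li) == 0) return(0)
        sum(cts[match(li, ids), samps, drop = FALSE])
      }, numeric(1))
      tot <- sum(sig)
      agg <- vapply(bins, function(b) sum(sig[sub$bin == b]), numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        tissue = ti, precursor = pre, bin = bins,
        labeled_ion_count = unname(agg),
        pct = if (tot > 0) 100 * unname(agg) / tot else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  DataFrame(do.call(rbind, out))
}
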