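#' Labeled fraction of a metabolite pool
#'
#' For one pair group and a set of \eqn{{}^{13}C}-fed samples, computes
#' per replicate the share of the feature's pool carried by its labeled
#' isotopologues:
#' \deqn{f = (I_6 + I_{12} + I_{18}) / (I_0 + I_6 + I_{12} + I_{18})}
#' where \eqn{I_0} is the unlabeled anchor's ion count and \eqn{I_{6k}}
#' the +6k isotopologue counts present in the group. Replicates with a
#' zero total pool are excluded and flagged. Multi-ring isotopologues
#' contribute raw ion counts without ring-multiplicity weighting.
#'
#' @param pair A single pair-group row (from \code{\link{findPairs}} or a
#'   library entry from \code{\link{buildLibrary}}).
#' @param x The \linkS4class{FeatureTable}.
#' @param samples Character or integer index of the \eqn{{}^{13}C}-fed
#'   samples to use.
#' @return List with \code{per_replicate} (named numeric, \code{NA} for
#'   excluded replicates), \code{mean} (over usable replicates) and
#'   \code{n_excluded}.
#' @examples
#' # a 75/25 split gives a labeled fraction of 0.25
#' @export
labeledFraction <- function(pair, x, samples) {
  stopifnot(length(samples) >= 1)
  cts <- counts(x)[, samples, drop = FALSE]
  ids <- featureIds(x)
  i0 <- match(pair$anchor_id, ids)
  if (is.na(i0)) stop("anchor ", pair$anchor_id, " not in table")
  lab_ids <- stats::na.omit(unlist(pair[c("labeled_1", "labeled_2",
                                          "labeled_3")], use.names = FALSE))
  il <- match(lab_ids, ids)
  if (anyNA(il)) stop("labeled feature(s) not in table")
  i_lab <- colSums(cts[il, , drop = FALSE])
  tot <- cts[i0, ] + i_lab
  f <- ifelse(tot > 0, i_lab / tot, NA_real_)
  names(f) <- colnames(cts)
  list(per_replicate = f,
       mean = if (all(is.na(f))) NA_real_ else mean(f, na.rm = TRUE),
       n_excluded = sum(is.na(f)))
}

#' Convert paired labeled fractions to mol percent of origin
#'
#' Normalizes the labeled fractions measured under the two feedings into
#' relative de novo contributions:
#' \code{mol_phe = 100 * frac_phe / (frac_phe + frac_tyr)} and
#' \code{mol_tyr = 100 - mol_phe}. With 25\% of a pool labeled from Phe
#' and 4.2\% from Tyr, the pool is 86 mol\% Phe-derived (nearest
#' integer).
#'
#' @param frac_phe,frac_tyr Labeled fractions in [0, 1] (vectorized).
#' @return List with numeric \code{mol_phe} and \code{mol_tyr}
#'   (percent); \code{NA} where both fractions are zero (undefined — the
#'   feature was not labeled by either precursor).
#' @examples
#' molPercent(0.25, 0.042)$mol_phe  # ~85.6, rounds to 86
#' molPercent(0.3, 0)               # exclusive Phe origin: 100 / 0
#' @export
molPercent <- function(frac_phe, frac_tyr) {
  stopifnot(all(frac_phe >= 0 | is.na(frac_phe)),
            all(frac_tyr >= 0 | is.na(frac_tyr)))
  tot <- frac_phe + frac_tyr
  mol_phe <- ifelse(!is.na(tot) & tot > 0, 100 * frac_phe / tot, NA_real_)
  list(mol_phe = mol_phe, mol_tyr = 100 - mol_phe)
}

#' Test for differential precursor incorporation
#'
#' Two-sided unequal-variance (Welch) two-sample t-test comparing
#' per-replicate percent \eqn{{}^{13}C} incorporation between the
#' Phe-fed and Tyr-fed arms. This is the filter behind the biased bins:
#' a bias in mean mol\% only counts when incorporation differs
#' significantly between the feedings.
#'
#' @param frac_phe,frac_tyr Per-replicate labeled fractions (or percent
#'   values; the test is scale-invariant) for the two arms; \code{NA}s
#'   dropped.
#' @return The p-value, or \code{NA} when either arm has fewer than 2
#'   usable replicates.
#' @export
incorporationTest <- function(frac_phe, frac_tyr) {
  x <- frac_phe[!is.na(frac_phe)]
  y <- frac_tyr[!is.na(frac_tyr)]
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Quantify precursor-of-origin enrichment per feature and tissue
#'
#' Runs \code{\link{labeledFraction}} for every library entry in each
#' tissue's \eqn{{}^{13}C}-Phe and \eqn{{}^{13}C}-Tyr arms, averages the
#' per-replicate fractions, converts the pair of means to mol\% with
#' \code{\link{molPercent}}, and attaches the
#' \code{\link{incorporationTest}} p-value. Fractions are computed per
#' replicate and then averaged (the test operates on replicate-level
#' incorporation); set \code{pooled = TRUE} to instead compute one
#' fraction from replicate-summed pools.
#'
#' @param x The \linkS4class{FeatureTable} from the labeling experiment.
#' @param library Library entries from \code{\link{buildLibrary}} (pair
#'   groups from \code{\link{findPairs}} also work).
#' @param tissues Tissues to quantify; default all in the design.
#' @param pooled Use summed pools instead of per-replicate fractions for
#'   the reported means (the t-test always uses per-replicate values).
#' @return A \link[S4Vectors]{DataFrame} with one row per (entry,
#'   tissue): \code{anchor_id}, \code{tissue}, \code{frac_phe},
#'   \code{frac_tyr}, \code{mol_phe}, \code{mol_tyr}, \code{p_value},
#'   \code{n_phe}, \code{n_tyr}, and \code{defined} (\code{FALSE} when
#'   both fractions are zero or no replicate was usable).
#' @export
quantifyEnrichment <- function(x, library, tissues = NULL,
                               pooled = FALSE) {
  cd <- colData(x)
  if (is.null(tissues))
    tissues <- unique(cd$tissue[!is.na(cd$tissue)])
  out <- list()
  for (ti in tissues) {
    arm <- function(pre) which(!is.na(cd$tissue) & cd$tissue == ti &
                                 !is.na(cd$precursor) & cd$precursor == pre &
                                 !is.na(cd$isotope) & cd$isotope == "13C")
    sp <- arm("Phe"); st <- arm("Tyr")
    if (length(sp) == 0 || length(st) == 0)
      stop("tissue ", ti, " lacks a 13C arm for one precursor")
    for (i in seq_len(nrow(library))) {
      entry <- library[i, ]
      fp <- labeledFraction(entry, x, sp)
      ft <- labeledFraction(entry, x, st)
      mfp <- fp$mean; mft <- ft$mean
      if (pooled) {
        pool_frac <- function(samps) {
          cts <- counts(x)[, samps, drop = FALSE]
          ids <- featureIds(x)
          lab_ids <- stats::na.omit(unlist(entry[c("labeled_1", "labeled_2",
                                                   "labeled_3")],
                                           use.names = FALSE))
          il <- sum(cts[match(lab_ids, ids), , drop = FALSE])
          i0 <- sum(cts[match(entry$anchor_id, ids), ])
          if (i0 + il > 0) il / (i0 + il) else NA_real_
        }
        mfp <- pool_frac(sp); mft <- pool_frac(st)
      }
      defined <- !is.na(mfp) && !is.na(mft) && (mfp + mft) > 0
      mol <- if (defined) molPercent(mfp, mft) else
        list(mol_phe = NA_real_, mol_tyr = NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        anchor_id = entry$anchor_id, tissue = ti,
        frac_phe = mfp, frac_tyr = mft,
        mol_phe = mol$mol_phe, mol_tyr = mol$mol_tyr,
        p_value = incorporationTest(100 * fp$per_replicate,
                                    100 * ft$per_replicate),
        n_phe = sum(!is.na(fp$per_replicate)),
        n_tyr = sum(!is.na(ft$per_replicate)),
        defined = defined,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(DataFrame(anchor_id = character(), tissue = character(),
                     frac_phe = numeric(), frac_tyr = numeric(),
                     mol_phe = numeric(), mol_tyr = numeric(),
                     p_value = numeric(), n_phe = integer(),
                     n_tyr = integer(), defined = logical()))
  DataFrame(do.call(rbind, out))
}
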