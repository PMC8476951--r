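#' Retrospectively annotate a feature table against the origin library
#'
#' Matches each feature of an unlabeled table (e.g. a mutant genotype
#' panel acquired in a separate run) to at most one library entry within
#' an m/z (ppm) and RT tolerance; among candidates the smallest combined
#' normalized distance \code{ppm_dist/tol_ppm + |drt|/tol_rt} wins. The
#' RT default is looser than for pairing because runs differ; an
#' optional global RT offset absorbs systematic drift between
#' experiments.
#'
#' @param x The \linkS4class{FeatureTable} to annotate.
#' @param library Library entries from \code{\link{buildLibrary}} (extra
#'   columns such as per-tissue mol\% are carried into the result).
#' @param tol_ppm m/z tolerance, ppm.
#' @param tol_rt RT tolerance, seconds.
#' @param rt_offset Global shift added to the table's RTs before
#'   matching (seconds).
#' @return A \link[S4Vectors]{DataFrame} with one row per annotated
#'   feature: \code{feature_id}, \code{library_anchor} plus all library
#'   columns of the matched entry.
#' @export
annotateFeatures <- function(x, library, tol_ppm = 15, tol_rt = 10,
                             rt_offset = 0) {
  stopifnot(tol_ppm > 0, tol_rt > 0)
  mz <- unname(featureMz(x))
  rt <- unname(featureRt(x)) + rt_offset
  ids <- featureIds(x)
  hit_id <- rep(NA_integer_, length(mz))
  for (i in seq_along(mz)) {
    dppm <- .ppm(mz[i], library$anchor_mz)
    drt <- abs(rt[i] - library$anchor_rt)
    ok <- which(dppm <= tol_ppm & drt <= tol_rt)
    if (length(ok)) {
      d <- dppm[ok] / tol_ppm + drt[ok] / tol_rt
      hit_id[i] <- ok[which.min(d)]
    }
  }
  keep <- which(!is.na(hit_id))
  res <- library[hit_id[keep], , drop = FALSE]
  out <- DataFrame(feature_id = ids[keep],
                   library_anchor = res$anchor_id)
  for (cn in setdiff(colnames(res), "anchor_id"))
    out[[cn]] <- res[[cn]]
  out
}

#' Differential abundance of annotated features between genotypes
#'
#' Per annotated feature and mutant genotype, a two-sided Welch t-test
#' on log2(count + pseudo) versus the wild type; \code{log2_fc} is the
#' difference of genotype means on that scale, and \code{direction} is
#' \code{"up"} / \code{"down"} when \code{p < alpha} (else
#' \code{"unchanged"}).
#'
#' @param x A \linkS4class{FeatureTable} whose \code{colData} has a
#'   \code{genotype} column (or pass \code{groups}).
#' @param annotation Output of \code{\link{annotateFeatures}}; only
#'   annotated features are tested.
#' @param groups Optional character vector of genotype labels per
#'   sample, overriding \code{colData(x)$genotype}.
#' @param wild_type Reference genotype name.
#' @param alpha Significance level.
#' @param pseudo Pseudo-count before the log2 transform.
#' @param log_scale Test on the log2 scale (default); \code{FALSE} tests
#'   raw counts (log2_fc still reported from log2 means).
#' @return A \link[S4Vectors]{DataFrame}: \code{feature_id},
#'   \code{library_anchor}, \code{genotype}, \code{log2_fc},
#'   \code{p_value}, \code{direction}.
#' @export
differentialTest <- function(x, annotation, groups = NULL,
                             wild_type = "WT", alpha = 0.05,
                             pseudo = 1, log_scale = TRUE) {
  if (is.null(groups)) groups <- colData(x)$genotype
  if (is.null(groups)) stop("no genotype information")
  groups <- as.character(groups)
  stopifnot(wild_type %in% groups)
  mutants <- setdiff(unique(groups), wild_type)
  cts <- counts(x)
  idx <- match(annotation$feature_id, featureIds(x))
  wt <- which(groups == wild_type)
  out <- list()
  for (g in mutants) {
    mu <- which(groups == g)
    if (length(mu) < 2 || length(wt) < 2) {
      warning("fewer than 2 replicates for ", g, " vs ", wild_type,
              "; skipped")
      next
    }
    for (r in seq_along(idx)) {
      a <- log2(cts[idx[r], mu] + pseudo)
      b <- log2(cts[idx[r], wt] + pseudo)
      ta <- if (log_scale) a else cts[idx[r], mu]
      tb <- if (log_scale) b else cts[idx[r], wt]
      p <- if (stats::sd(ta) == 0 && stats::sd(tb) == 0) {
        if (isTRUE(all.equal(mean(ta), mean(tb)))) 1 else 0
      } else stats::t.test(ta, tb, var.equal = FALSE)$p.value
      lfc <- mean(a) - mean(b)
      out[[length(out) + 1L]] <- data.frame(
        feature_id = annotation$feature_id[r],
        library_anchor = annotation$library_anchor[r],
        genotype = g, log2_fc = lfc, p_value = p,
        direction = if (p < alpha) {
          if (lfc > 0) "up" else "down"
        } else "unchanged",
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(DataFrame(feature_id = character(),
                     library_anchor = character(),
                     genotype = character(), log2_fc = numeric(),
                     p_value = numeric(), direction = character()))
  DataFrame(do.call(rbind, out))
}

#' Partition significant features between two mutants
#'
#' Exhaustive, disjoint partition of the features significantly changed
#' in either of two mutants, by direction and membership: down or up in
#' one mutant only, in both, or changed in opposite directions. The
#' seven counts sum to the number of features significant in at least
#' one mutant.
#'
#' @param res_a,res_b \code{\link{differentialTest}} results for the two
#'   mutants (single genotype each), on a shared annotated feature set.
#' @return Named integer vector: \code{down_A_only}, \code{down_B_only},
#'   \code{down_both}, \code{up_A_only}, \code{up_B_only},
#'   \code{up_both}, \code{opposing}.
#' @export
partitionOverlap <- function(res_a, res_b) {
  dir_a <- stats::setNames(res_a$direction, res_a$feature_id)
  dir_b <- stats::setNames(res_b$direction, res_b$feature_id)
  feats <- union(names(dir_a), names(dir_b))
  da <- dir_a[feats]; db <- dir_b[feats]
  da[is.na(da)] <- "unchanged"; db[is.na(db)] <- "unchanged"
  c(down_A_only = sum(da == "down" & db == "unchanged"),
    down_B_only = sum(da == "unchanged" & db == "down"),
    down_both = sum(da == "down" & db == "down"),
    up_A_only = sum(da == "up" & db == "unchanged"),
    up_B_only = sum(da == "unchanged" & db == "up"),
    up_both = sum(da == "up" & db == "up"),
    opposing = sum((da == "up" & db == "down") |
                     (da == "down" & db == "up")))
}
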