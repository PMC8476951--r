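#' Pairing parameters
#'
#' Tolerances and enrichment gates for \code{\link{findPairs}}. The m/z
#' tolerance is \code{max(tol_ppm * expected_mz * 1e-6, tol_mz_floor)};
#' the 15 ppm default echoes the usual peak-picking tolerance, with a
#' 0.005 Th absolute floor for low masses. The RT window applies to
#' already-aligned tables. The enrichment gates require the candidate
#' labeled feature to be at least \code{fold}-times more intense (mean
#' over replicates) in \eqn{{}^{13}C}-fed than in \eqn{{}^{12}C}-fed
#' samples and to pass a one-sided Welch t-test at \code{alpha};
#' \code{test = FALSE} disables the t-test gate, and
#' \code{require_absent = TRUE} additionally demands zero labeled-feature
#' signal in every \eqn{{}^{12}C}-fed sample.
#'
#' @param tol_ppm m/z tolerance, ppm.
#' @param tol_mz_floor Absolute m/z tolerance floor, Th.
#' @param tol_rt Co-elution tolerance, seconds.
#' @param fold Minimum \eqn{{}^{13}C}/\eqn{{}^{12}C} mean-intensity ratio.
#' @param alpha Significance level of the one-sided enrichment t-test.
#' @param test Apply the t-test gate?
#' @param require_absent Require zero signal in \eqn{{}^{12}C}-fed
#'   samples?
#' @param max_rings Largest ring shift searched (1-3).
#' @return A named list of parameters.
#' @export
pairParams <- function(tol_ppm = 15, tol_mz_floor = 0.005, tol_rt = 5,
                       fold = 2, alpha = 0.05, test = TRUE,
                       require_absent = FALSE, max_rings = 3L) {
  stopifnot(tol_ppm > 0, tol_mz_floor >= 0, tol_rt > 0, fold >= 1,
            alpha > 0, alpha < 1, max_rings %in% 1:3)
  list(tol_ppm = tol_ppm, tol_mz_floor = tol_mz_floor, tol_rt = tol_rt,
       fold = fold, alpha = alpha, test = isTRUE(test),
       require_absent = isTRUE(require_absent),
       max_rings = as.integer(max_rings))
}

# one-sided Welch p-value robust to zero-variance arms
.welchGreater <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (mean(x) > mean(y)) 0 else 1)
  stats::t.test(x, y, alternative = "greater", var.equal = FALSE)$p.value
}

# samples of one precursor design, split by isotope arm
.designArms <- function(x, precursor) {
  cd <- colData(x)
  sel <- which(!is.na(cd$precursor) & cd$precursor == precursor)
  if (length(sel) == 0)
    stop("no samples for precursor ", precursor)
  iso <- cd$isotope[sel]
  if (!all(c("12C", "13C") %in% iso))
    stop("design for precursor ", precursor,
         " must contain both 12C and 13C arms")
  list(c12 = sel[iso == "12C"], c13 = sel[iso == "13C"])
}

#' Detect co-eluting isotopologue peak pairs
#'
#' Scans one precursor's feeding design (its \eqn{{}^{12}C}- and
#' \eqn{{}^{13}C}-fed samples) for pairs of features separated by
#' \code{n * 6} times the \eqn{{}^{13}C}-\eqn{{}^{12}C} mass difference
#' (n = 1-3 labeled phenyl rings) that co-elute within the RT tolerance.
#' A candidate labeled feature must also be enriched in the
#' \eqn{{}^{13}C}-fed samples (fold and one-sided Welch t-test gates, see
#' \code{\link{pairParams}}). When several candidates satisfy the gates
#' for the same anchor and ring shift, the one with the smallest combined
#' normalized distance \code{|dmz|/tol_mz + |drt|/tol_rt} wins (input
#' order breaks exact ties). Matches for the same anchor are merged
#' across ring shifts into one pair group, whose \code{ring_count} is the
#' largest shift found and whose \code{dual_labeled} flag marks groups
#' with any shift >= 2 (lignan/neolignan candidates). Finally, a group
#' whose anchor itself sits at an expected ring-shift position (within
#' twice the mass and RT gates) of another candidate anchor is dropped:
#' isotopologue rows must not anchor chains of spurious higher-shift
#' pairs.
#'
#' @param x A \linkS4class{FeatureTable} containing both isotope arms for
#'   \code{precursor}.
#' @param precursor \code{"Phe"} or \code{"Tyr"}: which feeding design to
#'   scan.
#' @param params Gates and tolerances from \code{\link{pairParams}}.
#' @return A \link[S4Vectors]{DataFrame} with one row per pair group:
#'   \code{anchor_id}, \code{anchor_mz}, \code{anchor_rt},
#'   \code{labeled_1}..\code{labeled_3} (feature ids, \code{NA} when the
#'   shift was not found), \code{ring_count}, \code{dual_labeled},
#'   \code{precursor}, \code{enrichment_p} and \code{fold_enrichment} of
#'   the smallest-shift labeled member.
#' @examples
#' sim <- simulateExperiment(n_per_archetype = c(unbiased = 5, decoy = 5),
#'                           tissues = "leaf", seed = 7)
#' findPairs(sim$table, "Phe")
#' @export
findPairs <- function(x, precursor = c("Phe", "Tyr"),
                      params = pairParams()) {
  precursor <- match.arg(precursor)
  arms <- .designArms(x, precursor)
  if (params$test && (length(arms$c12) < 2 || length(arms$c13) < 2))
    stop("enrichment t-test needs >= 2 replicates per isotope arm")
  cts <- counts(x)
  mz <- unname(featureMz(x))
  rt <- unname(featureRt(x))
  ids <- featureIds(x)
  n <- length(mz)
  empty <- DataFrame(anchor_id = character(), anchor_mz = numeric(),
                     anchor_rt = numeric(), labeled_1 = character(),
                     labeled_2 = character(), labeled_3 = character(),
                     ring_count = integer(), dual_labeled = logical(),
                     precursor = character(), enrichment_p = numeric(),
                     fold_enrichment = numeric())
  if (n == 0) return(empty)

  m13 <- rowMeans(cts[, arms$c13, drop = FALSE])
  m12 <- rowMeans(cts[, arms$c12, drop = FALSE])
  ord <- order(mz)
  mz_s <- mz[ord]

  # enrichment gates, evaluated lazily per candidate labeled feature
  gate_cache <- rep(NA, n)
  p_cache <- rep(NA_real_, n)
  passes <- function(j) {
    if (!is.na(gate_cache[j])) return(gate_cache[j])
    ok <- m13[j] >= params$fold * m12[j] && m13[j] > 0
    if (ok && params$require_absent)
      ok <- all(cts[j, arms$c12] == 0)
    if (ok && params$test) {
      p_cache[j] <<- .welchGreater(cts[j, arms$c13], cts[j, arms$c12])
      ok <- p_cache[j] < params$alpha
    }
    gate_cache[j] <<- ok
    ok
  }

  hit <- vector("list", params$max_rings)
  for (k in seq_len(params$max_rings)) {
    target <- mz + k * 6 * C13C12_MASS_DIFF
    tol <- pmax(params$tol_ppm * 1e-6 * target, params$tol_mz_floor)
    lo <- findInterval(target - tol, mz_s) + 1L
    hi <- findInterval(target + tol, mz_s)
    len <- pmax(hi - lo + 1L, 0L)
    anch <- rep.int(seq_len(n), len)
    if (length(anch) == 0) next
    cand <- ord[unlist(lapply(which(len > 0), function(i)
      seq.int(lo[i], hi[i])), use.names = FALSE)]
    keep <- cand != anch &
      abs(rt[cand] - rt[anch]) <= params$tol_rt
    anch <- anch[keep]; cand <- cand[keep]
    if (length(anch) == 0) next
    keep <- vapply(cand, passes, logical(1))
    anch <- anch[keep]; cand <- cand[keep]
    if (length(anch) == 0) next
    dist <- abs(mz[cand] - target[anch]) / tol[anch] +
      abs(rt[cand] - rt[anch]) / params$tol_rt
    o <- order(anch, dist, cand)
    anch <- anch[o]; cand <- cand[o]; dist <- dist[o]
    first <- !duplicated(anch)
    hit[[k]] <- data.frame(anchor = anch[first], labeled = cand[first],
                           k = k)
  }
  hits <- do.call(rbind, hit)
  if (is.null(hits) || nrow(hits) == 0) return(empty)

  # chain suppression: drop groups whose anchor sits at an expected
  # ring-shift position of another candidate anchor (isotopologue rows
  # must not anchor spurious higher-shift pairs); the window is twice
  # the pairing gates because two independent mass errors separate an
  # anchor from its isotopologue row, and suppressing a borderline
  # anchor is cheap while missing one creates a false pair group
  anchors0 <- unique(hits$anchor)
  is_shift <- vapply(anchors0, function(b) {
    others <- setdiff(anchors0, b)
    if (length(others) == 0) return(FALSE)
    for (k in seq_len(params$max_rings)) {
      tg <- mz[others] + k * 6 * C13C12_MASS_DIFF
      tl <- 2 * pmax(params$tol_ppm * 1e-6 * tg, params$tol_mz_floor)
      if (any(abs(mz[b] - tg) <= tl &
                abs(rt[b] - rt[others]) <= 2 * params$tol_rt))
        return(TRUE)
    }
    FALSE
  }, logical(1))
  hits <- hits[!(hits$anchor %in% anchors0[is_shift]), , drop = FALSE]
  if (nrow(hits) == 0) return(empty)

  anchors <- sort(unique(hits$anchor))
  lab <- matrix(NA_integer_, length(anchors), 3)
  for (r in seq_len(nrow(hits)))
    lab[match(hits$anchor[r], anchors), hits$k[r]] <- hits$labeled[r]
  ring <- apply(lab, 1, function(z) max(which(!is.na(z))))
  firstlab <- lab[cbind(seq_along(anchors),
                        apply(lab, 1, function(z) which(!is.na(z))[1]))]
  DataFrame(
    anchor_id = ids[anchors],
    anchor_mz = mz[anchors],
    anchor_rt = rt[anchors],
    labeled_1 = ifelse(is.na(lab[, 1]), NA_character_, ids[lab[, 1]]),
    labeled_2 = ifelse(is.na(lab[, 2]), NA_character_, ids[lab[, 2]]),
    labeled_3 = ifelse(is.na(lab[, 3]), NA_character_, ids[lab[, 3]]),
    ring_count = as.integer(ring),
    dual_labeled = ring >= 2L,
    precursor = precursor,
    enrichment_p = p_cache[firstlab],
    fold_enrichment = ifelse(m12[firstlab] > 0,
                             m13[firstlab] / m12[firstlab], Inf)
  )
}

#' Flag pair groups carrying more than one labeled ring
#'
#' Refreshes the \code{dual_labeled} flag: a group with any +12 or +18
#' isotopologue incorporated two or more labeled phenyl rings, the
#' signature of lignans and neolignans.
#'
#' @param pairs Pair groups from \code{\link{findPairs}}.
#' @return \code{pairs} with an up-to-date \code{dual_labeled} column.
#' @export
flagDualLabeled <- function(pairs) {
  pairs$dual_labeled <- !is.na(pairs$labeled_2) | !is.na(pairs$labeled_3)
  pairs
}

#' Build the precursor-origin library
#'
#' Unions pair groups detected in the Phe and Tyr feeding designs by
#' matching unlabeled anchors on m/z (ppm) and RT. Each library entry
#' records which precursor(s) labeled the feature: entries found in both
#' designs are of mixed origin; an entry found in only one design is an
#' exclusive-origin candidate (e.g. dhurrin is Tyr-only). Labeled feature
#' ids from both designs are merged per ring shift (the Phe design's id
#' wins when both exist, which matters only when the same isotopologue
#' row was named differently — with a shared feature table it never is).
#'
#' @param pairs_phe,pairs_tyr Pair groups from \code{\link{findPairs}}
#'   run on the Phe and Tyr designs.
#' @param tol_ppm Anchor-matching m/z tolerance, ppm.
#' @param tol_rt Anchor-matching RT tolerance, seconds.
#' @return A \link[S4Vectors]{DataFrame} with one row per library entry:
#'   anchor coordinates, \code{origin} (\code{"Phe"}, \code{"Tyr"} or
#'   \code{"Phe+Tyr"}), merged \code{labeled_1..3} ids, \code{ring_count}
#'   and \code{dual_labeled}.
#' @export
buildLibrary <- function(pairs_phe, pairs_tyr, tol_ppm = 15, tol_rt = 5) {
  np <- nrow(pairs_phe); nt <- nrow(pairs_tyr)
  matched_t <- integer(0)
  rows <- list()
  used_t <- rep(FALSE, nt)
  for (i in seq_len(np)) {
    origin <- "Phe"
    l1 <- pairs_phe$labeled_1[i]; l2 <- pairs_phe$labeled_2[i]
    l3 <- pairs_phe$labeled_3[i]
    j <- which(!used_t &
                 .ppm(pairs_tyr$anchor_mz, pairs_phe$anchor_mz[i]) <= tol_ppm &
                 abs(pairs_tyr$anchor_rt - pairs_phe$anchor_rt[i]) <= tol_rt)
    if (length(j)) {
      d <- .ppm(pairs_tyr$anchor_mz[j], pairs_phe$anchor_mz[i]) / tol_ppm +
        abs(pairs_tyr$anchor_rt[j] - pairs_phe$anchor_rt[i]) / tol_rt
      j <- j[which.min(d)]
      used_t[j] <- TRUE
      origin <- "Phe+Tyr"
      if (is.na(l1)) l1 <- pairs_tyr$labeled_1[j]
      if (is.na(l2)) l2 <- pairs_tyr$labeled_2[j]
      if (is.na(l3)) l3 <- pairs_tyr$labeled_3[j]
    }
    rows[[length(rows) + 1L]] <- data.frame(
      anchor_id = pairs_phe$anchor_id[i],
      anchor_mz = pairs_phe$anchor_mz[i],
      anchor_rt = pairs_phe$anchor_rt[i],
      origin = origin, labeled_1 = l1, labeled_2 = l2, labeled_3 = l3,
      stringsAsFactors = FALSE)
  }
  for (j in which(!used_t)) {
    rows[[length(rows) + 1L]] <- data.frame(
      anchor_id = pairs_tyr$anchor_id[j],
      anchor_mz = pairs_tyr$anchor_mz[j],
      anchor_rt = pairs_tyr$anchor_rt[j],
      origin = "Tyr",
      labeled_1 = pairs_tyr$labeled_1[j],
      labeled_2 = pairs_tyr$labeled_2[j],
      labeled_3 = pairs_tyr$labeled_3[j],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(DataFrame(anchor_id = character(), anchor_mz = numeric(),
                     anchor_rt = numeric(), origin = character(),
                     labeled_1 = character(), labeled_2 = character(),
                     labeled_3 = character(), ring_count = integer(),
                     dual_labeled = logical()))
  lib <- DataFrame(do.call(rbind, rows))
  ring <- rep(0L, nrow(lib))
  for (k in 3:1)
    ring[ring == 0L & !is.na(lib[[paste0("labeled_", k)]])] <- k
  lib$ring_count <- ring
  lib$dual_labeled <- !is.na(lib$labeled_2) | !is.na(lib$labeled_3)
  lib
}

#' Score pair detection against planted truth
#'
#' Compares detected pair groups with the ground truth of
#' \code{\link{simulateExperiment}}: a planted ring-bearing feature
#' counts as recoverable in a design when its labeled fraction for that
#' precursor is at least \code{min_frac}; it is recovered when a detected
#' group is anchored on its emitted \eqn{{}^{12}C} feature id. Detected
#' groups anchored elsewhere (decoys, isotopologue rows, features below
#' \code{min_frac}) count as false discoveries if their anchor is not a
#' labeled planted anchor at all.
#'
#' @param pairs Pair groups from \code{\link{findPairs}}.
#' @param truth Ground truth from \code{\link{simulateExperiment}}.
#' @param precursor Which design the pairs came from.
#' @param min_frac Labeled-fraction floor defining recoverable features.
#' @return Named list: \code{sensitivity}, \code{fdp}, \code{n_true},
#'   \code{n_detected}.
#' @export
pairingRecovery <- function(pairs, truth, precursor = c("Phe", "Tyr"),
                            min_frac = 0.05) {
  precursor <- match.arg(precursor)
  f <- if (precursor == "Phe") truth$true_frac_phe else truth$true_frac_tyr
  labeled_any <- truth$ring_count > 0 & f > 0
  recoverable <- truth$anchor_id[truth$ring_count > 0 & f >= min_frac]
  true_anchors <- truth$anchor_id[labeled_any]
  det <- pairs$anchor_id
  list(sensitivity = if (length(recoverable))
         mean(recoverable %in% det) else NA_real_,
       fdp = if (length(det)) mean(!(det %in% true_anchors)) else 0,
       n_true = length(recoverable),
       n_detected = length(det))
}
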