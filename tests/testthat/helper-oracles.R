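# Independent oracles: deliberately naive re-implementations used to
# cross-check the package. They share no code with R/.

# textbook Welch two-sample t-test
welch_oracle <- function(x, y, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  if (vx == 0 && vy == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    if (alternative == "greater") return(if (mean(x) > mean(y)) 0 else 1)
    return(if (eq) 1 else 0)
  }
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  if (alternative == "greater") pt(tstat, df, lower.tail = FALSE)
  else 2 * pt(-abs(tstat), df)
}

# OLS by normal equations
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# exhaustive quadratic scan implementing the pairing rules literally
brute_force_pairs <- function(tab, precursor, params = pairParams()) {
  cd <- as.data.frame(SummarizedExperiment::colData(tab))
  s13 <- which(cd$precursor == precursor & cd$isotope == "13C")
  s12 <- which(cd$precursor == precursor & cd$isotope == "12C")
  cts <- counts(tab)
  mz <- unname(featureMz(tab)); rt <- unname(featureRt(tab))
  ids <- featureIds(tab)
  n <- length(mz)
  delta <- 6 * 1.0033548
  m13 <- apply(cts[, s13, drop = FALSE], 1, mean)
  m12 <- apply(cts[, s12, drop = FALSE], 1, mean)
  gate <- logical(n)
  for (j in seq_len(n)) {
    ok <- m13[j] >= params$fold * m12[j] && m13[j] > 0
    if (ok && params$require_absent) ok <- all(cts[j, s12] == 0)
    if (ok && params$test)
      ok <- welch_oracle(cts[j, s13], cts[j, s12], "greater") < params$alpha
    gate[j] <- ok
  }
  sel <- list()
  for (i in seq_len(n)) for (k in seq_len(params$max_rings)) {
    target <- mz[i] + k * delta
    tol <- max(params$tol_ppm * 1e-6 * target, params$tol_mz_floor)
    best <- NA_integer_; best_d <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      if (abs(mz[j] - target) > tol) next
      if (abs(rt[j] - rt[i]) > params$tol_rt) next
      if (!gate[j]) next
      d <- abs(mz[j] - target) / tol + abs(rt[j] - rt[i]) / params$tol_rt
      if (d < best_d) { best_d <- d; best <- j }
    }
    if (!is.na(best)) sel[[length(sel) + 1L]] <- c(i, best, k)
  }
  if (length(sel) == 0)
    return(data.frame(anchor_id = character(), labeled_1 = character(),
                      labeled_2 = character(), labeled_3 = character(),
                      ring_count = integer(), stringsAsFactors = FALSE))
  sel <- do.call(rbind, sel)
  anchors0 <- unique(sel[, 1])
  shifted <- anchors0[vapply(anchors0, function(b) {
    for (a in setdiff(anchors0, b)) for (k in seq_len(params$max_rings)) {
      tg <- mz[a] + k * delta
      tol <- 2 * max(params$tol_ppm * 1e-6 * tg, params$tol_mz_floor)
      if (abs(mz[b] - tg) <= tol && abs(rt[b] - rt[a]) <= 2 * params$tol_rt)
        return(TRUE)
    }
    FALSE
  }, logical(1))]
  sel <- sel[!(sel[, 1] %in% shifted), , drop = FALSE]
  if (nrow(sel) == 0)
    return(data.frame(anchor_id = character(), labeled_1 = character(),
                      labeled_2 = character(), labeled_3 = character(),
                      ring_count = integer(), stringsAsFactors = FALSE))
  anchors <- sort(unique(sel[, 1]))
  out <- data.frame(anchor_id = ids[anchors],
                    labeled_1 = NA_character_, labeled_2 = NA_character_,
                    labeled_3 = NA_character_, ring_count = 0L,
                    stringsAsFactors = FALSE)
  for (r in seq_len(nrow(sel))) {
    at <- match(sel[r, 1], anchors)
    out[at, paste0("labeled_", sel[r, 3])] <- ids[sel[r, 2]]
    out$ring_count[at] <- max(out$ring_count[at], sel[r, 3])
  }
  out[order(out$anchor_id), , drop = FALSE]
}

# compare findPairs output with the brute-force scan
expect_pairs_identical <- function(tab, precursor, params = pairParams()) {
  got <- as.data.frame(findPairs(tab, precursor, params))
  got <- got[order(got$anchor_id),
             c("anchor_id", "labeled_1", "labeled_2", "labeled_3",
               "ring_count")]
  rownames(got) <- NULL
  want <- brute_force_pairs(tab, precursor, params)
  rownames(want) <- NULL
  expect_identical(got, want)
}
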