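test_that("labeled fraction is the labeled share of the pool, per replicate", {
  # I0 = 75, I6 = 25 in every replicate -> fraction 0.25
  d <- toy_design()
  cts <- rbind(c(100, 100, 75, 75), c(0, 0, 25, 25))
  colnames(cts) <- d$sample_id
  tab <- FeatureTable(cts, mz = c(310.0935, 316.1138), rt = c(325, 325),
                      sampleData = d)
  pair <- findPairs(tab, "Phe")
  s13 <- which(d$isotope == "13C")
  lf <- labeledFraction(pair[1, ], tab, s13)
  expect_equal(unname(lf$per_replicate), c(0.25, 0.25), tolerance = 1e-12)
  expect_equal(lf$mean, 0.25, tolerance = 1e-12)
  # all-zero labeled signal gives fraction 0
  s12 <- which(d$isotope == "12C")
  expect_equal(labeledFraction(pair[1, ], tab, s12)$mean, 0)
})

test_that("labeled fraction matches direct arithmetic on random intensities", {
  withr::with_seed(61, {
    for (rep in 1:20) {
      i0 <- runif(3, 0, 1e5)
      i6 <- runif(3, 0, 1e4)
      i12 <- runif(3, 0, 1e3)
      d <- expand.grid(replicate = 1:3, isotope = c("12C", "13C"),
                       precursor = "Phe", tissue = "leaf",
                       stringsAsFactors = FALSE)
      d$sample_id <- paste0("s", 1:6)
      cts <- rbind(c(i0, i0), c(0, 0, 0, i6), c(0, 0, 0, i12))
      colnames(cts) <- d$sample_id
      m0 <- runif(1, 200, 700)
      tab <- FeatureTable(cts, mz = m0 + c(0, 6, 12) * 1.0033548,
                          rt = rep(300, 3), sampleData = d)
      pair <- S4Vectors::DataFrame(anchor_id = featureIds(tab)[1],
                                   labeled_1 = featureIds(tab)[2],
                                   labeled_2 = featureIds(tab)[3],
                                   labeled_3 = NA_character_)
      lf <- labeledFraction(pair, tab, 4:6)
      expect_equal(unname(lf$per_replicate),
                   (i6 + i12) / (i0 + i6 + i12), tolerance = 1e-12)
    }
  })
})

test_that("labeled fraction is invariant to uniform intensity rescaling", {
  tab <- toy_table()
  pair <- findPairs(tab, "Phe")
  s13 <- which(sampleData(tab)$isotope == "13C")
  f1 <- labeledFraction(pair[1, ], tab, s13)$per_replicate
  scaled <- FeatureTable(counts(tab) * 37.5, mz = featureMz(tab),
                         rt = featureRt(tab),
                         sampleData = as.data.frame(sampleData(tab)) |>
                           (\(d) { d$sample_id <- rownames(d); d })())
  f2 <- labeledFraction(pair[1, ], scaled, s13)$per_replicate
  expect_equal(unname(f1), unname(f2), tolerance = 1e-12)
})

test_that("zero-pool replicates are excluded and flagged", {
  d <- toy_design()
  cts <- rbind(c(100, 100, 75, 0), c(0, 0, 25, 0))
  colnames(cts) <- d$sample_id
  tab <- FeatureTable(cts, mz = c(310.0935, 316.1138), rt = c(325, 325),
                      sampleData = d)
  pair <- S4Vectors::DataFrame(anchor_id = "M310T325",
                               labeled_1 = "M316T325",
                               labeled_2 = NA_character_,
                               labeled_3 = NA_character_)
  lf <- labeledFraction(pair, tab, 3:4)
  expect_identical(lf$n_excluded, 1L)
  expect_equal(lf$mean, 0.25, tolerance = 1e-12)
  lf0 <- labeledFraction(pair, tab, 4)
  expect_true(is.na(lf0$mean))
  expect_identical(lf0$n_excluded, 1L)
})

test_that("mol percent normalizes paired fractions", {
  # the worked leaf example: 25% labeled from Phe, 4.2% from Tyr
  m <- molPercent(0.25, 0.042)
  expect_identical(round(m$mol_phe), 86)
  expect_equal(m$mol_phe + m$mol_tyr, 100, tolerance = 1e-9)
  # symmetry and exclusivity
  expect_equal(molPercent(0.123, 0.123)$mol_phe, 50, tolerance = 1e-12)
  expect_equal(molPercent(0.30, 0)$mol_phe, 100, tolerance = 1e-12)
  expect_equal(molPercent(0.30, 0)$mol_tyr, 0, tolerance = 1e-12)
  # undefined when both fractions are zero
  expect_true(is.na(molPercent(0, 0)$mol_phe))
  # vectorized normalization always sums to 100 when defined
  withr::with_seed(71, {
    fp <- runif(50); ft <- runif(50)
    m <- molPercent(fp, ft)
    expect_equal(m$mol_phe + m$mol_tyr, rep(100, 50), tolerance = 1e-9)
  })
})

test_that("incorporation test equals the Welch formula oracle", {
  # identical arms: p = 1
  expect_equal(incorporationTest(c(25, 25, 25), c(25, 25, 25)), 1)
  # clearly separated arms with tiny jitter are significant
  withr::with_seed(81, {
    x <- 25 + rnorm(3, 0, 0.01); y <- 4.2 + rnorm(3, 0, 0.01)
    expect_lt(incorporationTest(x, y), 0.05)
    expect_equal(incorporationTest(x, y), welch_oracle(x, y),
                 tolerance = 1e-10)
    for (rep in 1:25) {
      a <- rnorm(sample(2:6, 1), mean = runif(1, 0, 10))
      b <- rnorm(sample(2:6, 1), mean = runif(1, 0, 10))
      expect_equal(incorporationTest(a, b), welch_oracle(a, b),
                   tolerance = 1e-10)
    }
  })
  # insufficient replicates are flagged, not guessed
  expect_true(is.na(incorporationTest(1, c(1, 2))))
})

test_that("quantifyEnrichment recovers planted fractions", {
  # zero observation noise: exact recovery
  sim0 <- simulateExperiment(mz_error_ppm = 0, rt_jitter_sd = 0,
                             rt_iso_sd = 0, intensity_cv = 0,
                             artifact_rate = 0, tissues = "leaf",
                             seed = 91)
  pp <- findPairs(sim0$table, "Phe", pairParams(test = FALSE))
  pt <- findPairs(sim0$table, "Tyr", pairParams(test = FALSE))
  lib <- buildLibrary(pp, pt)
  enr <- quantifyEnrichment(sim0$table, lib)
  tr <- sim0$truth
  m <- match(enr$anchor_id, tr$anchor_id)
  expect_true(all(!is.na(m)))
  expect_equal(enr$frac_phe, tr$true_frac_phe[m], tolerance = 1e-10)
  expect_equal(enr$frac_tyr, tr$true_frac_tyr[m], tolerance = 1e-10)
  def <- enr$defined
  expect_equal(enr$mol_phe[def], tr$true_mol_phe[m][def],
               tolerance = 1e-10)
  # default noise: mol% recovered within a few points (median)
  sim <- simulateExperiment(seed = 92)
  pp <- findPairs(sim$table, "Phe"); pt <- findPairs(sim$table, "Tyr")
  enr <- quantifyEnrichment(sim$table, buildLibrary(pp, pt))
  enr <- enr[enr$defined, ]
  m <- match(enr$anchor_id, sim$truth$anchor_id)
  err <- abs(enr$mol_phe - sim$truth$true_mol_phe[m])
  expect_lte(median(err, na.rm = TRUE), 5)
  # normalization invariant on the full result
  expect_equal(enr$mol_phe + enr$mol_tyr, rep(100, nrow(enr)),
               tolerance = 1e-9)
})
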