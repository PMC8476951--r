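mk_library <- function() {
  S4Vectors::DataFrame(
    anchor_id = c("M310T325", "M121T468"),
    anchor_mz = c(310.0935, 121.0298),
    anchor_rt = c(325, 468),
    origin = c("Tyr", "Tyr"),
    labeled_1 = c("M316T325", "M127T468"),
    labeled_2 = NA_character_, labeled_3 = NA_character_)
}

test_that("annotation matches within tolerance and rejects outside it", {
  lib <- mk_library()
  d <- data.frame(sample_id = c("a", "b"), tissue = "leaf",
                  genotype = c("WT", "mut"), replicate = 1L)
  cts <- matrix(1, 3, 2, dimnames = list(NULL, d$sample_id))
  tab <- FeatureTable(cts, mz = c(310.0940, 310.2, 121.0299),
                      rt = c(326, 325, 470), sampleData = d)
  ann <- annotateFeatures(tab, lib, tol_ppm = 15, tol_rt = 10)
  # (310.0940, 326) matches the dhurrin anchor; (310.2, 325) fails mass
  expect_identical(nrow(ann), 2L)
  expect_identical(ann$library_anchor[ann$feature_id == featureIds(tab)[1]],
                   "M310T325")
  expect_false(featureIds(tab)[2] %in% ann$feature_id)
  # a global RT offset rescues drifted runs
  drift <- FeatureTable(cts, mz = c(310.0940, 310.2, 121.0299),
                        rt = c(326, 325, 470) + 50, sampleData = d)
  expect_identical(nrow(annotateFeatures(drift, lib)), 0L)
  expect_identical(nrow(annotateFeatures(drift, lib, rt_offset = -50)), 2L)
})

test_that("annotation equals exhaustive nearest-neighbor search", {
  withr::with_seed(151, {
    for (rep in 1:5) {
      sim <- simulateExperiment(seed = 151 + rep, tissues = "leaf")
      pp <- findPairs(sim$table, "Phe"); pt <- findPairs(sim$table, "Tyr")
      lib <- buildLibrary(pp, pt)
      mut <- simulateMutantTable(sim$truth, seed = 250 + rep)
      ann <- annotateFeatures(mut$table, lib)
      # oracle: full scan per feature
      mz <- unname(featureMz(mut$table)); rt <- unname(featureRt(mut$table))
      ids <- featureIds(mut$table)
      for (i in seq_along(mz)) {
        dppm <- abs(mz[i] - lib$anchor_mz) / lib$anchor_mz * 1e6
        drt <- abs(rt[i] - lib$anchor_rt)
        ok <- which(dppm <= 15 & drt <= 10)
        row <- ann[ann$feature_id == ids[i], ]
        if (length(ok) == 0) expect_identical(nrow(row), 0L)
        else {
          best <- ok[which.min(dppm[ok] / 15 + drt[ok] / 10)]
          expect_identical(row$library_anchor, lib$anchor_id[best])
        }
      }
      # annotation is injective per table feature
      expect_false(anyDuplicated(ann$feature_id) > 0)
      # and stable under library row order
      perm <- sample(nrow(lib))
      ann2 <- annotateFeatures(mut$table, lib[perm, ])
      o1 <- ann[order(ann$feature_id), c("feature_id", "library_anchor")]
      o2 <- ann2[order(ann2$feature_id), c("feature_id", "library_anchor")]
      expect_identical(as.data.frame(o1), as.data.frame(o2))
    }
  })
})

test_that("differential test recovers planted fold changes", {
  withr::with_seed(161, {
    pm <- planted_mutant_table(n = 40, n_down = 8, n_up = 4, lfc = 2)
    lib <- S4Vectors::DataFrame(
      anchor_id = featureIds(pm$table), anchor_mz = featureMz(pm$table),
      anchor_rt = featureRt(pm$table), origin = "Phe+Tyr",
      labeled_1 = NA_character_, labeled_2 = NA_character_,
      labeled_3 = NA_character_)
    ann <- annotateFeatures(pm$table, lib)
    res <- differentialTest(pm$table, ann, wild_type = "WT")
    m <- match(featureIds(pm$table), res$feature_id)
    down <- pm$effect < 0
    # planted 4-fold decreases: direction down, log2_fc near -2
    expect_true(all(res$direction[m[down]] == "down"))
    expect_true(all(abs(res$log2_fc[m[down]] + 2) <= 0.3))
    expect_true(all(res$direction[m[pm$effect > 0]] == "up"))
    # unperturbed features are overwhelmingly unchanged
    expect_gte(mean(res$direction[m[pm$effect == 0]] == "unchanged"), 0.85)
  })
})

test_that("differential p-values equal the Welch oracle on log2 counts", {
  withr::with_seed(171, {
    pm <- planted_mutant_table(n = 10, n_down = 2, n_up = 1)
    lib <- S4Vectors::DataFrame(
      anchor_id = featureIds(pm$table), anchor_mz = featureMz(pm$table),
      anchor_rt = featureRt(pm$table), origin = "Phe",
      labeled_1 = NA_character_, labeled_2 = NA_character_,
      labeled_3 = NA_character_)
    ann <- annotateFeatures(pm$table, lib)
    res <- differentialTest(pm$table, ann, wild_type = "WT")
    cd <- as.data.frame(sampleData(pm$table))
    cts <- counts(pm$table)
    for (r in seq_len(nrow(res))) {
      a <- log2(cts[res$feature_id[r], cd$genotype == "mut"] + 1)
      b <- log2(cts[res$feature_id[r], cd$genotype == "WT"] + 1)
      expect_equal(res$p_value[r], welch_oracle(a, b), tolerance = 1e-10)
      expect_equal(res$log2_fc[r], mean(a) - mean(b), tolerance = 1e-12)
    }
  })
  # identical arms: unchanged with zero fold change
  d <- data.frame(sample_id = paste0("s", 1:4), tissue = "leaf",
                  genotype = rep(c("WT", "mut"), each = 2),
                  replicate = c(1, 2, 1, 2))
  cts <- matrix(c(10, 20, 10, 20), 1, 4,
                dimnames = list(NULL, d$sample_id))
  tab <- FeatureTable(cts, mz = 200.5, rt = 300, sampleData = d)
  lib1 <- S4Vectors::DataFrame(anchor_id = featureIds(tab),
                               anchor_mz = 200.5, anchor_rt = 300,
                               origin = "Phe", labeled_1 = NA_character_,
                               labeled_2 = NA_character_,
                               labeled_3 = NA_character_)
  res <- differentialTest(tab, annotateFeatures(tab, lib1),
                          wild_type = "WT")
  expect_identical(res$direction, "unchanged")
  expect_equal(res$log2_fc, 0, tolerance = 1e-12)
})

test_that("overlap partition is exhaustive and disjoint", {
  mk <- function(ids, dirs) data.frame(feature_id = ids, direction = dirs,
                                       stringsAsFactors = FALSE)
  # no significant features at all
  empty <- mk(character(), character())
  expect_true(all(partitionOverlap(empty, empty) == 0))
  # a feature down in both is counted once, in down_both only
  a <- mk(c("f1", "f2"), c("down", "unchanged"))
  b <- mk(c("f1", "f2"), c("down", "up"))
  po <- partitionOverlap(a, b)
  expect_identical(po[["down_both"]], 2L - 1L)
  expect_identical(po[["up_B_only"]], 1L)
  expect_identical(sum(po), 2L)
  # random results: counts equal brute-force set algebra
  withr::with_seed(181, {
    for (rep in 1:10) {
      ids <- paste0("f", 1:30)
      da <- sample(c("up", "down", "unchanged"), 30, replace = TRUE)
      db <- sample(c("up", "down", "unchanged"), 30, replace = TRUE)
      po <- partitionOverlap(mk(ids, da), mk(ids, db))
      expect_identical(po[["down_A_only"]],
                       sum(da == "down" & db == "unchanged"))
      expect_identical(po[["up_both"]], sum(da == "up" & db == "up"))
      expect_identical(po[["opposing"]],
                       sum(da != db & da != "unchanged" &
                             db != "unchanged"))
      expect_identical(sum(po), sum(da != "unchanged" | db != "unchanged"))
    }
  })
})
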