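#' Simulate a dual-precursor isotope-feeding experiment
#'
#' Generates an LC-MS feature table with planted ground truth emulating a
#' replicated feeding design: each tissue is fed, in separate arms,
#' unlabeled or ring-\eqn{{}^{13}C_6} Phe and Tyr. Every planted
#' metabolite feature carries 0-3 labelable phenyl rings and a true
#' labeled fraction for each precursor; the generator emits the unlabeled
#' (\eqn{{}^{12}C}) feature row plus, for ring-bearing features, one row
#' per attainable isotopologue (+6, +12, +18 times
#' \code{\link{C13C12_MASS_DIFF}}).
#'
#' Within a \eqn{{}^{13}C}-fed sample the pool of a feature is split
#' across isotopologues by an independent-ring binomial model: with
#' \code{r} rings and target labeled fraction \code{f}, each ring is
#' labeled with probability \eqn{q = 1-(1-f)^{1/r}}, so the share of
#' molecules with \eqn{k} labeled rings is \eqn{C(r,k)q^k(1-q)^{r-k}} and
#' the total labeled fraction of the pool is exactly \code{f}. Replicate
#' pool intensities are log-normal around the tissue base intensity, and
#' in \eqn{{}^{13}C}-fed samples each isotopologue peak is additionally
#' integrated with its own log-normal measurement error (same CV),
#' renormalized so the pool total is conserved exactly — this is what
#' makes per-replicate incorporation vary, as it does in real data;
#' observed m/z gets multiplicative ppm-scale Gaussian error; RT jitter is
#' shared by all isotopologues of a feature (they co-elute) plus small
#' per-row noise. Peak-filling artifacts optionally give labeled rows a
#' small spurious signal (a uniform 1-5\% of what the matching
#' \eqn{{}^{13}C}-fed signal would be) in \eqn{{}^{12}C}-fed samples.
#'
#' Feature archetypes: \code{exclusive_tyr} / \code{exclusive_phe}
#' (labeled by one precursor only, e.g. dhurrin-like Tyr-only features),
#' \code{phe_biased} / \code{tyr_biased} (60-80 mol\% toward one
#' precursor), \code{unbiased} (45-55 mol\%), and \code{decoy}
#' (non-aromatic, never labeled).
#'
#' @param n_per_archetype Named integer vector of planted feature counts
#'   per archetype. The default mirrors a leaf-like composition in which
#'   unbiased features are the majority and exclusive features are few.
#' @param tissues Character vector of tissues.
#' @param replicates Replicates per design cell (>= 2).
#' @param mz_error_ppm SD of multiplicative m/z error, ppm.
#' @param rt_jitter_sd SD of the shared per-feature RT jitter, seconds.
#' @param rt_iso_sd SD of the small per-row RT noise, seconds.
#' @param intensity_cv Coefficient of variation of replicate intensity
#'   noise (log-normal).
#' @param labeled_frac_range Range the dominant-precursor labeled
#'   fraction is drawn from; the default 0.04-0.40 spans the incorporation
#'   levels seen in 24 h feedings.
#' @param artifact_rate Fraction of ring-bearing features whose labeled
#'   rows receive spurious peak-fill signal in \eqn{{}^{12}C}-fed samples.
#' @param artifact_frac_range Artifact size as a fraction of the
#'   corresponding \eqn{{}^{13}C}-fed signal.
#' @param ring_weights Sampling weights for ring counts 1-3 of non-decoy
#'   features.
#' @param mz_range,rt_range Ranges base m/z (Th) and RT (s) are drawn
#'   from.
#' @param intensity_range Range of per-feature base intensities (ion
#'   counts, drawn log-uniformly).
#' @param tissue_effect Named multipliers on base intensity per tissue;
#'   unnamed tissues get 1.
#' @param precursor_effect_sd Optional sdlog of a per-feature,
#'   per-precursor log-normal multiplier emulating perturbation of
#'   endogenous pools by the fed amino acid (0 = off).
#' @param truth Optional pre-built ground-truth \code{DataFrame} (columns
#'   \code{archetype}, \code{ring_count}, \code{base_mz}, \code{rt},
#'   \code{true_frac_phe}, \code{true_frac_tyr}, \code{base_intensity});
#'   when supplied, the drawing step is skipped and only emission runs.
#' @param seed Integer seed; the single RNG all draws flow from.
#' @return A list with \code{table} (a \linkS4class{FeatureTable}) and
#'   \code{truth} (a \code{DataFrame} with the planted features, their
#'   true fractions and mol\%, and the emitted anchor / labeled feature
#'   ids).
#' @examples
#' sim <- simulateExperiment(
#'   n_per_archetype = c(unbiased = 4, decoy = 4),
#'   tissues = "leaf", seed = 1)
#' sim$table
#' @export
simulateExperiment <- function(
    n_per_archetype = c(exclusive_tyr = 5, exclusive_phe = 5,
                        phe_biased = 14, tyr_biased = 6,
                        unbiased = 44, decoy = 50),
    tissues = c("leaf", "base", "root"),
    replicates = 3L,
    mz_error_ppm = 5,
    rt_jitter_sd = 1,
    rt_iso_sd = 0.3,
    intensity_cv = 0.2,
    labeled_frac_range = c(0.04, 0.40),
    artifact_rate = 0.1,
    artifact_frac_range = c(0.01, 0.05),
    ring_weights = c(0.8, 0.15, 0.05),
    mz_range = c(150, 900),
    rt_range = c(120, 1080),
    intensity_range = c(1e4, 1e6),
    tissue_effect = c(root = 0.5),
    precursor_effect_sd = 0,
    truth = NULL,
    seed = 1L) {
  stopifnot(replicates >= 2,
            artifact_rate >= 0, artifact_rate <= 1,
            all(labeled_frac_range >= 0), all(labeled_frac_range <= 1),
            mz_error_ppm >= 0, intensity_cv >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))

  if (is.null(truth))
    truth <- .drawGroundTruth(n_per_archetype, labeled_frac_range,
                              ring_weights, mz_range, rt_range,
                              intensity_range)
  truth <- DataFrame(truth)
  ntruth <- nrow(truth)

  design <- expand.grid(replicate = seq_len(replicates),
                        isotope = c("12C", "13C"),
                        precursor = c("Phe", "Tyr"),
                        tissue = tissues,
                        stringsAsFactors = FALSE)
  design$sample_id <- with(design, paste(tissue, precursor, isotope,
                                         replicate, sep = "_"))
  nsamp <- nrow(design)

  if (ntruth == 0) {
    tab <- FeatureTable(matrix(0, 0, nsamp,
                               dimnames = list(NULL, design$sample_id)),
                        mz = numeric(), rt = numeric(),
                        sampleData = design, feature_id = character())
    return(list(table = tab, truth = truth))
  }

  tmult <- stats::setNames(rep(1, length(tissues)), tissues)
  tmult[names(tissue_effect)] <- tissue_effect
  sdlog <- sqrt(log(1 + intensity_cv^2))

  # per-feature x precursor pool perturbation (12C feeding effect)
  pert <- matrix(1, ntruth, 2, dimnames = list(NULL, c("Phe", "Tyr")))
  if (precursor_effect_sd > 0)
    pert[] <- stats::rlnorm(2 * ntruth, -precursor_effect_sd^2 / 2,
                            precursor_effect_sd)

  has_artifact <- stats::runif(ntruth) < artifact_rate

  rows_mz <- rows_rt <- numeric(0)
  rows_truth <- rows_k <- integer(0)
  for (i in seq_len(ntruth)) {
    r <- truth$ring_count[i]
    ks <- 0:r
    th_mz <- truth$base_mz[i] + ks * 6 * C13C12_MASS_DIFF
    jit <- stats::rnorm(1, 0, rt_jitter_sd)
    obs_mz <- th_mz * (1 + stats::rnorm(length(ks), 0, mz_error_ppm * 1e-6))
    obs_rt <- truth$rt[i] + jit + stats::rnorm(length(ks), 0, rt_iso_sd)
    rows_mz <- c(rows_mz, obs_mz)
    rows_rt <- c(rows_rt, pmax(obs_rt, 0))
    rows_truth <- c(rows_truth, rep(i, length(ks)))
    rows_k <- c(rows_k, ks)
  }
  nrows <- length(rows_mz)

  cts <- matrix(0, nrows, nsamp)
  for (s in seq_len(nsamp)) {
    iso <- design$isotope[s]
    pre <- design$precursor[s]
    base <- truth$base_intensity * tmult[[design$tissue[s]]] *
      pert[, pre]
    pool <- if (intensity_cv > 0)
      base * stats::rlnorm(ntruth, -sdlog^2 / 2, sdlog) else base
    f <- if (pre == "Phe") truth$true_frac_phe else truth$true_frac_tyr
    r <- truth$ring_count
    share0 <- rep(1, ntruth)
    shares <- matrix(0, ntruth, 3)
    lab <- which(r > 0 & f > 0)
    if (length(lab)) {
      q <- 1 - (1 - f[lab])^(1 / r[lab])
      for (j in seq_along(lab)) {
        ii <- lab[j]
        pk <- stats::dbinom(0:r[ii], r[ii], q[j])
        share0[ii] <- pk[1]
        shares[ii, seq_len(r[ii])] <- pk[-1]
      }
    }
    if (iso == "13C") {
      # noisy partition of the pool across isotopologues: each peak is
      # integrated with its own multiplicative error, renormalized so the
      # pool total is conserved exactly
      cts[rows_k == 0, s] <- pool[rows_truth[rows_k == 0]] *
        share0[rows_truth[rows_k == 0]]
      at <- which(rows_k > 0)
      cts[at, s] <- pool[rows_truth[at]] *
        shares[cbind(rows_truth[at], rows_k[at])]
      if (intensity_cv > 0 && length(lab)) {
        for (ii in lab) {
          rws <- which(rows_truth == ii)
          e <- stats::rlnorm(length(rws), -sdlog^2 / 2, sdlog)
          w <- cts[rws, s] * e
          cts[rws, s] <- pool[ii] * w / sum(w)
        }
      }
    } else {
      cts[rows_k == 0, s] <- pool[rows_truth[rows_k == 0]]
      at <- which(rows_k > 0 & has_artifact[rows_truth])
      if (length(at)) {
        u <- stats::runif(length(at), artifact_frac_range[1],
                          artifact_frac_range[2])
        cts[at, s] <- u * pool[rows_truth[at]] *
          shares[cbind(rows_truth[at], rows_k[at])]
      }
    }
  }

  ids <- makeFeatureId(rows_mz, rows_rt)
  tab <- FeatureTable(cts, mz = rows_mz, rt = rows_rt,
                      sampleData = design, feature_id = ids,
                      provenance = "synthetic dual-precursor feeding")

  truth$anchor_id <- ids[rows_k == 0]
  for (k in 1:3) {
    lid <- rep(NA_character_, ntruth)
    at <- which(rows_k == k)
    lid[rows_truth[at]] <- ids[at]
    truth[[paste0("labeled_", k)]] <- lid
  }
  tot <- truth$true_frac_phe + truth$true_frac_tyr
  truth$true_mol_phe <- ifelse(tot > 0, 100 * truth$true_frac_phe / tot, NA)
  list(table = tab, truth = truth)
}

# draw the planted ground-truth features
.drawGroundTruth <- function(n_per_archetype, labeled_frac_range,
                             ring_weights, mz_range, rt_range,
                             intensity_range) {
  arche <- rep(names(n_per_archetype), n_per_archetype)
  n <- length(arche)
  if (n == 0)
    return(DataFrame(archetype = character(), ring_count = integer(),
                     base_mz = numeric(), rt = numeric(),
                     true_frac_phe = numeric(), true_frac_tyr = numeric(),
                     base_intensity = numeric()))
  ring <- integer(n)
  ring[arche != "decoy"] <- sample.int(3, sum(arche != "decoy"),
                                       replace = TRUE,
                                       prob = ring_weights)
  mol <- rep(NA_real_, n)
  mol[arche == "unbiased"] <- stats::runif(sum(arche == "unbiased"), 45, 55)
  mol[arche == "phe_biased"] <- stats::runif(sum(arche == "phe_biased"), 60, 80)
  mol[arche == "tyr_biased"] <- stats::runif(sum(arche == "tyr_biased"), 20, 40)
  mol[arche == "exclusive_phe"] <- 100
  mol[arche == "exclusive_tyr"] <- 0
  f <- stats::runif(n, labeled_frac_range[1], labeled_frac_range[2])
  frac_phe <- frac_tyr <- numeric(n)
  lab <- arche != "decoy"
  dom_phe <- lab & mol >= 50
  frac_phe[dom_phe] <- f[dom_phe]
  frac_tyr[dom_phe] <- f[dom_phe] * (100 - mol[dom_phe]) / mol[dom_phe]
  dom_tyr <- lab & mol < 50
  frac_tyr[dom_tyr] <- f[dom_tyr]
  frac_phe[dom_tyr] <- f[dom_tyr] * mol[dom_tyr] / (100 - mol[dom_tyr])
  DataFrame(
    archetype = arche,
    ring_count = ring,
    base_mz = stats::runif(n, mz_range[1], mz_range[2]),
    rt = stats::runif(n, rt_range[1], rt_range[2]),
    true_frac_phe = frac_phe,
    true_frac_tyr = frac_tyr,
    base_intensity = exp(stats::runif(n, log(intensity_range[1]),
                                      log(intensity_range[2])))
  )
}

#' Write / read planted ground truth
#'
#' CSV round-trip for the ground-truth table produced by
#' \code{\link{simulateExperiment}} (one row per planted feature with its
#' archetype, ring count, true fractions and true mol\%).
#'
#' @param truth Ground-truth \code{DataFrame}.
#' @param path CSV path.
#' @return \code{writeGroundTruth} invisibly returns \code{path};
#'   \code{readGroundTruth} returns the \code{DataFrame}.
#' @export
writeGroundTruth <- function(truth, path) {
  utils::write.csv(as.data.frame(truth), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  DataFrame(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Simulate unlabeled genotype feature tables
#'
#' Emits an unlabeled (no isotope feeding) feature table for a wild type
#' and one or more mutant genotypes over the anchor features of a planted
#' ground truth, with per-feature multiplicative abundance effects in the
#' mutants. This supplies the retrospective-annotation stage
#' (\code{\link{annotateFeatures}}, \code{\link{differentialTest}}) with a
#' testable input whose differential features are known.
#'
#' @param truth Ground-truth \code{DataFrame} from
#'   \code{\link{simulateExperiment}}.
#' @param genotypes Character vector of mutant genotype names.
#' @param wild_type Wild-type genotype name.
#' @param replicates Replicates per genotype.
#' @param tissue Tissue label for all samples.
#' @param affected_rate Probability a non-decoy feature is perturbed in a
#'   given mutant.
#' @param lfc_range Magnitude range of planted |log2 fold changes|;
#'   direction is down with probability \code{down_prob}.
#' @param down_prob Probability a planted effect is a decrease.
#' @param intensity_cv Replicate noise CV (log-normal).
#' @param mz_error_ppm,rt_jitter_sd Observation noise on feature
#'   coordinates (a fresh chromatographic run).
#' @param seed Integer seed.
#' @return List with \code{table} (a \linkS4class{FeatureTable} whose
#'   \code{colData} has a \code{genotype} column) and \code{effects}
#'   (\code{DataFrame}: \code{truth_row}, \code{genotype},
#'   \code{log2_fc} for every planted perturbation).
#' @export
simulateMutantTable <- function(truth,
                                genotypes = c("mutA", "mutB"),
                                wild_type = "WT",
                                replicates = 3L,
                                tissue = "leaf",
                                affected_rate = 0.25,
                                lfc_range = c(1, 3),
                                down_prob = 0.7,
                                intensity_cv = 0.1,
                                mz_error_ppm = 5,
                                rt_jitter_sd = 2,
                                seed = 1L) {
  stopifnot(nrow(truth) > 0, replicates >= 2)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(truth)
  geno_all <- c(wild_type, genotypes)
  design <- expand.grid(replicate = seq_len(replicates),
                        genotype = geno_all, stringsAsFactors = FALSE)
  design$sample_id <- with(design, paste(genotype, replicate, sep = "_"))
  design$tissue <- tissue

  eff <- matrix(0, n, length(genotypes),
                dimnames = list(NULL, genotypes))
  targetable <- which(truth$archetype != "decoy")
  for (g in genotypes) {
    hit <- targetable[stats::runif(length(targetable)) < affected_rate]
    mag <- stats::runif(length(hit), lfc_range[1], lfc_range[2])
    sgn <- ifelse(stats::runif(length(hit)) < down_prob, -1, 1)
    eff[hit, g] <- sgn * mag
  }

  sdlog <- sqrt(log(1 + intensity_cv^2))
  obs_mz <- truth$base_mz * (1 + stats::rnorm(n, 0, mz_error_ppm * 1e-6))
  obs_rt <- pmax(truth$rt + stats::rnorm(n, 0, rt_jitter_sd), 0)
  cts <- matrix(0, n, nrow(design))
  for (s in seq_len(nrow(design))) {
    g <- design$genotype[s]
    mult <- if (g == wild_type) rep(1, n) else 2^eff[, g]
    base <- truth$base_intensity * mult
    cts[, s] <- if (intensity_cv > 0)
      base * stats::rlnorm(n, -sdlog^2 / 2, sdlog) else base
  }
  ids <- makeFeatureId(obs_mz, obs_rt)
  tab <- FeatureTable(cts, mz = obs_mz, rt = obs_rt,
                      sampleData = design, feature_id = ids,
                      provenance = "synthetic unlabeled genotype panel")
  planted <- which(eff != 0, arr.ind = TRUE)
  effects <- DataFrame(
    truth_row = as.integer(planted[, 1]),
    feature_id = ids[planted[, 1]],
    genotype = genotypes[planted[, 2]],
    log2_fc = eff[planted]
  )
  list(table = tab, effects = effects)
}
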