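# Small in-code fixtures shared across test files.

# a 2-feature x 4-sample hand-written table: dhurrin anchor + its +6 row
# in one precursor design with 2 replicates per isotope arm
toy_design <- function(replicates = 2) {
  expand.grid(replicate = seq_len(replicates),
              isotope = c("12C", "13C"),
              precursor = "Phe", tissue = "leaf",
              stringsAsFactors = FALSE) |>
    (\(d) { d$sample_id <- paste0("s", seq_len(nrow(d))); d })()
}

toy_table <- function() {
  d <- toy_design()
  cts <- rbind(c(1000, 990, 760, 740),   # anchor, drops under labeling
               c(0, 0, 250, 260))        # +6 row, present only in 13C
  colnames(cts) <- d$sample_id
  FeatureTable(cts, mz = c(310.0935, 316.1138), rt = c(325, 325),
               sampleData = d)
}

# random feature table with planted pairs near the tolerance boundaries,
# for oracle-equivalence stress tests; assumes a live RNG (seed set by
# the caller)
random_pair_table <- function(n_base = 25, n_decoy = 30,
                              replicates = 3, tol_ppm = 15, tol_rt = 5) {
  delta <- 6 * 1.0033548
  d <- expand.grid(replicate = seq_len(replicates),
                   isotope = c("12C", "13C"),
                   precursor = "Phe", tissue = "leaf",
                   stringsAsFactors = FALSE)
  d$sample_id <- paste0("s", seq_len(nrow(d)))
  s12 <- which(d$isotope == "12C"); s13 <- which(d$isotope == "13C")
  mz <- rt <- numeric(0); cts <- NULL
  add_row <- function(m, r, i12, i13) {
    mz <<- c(mz, m); rt <<- c(rt, r)
    row <- numeric(nrow(d))
    row[s12] <- i12 * runif(length(s12), 0.7, 1.3)
    row[s13] <- i13 * runif(length(s13), 0.7, 1.3)
    cts <<- rbind(cts, row)
  }
  for (i in seq_len(n_base)) {
    m0 <- runif(1, 150, 800); r0 <- runif(1, 100, 1100)
    base_int <- 10^runif(1, 3, 5)
    add_row(m0, r0, base_int, base_int * runif(1, 0.6, 1))
    nrings <- sample(0:2, 1, prob = c(0.3, 0.5, 0.2))
    for (k in seq_len(nrings)) {
      tol <- max(tol_ppm * 1e-6 * (m0 + k * delta), 0.005)
      # offsets straddle the mass and RT gates to stress boundaries
      mk <- m0 + k * delta + runif(1, -1.5, 1.5) * tol
      rk <- r0 + runif(1, -1.6, 1.6) * tol_rt
      lab_int <- base_int * runif(1, 0.05, 0.4)
      enriched <- runif(1) < 0.8
      add_row(mk, max(rk, 0),
              if (enriched) lab_int * 0.02 else lab_int,
              lab_int)
    }
  }
  for (i in seq_len(n_decoy))
    add_row(runif(1, 150, 810), runif(1, 100, 1100),
            10^runif(1, 3, 5), 10^runif(1, 3, 5))
  keep <- !duplicated(paste(mz, rt))
  FeatureTable(cts[keep, , drop = FALSE], mz = mz[keep], rt = rt[keep],
               sampleData = d)
}

# unlabeled two-genotype table with planted log2 fold changes
planted_mutant_table <- function(n = 30, n_down = 6, n_up = 3,
                                 lfc = 2, replicates = 3, cv = 0.1) {
  d <- expand.grid(replicate = seq_len(replicates),
                   genotype = c("WT", "mut"), stringsAsFactors = FALSE)
  d$sample_id <- paste(d$genotype, d$replicate, sep = "_")
  d$tissue <- "leaf"
  mz <- runif(n, 150, 900); rt <- runif(n, 100, 1100)
  base <- 10^runif(n, 4, 6)
  eff <- rep(0, n)
  eff[seq_len(n_down)] <- -lfc
  eff[n_down + seq_len(n_up)] <- lfc
  sdlog <- sqrt(log(1 + cv^2))
  cts <- sapply(seq_len(nrow(d)), function(s) {
    mult <- if (d$genotype[s] == "mut") 2^eff else rep(1, n)
    base * mult * rlnorm(n, -sdlog^2 / 2, sdlog)
  })
  colnames(cts) <- d$sample_id
  list(table = FeatureTable(cts, mz = mz, rt = rt, sampleData = d),
       effect = eff)
}
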