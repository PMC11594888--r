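small_cfg <- function(...) {
  args <- list(n_tall = 5, n_short = 5,
               chrom_lengths = c(chr1 = 1e6), n_variants = 300,
               sweep_regions = NULL,
               causal_snp = list(chrom = "chr1", pos = 5e5, effect = 2),
               missing_rate = 0.05, seed = 11)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

test_that("config validation rejects degenerate inputs", {
  expect_error(small_cfg(n_variants = 0), "n_variants")
  expect_error(small_cfg(background_fst = 0), "background_fst")
  expect_error(small_cfg(missing_rate = 0.6), "missing_rate")
  expect_error(small_cfg(sweep_regions = data.frame(
    chrom = "chr1", start = 9e5, end = 2e6, focal = "SL", boost = 0.5)),
    "within chrom_lengths")
  expect_error(small_cfg(causal_snp = list(chrom = "chrX", pos = 1,
                                           effect = 1)), "unknown chromosome")
})

test_that("population frequencies follow the Balding-Nichols layers", {
  # no-drift limit: tiny F keeps population frequencies at the ancestral
  f0 <- simulate_population_frequencies(small_cfg(background_fst = 1e-4,
                                                  n_variants = 2000))
  expect_lt(max(abs(f0$p_TL - f0$p_anc)), 0.08)
  expect_lt(mean(abs(f0$p_TL - f0$p_anc)), 0.01)

  # forced fixation at boost 1 inside the sweep, focal population only
  sw <- data.frame(chrom = "chr1", start = 1, end = 5e5, focal = "SL",
                   boost = 1.0)
  f1 <- simulate_population_frequencies(small_cfg(sweep_regions = sw,
                                                  n_variants = 2000))
  inside <- !is.na(f1$in_sweep)
  expect_true(any(inside))
  expect_true(all(f1$p_SL[inside] %in% c(0, 1)))
  expect_false(all(f1$p_TL[inside] %in% c(0, 1)))

  # ancestral prior bounds and causal anchoring
  expect_true(all(f1$p_anc >= 0.05 & f1$p_anc <= 0.95))
  expect_equal(f1$p_anc[f1$is_causal], 0.5)
})

test_that("realized genome-wide Fst matches the drift parameter", {
  cfg <- sim_config(background_fst = 0.03, n_variants = 50000,
                    sweep_regions = NULL, causal_snp = NULL, seed = 5,
                    missing_rate = 0)
  sim <- simulate_genotypes_and_phenotypes(cfg, reference = FALSE)
  tl <- grep("^TL", sim$genotypes$samples)
  sl <- grep("^SL", sim$genotypes$samples)
  win <- make_windows(cfg$chrom_lengths, size = 5e6, step = 5e6)
  wf <- window_fst(sim$genotypes, list(sim$genotypes$samples[tl],
                                       sim$genotypes$samples[sl]), win)
  genome_fst <- weighted.mean(wf$fst, wf$n_snps)
  expect_lt(abs(genome_fst - 0.03), 0.01)
})

test_that("genotypes and phenotypes respect the stated generative model", {
  cfg <- small_cfg()
  sim <- simulate_genotypes_and_phenotypes(cfg)
  g <- sim$genotypes
  ph <- sim$phenotypes

  # one phenotype record per sample, derived trait identity exact
  expect_identical(ph$sample, g$samples)
  expect_equal(ph$height_cm - ph$chest_depth_cm, ph$leg_length_cm)

  # causal position is among simulated variants
  expect_true(any(g$variants$chrom == cfg$causal_snp$chrom &
                    g$variants$pos == cfg$causal_snp$pos))

  # missingness close to configured rate
  expect_lt(abs(mean(is.na(g$calls)) - cfg$missing_rate), 0.02)

  # determinism: same config, byte-identical VCF
  d1 <- tempfile(); d2 <- tempfile()
  write_outputs(sim, d1)
  write_outputs(simulate_genotypes_and_phenotypes(small_cfg()), d2)
  expect_identical(readLines(file.path(d1, "genotypes.vcf")),
                   readLines(file.path(d2, "genotypes.vcf")))

  # truth file: one row per sweep region + 1 causal row
  sw <- data.frame(chrom = "chr1", start = c(1, 200001), end = c(1e5, 3e5),
                   focal = "SL", boost = 0.8)
  sim2 <- simulate_genotypes_and_phenotypes(small_cfg(sweep_regions = sw))
  d3 <- tempfile()
  write_outputs(sim2, d3)
  truth <- read.delim(file.path(d3, "truth.tsv"))
  expect_equal(nrow(truth), nrow(sw) + 1)

  # missing calls are ./. in the VCF
  vcf <- readLines(file.path(d1, "genotypes.vcf"))
  body <- vcf[!startsWith(vcf, "#")]
  miss_idx <- which(is.na(g$calls[, 1]))
  if (length(miss_idx)) {
    fields <- strsplit(body[1], "\t")[[1]]
    expect_true(all(grepl("^\\./\\.", fields[9 + miss_idx])))
  }
})

test_that("null effect gives uniform group-difference p-values", {
  pv <- vapply(1:20, function(s) {
    cfg <- small_cfg(causal_snp = NULL, n_variants = 30, seed = s,
                     n_tall = 10, n_short = 10)
    sim <- simulate_genotypes_and_phenotypes(cfg, reference = FALSE)
    t.test(leg_length_cm ~ group, data = sim$phenotypes)$p.value
  }, numeric(1))
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("additive effect is recovered by the marker association", {
  est <- vapply(1:20, function(s) {
    cfg <- sim_config(n_tall = 125, n_short = 125,
                      chrom_lengths = c(chr1 = 1e6), n_variants = 40,
                      sweep_regions = NULL,
                      causal_snp = list(chrom = "chr1", pos = 5e5,
                                        effect = 3.0),
                      pheno_sd = 1.0, missing_rate = 0, seed = s)
    sim <- simulate_genotypes_and_phenotypes(cfg, reference = FALSE)
    i <- which(sim$frequencies$is_causal)
    calls <- sim$genotypes$calls[, i]
    at <- glm_association(sim$phenotypes$leg_length_cm,
                          c("AA", "AB", "BB")[calls + 1])
    gr <- at$groups
    (gr$mean[gr$genotype == "BB"] - gr$mean[gr$genotype == "AA"]) / 2
  }, numeric(1))
  expect_lt(abs(mean(est) - 3.0), 0.5)
  expect_true(all(abs(est - 3.0) < 0.5))
})

test_that("per-population heterozygosity matches the analytic expectation", {
  cfg <- small_cfg(n_variants = 20000, missing_rate = 0, causal_snp = NULL,
                   n_tall = 15, n_short = 15, background_fst = 0.05)
  sim <- simulate_genotypes_and_phenotypes(cfg, reference = FALSE)
  tl <- grep("^TL", sim$genotypes$samples)
  obs_het <- mean(sim$genotypes$calls[tl, ] == 1)
  expected <- mean(2 * sim$frequencies$p_anc * (1 - sim$frequencies$p_anc) *
                     (1 - cfg$background_fst))
  expect_lt(abs(obs_het - expected), 0.01)
})

test_that("realized allele counts are binomial around population frequencies", {
  cfg <- small_cfg(n_variants = 1000, missing_rate = 0, causal_snp = NULL,
                   n_tall = 15, n_short = 15, seed = 3)
  sim <- simulate_genotypes_and_phenotypes(cfg, reference = FALSE)
  tl <- grep("^TL", sim$genotypes$samples)
  f <- sim$frequencies$p_TL
  keep <- f > 0.01 & f < 0.99
  nchr <- 2 * length(tl)
  obs <- colSums(sim$genotypes$calls[tl, keep])
  z2 <- (obs - nchr * f[keep])^2 / (nchr * f[keep] * (1 - f[keep]))
  p <- pchisq(sum(z2), df = sum(keep), lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("sweep regions deplete focal-population diversity", {
  deficit <- vapply(1:10, function(s) {
    sw <- data.frame(chrom = "chr1", start = 4e5, end = 6e5, focal = "SL",
                     boost = 0.9)
    cfg <- small_cfg(sweep_regions = sw, n_variants = 3000, seed = s,
                     causal_snp = NULL, n_tall = 10, n_short = 10)
    sim <- simulate_genotypes_and_phenotypes(cfg, reference = FALSE)
    sl <- sim$genotypes$samples[grep("^SL", sim$genotypes$samples)]
    win <- make_windows(cfg$chrom_lengths, size = 1e5, step = 1e5)
    wp <- window_pi(sim$genotypes, sl, win, col = "pi_SL")
    sweep_pi <- mean(wp$pi_SL[wp$start >= 4e5 & wp$end <= 6e5])
    median(wp$pi_SL) - sweep_pi
  }, numeric(1))
  expect_gt(mean(deficit), 0)
  expect_gt(mean(deficit > 0), 0.8)
})
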