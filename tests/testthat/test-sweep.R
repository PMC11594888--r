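test_that("window tiling follows the enumeration rules", {
  w <- make_windows(c(c1 = 250000))
  expect_equal(w$start, c(1, 50001, 100001, 150001, 200001))
  expect_equal(w$end, c(100000, 150000, 200000, 250000, 250000))
  expect_equal(nrow(w), floor((250000 - 1) / 50000) + 1)

  # step = size gives a non-overlapping tiling
  w2 <- make_windows(c(c1 = 300000), size = 1e5, step = 1e5)
  expect_equal(w2$start, c(1, 100001, 200001))
  expect_equal(w2$end, w2$start + 1e5 - 1)

  # closed-form count on random lengths
  for (L in c(123456, 1e6, 777777)) {
    expect_equal(nrow(make_windows(c(x = L))), floor((L - 1) / 50000) + 1)
  }
  expect_error(make_windows(c(x = 1e5), step = 0), "positive")
  expect_error(make_windows(c(x = 1e5), size = 1e4, step = 2e4), "exceed")
})

test_that("windowed Fst matches the per-site variance-component oracle", {
  set.seed(6)
  calls <- matrix(sample(c(0:2, NA), 6 * 5, replace = TRUE,
                         prob = c(.3, .3, .3, .1)), 6, 5)
  calls[1, 1] <- 0L; calls[4, 1] <- 2L   # ensure both pops called at site 1
  g <- toy_geno(calls, pos = c(10, 20, 30, 40, 50))
  pops <- list(A = g$samples[1:3], B = g$samples[4:6])
  win <- data.frame(chrom = "chr1", start = 1, end = 100)
  wf <- window_fst(g, pops, win)
  oracle <- wc_fst_oracle(calls[1:3, , drop = FALSE],
                          calls[4:6, , drop = FALSE])
  expect_equal(wf$fst, oracle, tolerance = 1e-10)

  # fixed opposite alleles give Fst = 1
  gfix <- toy_geno(rbind(matrix(0L, 3, 4), matrix(2L, 3, 4)),
                   pos = c(10, 20, 30, 40))
  wfix <- window_fst(gfix, list(gfix$samples[1:3], gfix$samples[4:6]),
                     data.frame(chrom = "chr1", start = 1, end = 100))
  expect_equal(wfix$fst, 1)

  # identical composition in both populations: estimator at or below 0
  gid <- toy_geno(rbind(c(0L, 1L, 2L), c(1L, 2L, 0L),
                        c(0L, 1L, 2L), c(1L, 2L, 0L)),
                  pos = c(10, 20, 30))
  wid <- window_fst(gid, list(gid$samples[1:2], gid$samples[3:4]),
                    data.frame(chrom = "chr1", start = 1, end = 100))
  expect_lte(wid$fst, 0)

  # symmetry in population labels; empty window is NA
  wf2 <- window_fst(g, rev(pops), win)
  expect_equal(wf2$fst, wf$fst)
  wempty <- window_fst(g, pops, data.frame(chrom = "chr1", start = 1000,
                                           end = 2000))
  expect_true(is.na(wempty$fst))
  expect_equal(wempty$n_snps, 0L)
})

test_that("windowed diversity matches the pairwise-enumeration oracle", {
  # single site, hom-ref + hom-alt diploids: site pi = 2*2 / C(4,2) = 2/3
  g <- toy_geno(matrix(c(0L, 2L), 2, 1), pos = 5)
  w <- window_pi(g, g$samples, data.frame(chrom = "chr1", start = 1,
                                          end = 10))
  expect_equal(w$pi, (2 / 3) / 10)
  expect_equal(pi_oracle_site(c(0L, 2L)), 2 / 3)

  set.seed(7)
  calls <- matrix(sample(c(0:2, NA), 5 * 8, replace = TRUE,
                         prob = c(.3, .3, .3, .1)), 5, 8)
  g2 <- toy_geno(calls, pos = seq_len(8) * 10)
  w2 <- window_pi(g2, g2$samples, data.frame(chrom = "chr1", start = 1,
                                             end = 100))
  oracle <- sum(vapply(seq_len(8), function(j) pi_oracle_site(calls[, j]),
                       numeric(1))) / 100
  expect_equal(w2$pi, oracle, tolerance = 1e-10)

  # fixed population has zero diversity; doubling window length halves pi
  gfix <- toy_geno(matrix(2L, 4, 3), pos = c(10, 20, 30))
  expect_equal(window_pi(gfix, gfix$samples,
                         data.frame(chrom = "chr1", start = 1,
                                    end = 100))$pi, 0)
  w_short <- window_pi(g2, g2$samples,
                       data.frame(chrom = "chr1", start = 1, end = 100))
  w_long <- window_pi(g2, g2$samples,
                      data.frame(chrom = "chr1", start = 1, end = 200))
  expect_equal(w_long$pi, w_short$pi / 2)

  # sample-order invariance
  w3 <- window_pi(g2, rev(g2$samples),
                  data.frame(chrom = "chr1", start = 1, end = 100))
  expect_equal(w3$pi, w2$pi)
})

test_that("Fst binning fractions count the three ranges", {
  expect_equal(unname(fst_bins(rep(0, 10))), c(1, 0, 0))
  expect_equal(unname(fst_bins(c(rep(0.01, 19), 0.1))), c(0.95, 0.05, 0))
  expect_equal(sum(fst_bins(runif(100))), 1)
  expect_error(fst_bins(NA_real_), "no defined")
})

test_that("joint selection intersects the two top tails", {
  set.seed(8)
  n <- 100
  w <- data.frame(chrom = "c", start = seq_len(n), end = seq_len(n),
                  n_snps = 10L, fst = runif(n, 0, 0.1),
                  pi_TL = runif(n, 1e-4, 1e-3),
                  pi_SL = runif(n, 1e-4, 1e-3))
  w$fst[42] <- 0.5
  w$pi_SL[42] <- 1e-6    # depleted focal diversity
  js <- joint_select(w, "SL")
  expect_true(js$windows$selected[42])
  expect_equal(which(js$windows$selected), 42)

  # quantile extremes
  expect_equal(sum(joint_select(w, "SL", quantile = 1.0)$windows$selected), 1)
  js0 <- joint_select(w, "SL", quantile = 0.0)
  expect_true(all(js0$windows$selected[js0$windows$ranked]))

  # min_snps exclusion and zero-pi pseudocount
  w$n_snps[42] <- 2L
  js2 <- joint_select(w, "SL")
  expect_false(js2$windows$selected[42])
  w$pi_SL[7] <- 0
  expect_message(joint_select(w, "SL", min_snps = 1), "pseudocount")
})

test_that("independent statistics select about quantile^2 of windows", {
  set.seed(9)
  total <- 0
  for (s in 1:50) {
    n <- 400
    w <- data.frame(chrom = "c", start = 1, end = 2, n_snps = 10L,
                    fst = runif(n), pi_TL = runif(n), pi_SL = runif(n))
    total <- total + sum(joint_select(w, "SL")$windows$selected)
  }
  # Binomial(50 * 400, 0.0025): mean 50, sd ~ 7
  expect_gt(total, 25)
  expect_lt(total, 75)
})

test_that("selected windows map to overlapping genes with deduplication", {
  models <- list(
    gene_model("g1", "c1", "+", exons = data.frame(start = 150, end = 450)),
    gene_model("g2", "c1", "+", exons = data.frame(start = 900, end = 1200)),
    gene_model("g3", "c1", "-", exons = data.frame(start = 1150, end = 1350)),
    gene_model("g4", "c2", "+", exons = data.frame(start = 10, end = 90)))
  win <- data.frame(chrom = c("c1", "c1", "c2"),
                    start = c(100, 1000, 1000), end = c(1000, 1300, 2000))
  res <- windows_to_genes(win, models)
  expect_equal(res$per_window[[1]], c("g1", "g2"))
  expect_equal(res$per_window[[2]], c("g2", "g3"))
  expect_equal(res$per_window[[3]], character(0))
  expect_equal(res$union, c("g1", "g2", "g3"))   # g2 counted once
  expect_equal(windows_to_genes(win[0, ], models)$union, character(0))
})

test_that("planted sweeps are recovered by the joint screen", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = s)
    sim <- simulate_genotypes_and_phenotypes(cfg, reference = FALSE)
    pops <- split(sim$phenotypes$sample, sim$phenotypes$group)
    win <- make_windows(cfg$chrom_lengths)
    win <- window_fst(sim$genotypes, pops[c("TL", "SL")], win)
    win <- window_pi(sim$genotypes, pops$TL, win, "pi_TL")
    win <- window_pi(sim$genotypes, pops$SL, win, "pi_SL")
    js <- joint_select(win, "SL")
    sel <- js$windows[js$windows$selected, ]
    sw <- sim$truth$sweeps
    sum(vapply(seq_len(nrow(sw)), function(k)
      any(sel$chrom == sw$chrom[k] & sel$start <= sw$end[k] &
            sel$end >= sw$start[k]), logical(1)))
  }, numeric(1))
  expect_true(all(hits >= 2))
  # and the background Fst distribution is dominated by the first bin
  cfg <- sim_config(seed = 1)
  sim <- simulate_genotypes_and_phenotypes(cfg, reference = FALSE)
  pops <- split(sim$phenotypes$sample, sim$phenotypes$group)
  win <- window_fst(sim$genotypes, pops[c("TL", "SL")],
                    make_windows(cfg$chrom_lengths))
  expect_gt(fst_bins(win)[["low"]], 0.9)
})
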