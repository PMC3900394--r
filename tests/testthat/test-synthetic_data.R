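test_that("all generators are byte-identical under a fixed seed", {
  p <- sim_params(seed = 99)
  expect_identical(sim_haplotypes(p), sim_haplotypes(p))
  expect_identical(sim_divergence_pair(p), sim_divergence_pair(p))
  expect_identical(sim_cds_pair(p, n_codons = 30),
                   sim_cds_pair(p, n_codons = 30))
  expect_identical(sim_mk(p), sim_mk(p))
  expect_identical(sim_presence(p), sim_presence(p))
  expect_identical(sim_fst(p, n_snps = 50), sim_fst(p, n_snps = 50))
  expect_identical(sim_expression(p), sim_expression(p))
})

test_that("haplotype generator honours theta = 0 and emits a truth record", {
  hap <- sim_haplotypes(sim_params(seed = 1, theta = 0, n = 5, L = 80))
  expect_equal(hap$truth$S, 0)
  ps <- polarize(hap$alignment)
  expect_equal(length(ps$site_counts), 0L)
  expect_equal(ps$L, 80L)

  hap2 <- sim_haplotypes(sim_params(seed = 2, theta = 6, n = 8, L = 300))
  ps2 <- polarize(hap2$alignment)
  # polarization recovers the planted derived counts exactly
  expect_equal(sort(ps2$site_counts), sort(hap2$truth$derived_counts))
  expect_equal(ps2$L, 300L)
})

test_that("hitchhiking skew plants high-frequency derived variants", {
  skewed <- sim_haplotypes(sim_params(seed = 3, theta = 30, n = 20, L = 500,
                                      skew_mode = "hitchhiking",
                                      hitchhiking_weight = 0.9))
  expect_gt(mean(skewed$truth$derived_counts > 0.8 * 20), 0.5)
})

test_that("divergence pairs hit the target distance in expectation", {
  same <- sim_divergence_pair(sim_params(seed = 4, target_k = 0))
  expect_identical(same$seq_a, same$seq_b)

  # kappa -> infinity suppresses transversions
  ts_only <- sim_divergence_pair(sim_params(seed = 5, L = 2000,
                                            target_k = 0.2,
                                            ts_tv_kappa = 1e9))
  est <- k2p_distance(ts_only$seq_a, ts_only$seq_b)
  expect_equal(est$Q, 0)

  ks <- vapply(1:100, function(s) {
    pair <- sim_divergence_pair(sim_params(seed = s, L = 1000,
                                           target_k = 0.17))
    k2p_distance(pair$seq_a, pair$seq_b)$k
  }, numeric(1))
  se <- stats::sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - 0.17), 3 * se)
})

test_that("CDS pairs are stop-free and usable for NG86", {
  cds <- sim_cds_pair(sim_params(seed = 6, target_k = 0.3), n_codons = 120)
  expect_equal(nchar(cds$cds_a) %% 3, 0)
  r <- nei_gojobori_ks(cds$cds_a, cds$cds_b)
  expect_gt(r$ks, 0)
})

test_that("MK generator centres alpha estimates on the truth", {
  a0 <- vapply(1:100, function(s)
    mk_alpha(sim_mk(sim_params(seed = s, alpha_true = 0))$table),
    numeric(1))
  se <- stats::sd(a0) / sqrt(length(a0))
  expect_lt(abs(mean(a0)), 3 * se + 0.01)

  # null calibration: equal rate ratios give uniform-ish one-sided p
  ps <- vapply(1:100, function(s)
    mk_test(sim_mk(sim_params(seed = s, alpha_true = 0))$table)$p_value,
    numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("presence histories respect birth and loss limits", {
  none <- sim_presence(sim_params(seed = 7, birth_rate = 0))
  expect_equal(nrow(none$presence$mat), 0L)
  expect_equal(none$n_born_total, 0L)

  lossfree <- sim_presence(sim_params(seed = 8, birth_rate = 0.3,
                                      loss_rate_per_myr = 0))
  # without loss every born gene is observed and has no absent taxa
  # inside its origin clade
  expect_equal(nrow(lossfree$presence$mat), lossfree$n_born_total)

  lossy <- sim_presence(sim_params(seed = 9, birth_rate = 1,
                                   loss_rate_per_myr = 0.2))
  expect_lt(nrow(lossy$presence$mat), lossy$n_born_total)
  # focal taxon is always present-expressed
  expect_true(all(lossy$presence$mat[, "mel"] == "present-expressed"))
})

test_that("Fst generator covers both extremes", {
  hi <- sim_fst(sim_params(seed = 10, fst_true = 1), n_snps = 300)
  est <- suppressMessages(weir_fst(hi$pop1, hi$pop2))
  expect_equal(est$regional, 1)

  lo <- sim_fst(sim_params(seed = 11, fst_true = 0), n_snps = 3000)
  est0 <- suppressMessages(weir_fst(lo$pop1, lo$pop2))
  expect_lt(abs(est0$regional), 0.02)
})

test_that("young simulated genes are silent outside their configured tissues", {
  sim <- sim_expression(sim_params(seed = 12), genes_per_group = 5)
  young <- sim$raw_counts[sim$truth == "0-4", , drop = FALSE]
  off <- setdiff(colnames(young),
                 default_breadth_config()[["0-4"]]$libraries)
  expect_true(all(young[, off] == 0))
})
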