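make_block <- function(ing_cols, og, n = length(ing_cols[[1]])) {
  # ing_cols: list of per-site ingroup character vectors (length n each);
  # og: outgroup base(s), recycled across sites
  og <- rep(og, length.out = length(ing_cols))
  m <- do.call(cbind, ing_cols)
  seqs <- c(apply(m, 1, paste, collapse = ""), paste(og, collapse = ""))
  names(seqs) <- c(paste0("h", seq_len(n)), "og")
  alignment_block(seqs, outgroup_id = "og")
}

test_that("polarization follows the outgroup-match rule", {
  blk <- make_block(list(c("A", "A", "G")), og = "A")
  ps <- polarize(blk)
  expect_equal(ps$site_counts, 1L)   # derived allele G carried once
  expect_equal(ps$L, 1L)

  # outgroup matches neither allele: site dropped from S and L
  blk2 <- make_block(list(c("A", "A", "G")), og = "C")
  ps2 <- polarize(blk2)
  expect_equal(length(ps2$site_counts), 0L)
  expect_equal(ps2$L, 0L)

  # fully monomorphic alignment
  mono <- make_block(rep(list(c("A", "A", "A")), 100), og = "A")
  psm <- polarize(mono)
  expect_equal(length(psm$site_counts), 0L)
  expect_equal(psm$L, 100L)

  # gap/N columns and tri-allelic columns are uncallable
  blk3 <- make_block(list(c("A", "-", "G"), c("A", "C", "G"),
                          c("T", "T", "N")), og = "A")
  expect_equal(polarize(blk3)$L, 0L)

  expect_error(polarize(alignment_block(c(a = "AC", b = "AC"))),
               "no outgroup")
})

test_that("theta_pi matches hand-derived value and brute-force pairwise oracle", {
  ps <- polarized_sites(n = 4, site_counts = c(1, 1, 3), L = 10)
  expect_equal(theta_pi(ps), 1.5)
  expect_equal(theta_pi(polarized_sites(4, integer(), L = 10)), 0)

  # symmetry i <-> n - i
  a <- polarized_sites(10, rep(1L, 6), L = 50)
  b <- polarized_sites(10, rep(9L, 6), L = 50)
  expect_equal(theta_pi(a), theta_pi(b))

  # oracle equivalence on random small instances
  for (seed in 1:20) {
    hap <- sim_haplotypes(sim_params(seed = seed, n = sample(3:8, 1),
                                     L = 50, theta = 3))
    expect_equal(theta_pi(polarize(hap$alignment)),
                 oracle_pairwise_pi(hap$alignment))
  }
})

test_that("theta_w uses the harmonic correction", {
  expect_equal(theta_w(polarized_sites(4, c(1, 1, 3), L = 10)),
               3 / (1 + 1/2 + 1/3), tolerance = 1e-12)
  expect_equal(theta_w(polarized_sites(2, c(1, 1, 1, 1, 1), L = 10)), 5)
  expect_equal(theta_w(polarized_sites(5, integer(), L = 10)), 0)
})

test_that("theta_h and H follow the unfolded-spectrum definitions", {
  res <- theta_h(polarized_sites(4, c(1, 1, 3), L = 10))
  expect_equal(res$theta_h, (2 * 2 * 1 + 2 * 1 * 9) / 12)
  expect_equal(res$H, 1.5 - res$theta_h)

  z <- theta_h(polarized_sites(6, integer(), L = 10))
  expect_equal(z$theta_h, 0)
  expect_equal(z$H, 0)

  # singleton-only spectra give positive H (theta_h = 2S/(n(n-1)) < pi)
  n <- 8; S <- 5
  res_s <- theta_h(polarized_sites(n, rep(1L, S), L = 20))
  expect_equal(res_s$theta_h, 2 * S / (n * (n - 1)))
  expect_gt(res_s$H, 0)
})

test_that("theta statistics are invariant to haplotype row order", {
  hap <- sim_haplotypes(sim_params(seed = 11, n = 10, L = 100, theta = 8))
  blk <- hap$alignment
  ing <- setdiff(blk$sequence_ids, blk$outgroup_id)
  perm <- sample(ing)
  seqs <- blk$sequences[match(c(perm, "outgroup"), blk$sequence_ids)]
  names(seqs) <- c(perm, "outgroup")
  blk2 <- alignment_block(seqs, outgroup_id = "outgroup")
  expect_equal(theta_pi(polarize(blk)), theta_pi(polarize(blk2)))
  expect_equal(theta_w(polarize(blk)), theta_w(polarize(blk2)))
  expect_equal(theta_h(polarize(blk)), theta_h(polarize(blk2)))
})

test_that("the DAF filter applies both strict thresholds", {
  snp <- function(dc, n) data.frame(position = 1L, ancestral_allele = "A",
                                    derived_allele = "G",
                                    derived_count = dc, sample_size = n,
                                    population_label = "mel")
  expect_equal(nrow(daf_filter(snp(1L, 40L))), 0L)    # DAF 2.5%
  expect_equal(nrow(daf_filter(snp(3L, 40L))), 1L)    # DAF 7.5%
  expect_equal(nrow(daf_filter(snp(3L, 30L))), 0L)    # n not > 30
  expect_equal(nrow(daf_filter(snp(2L, 40L))), 0L)    # DAF exactly 5%
})

test_that("sliding windows anchor at 0 and drop trailing partials", {
  hap <- sim_haplotypes(sim_params(seed = 3, n = 6, L = 150, theta = 6))
  tr <- sliding_scan(hap$alignment, "theta_pi", window = 100, step = 25)
  expect_equal(tr$start, c(0, 25, 50))
  expect_equal(tr$end, c(100, 125, 150))

  mono <- alignment_block(
    setNames(rep(paste(rep("A", 120), collapse = ""), 4),
             c("a", "b", "c", "og")), outgroup_id = "og")
  trm <- sliding_scan(mono, "theta_w", window = 100, step = 25)
  expect_true(all(trm$value == 0))
  trk <- sliding_scan(mono, "k2p", window = 100, step = 25)
  expect_true(all(trk$value == 0))

  short <- alignment_block(
    setNames(rep(paste(rep("A", 50), collapse = ""), 3),
             c("a", "b", "og")), outgroup_id = "og")
  expect_error(sliding_scan(short, "theta_pi", window = 100), "shorter")
  tr1 <- sliding_scan(short, "theta_pi", window = 100, allow_partial = TRUE)
  expect_equal(nrow(tr1), 1L)
  expect_equal(tr1$end, 50)
})
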