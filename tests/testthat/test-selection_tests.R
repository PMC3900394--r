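test_that("MK test reproduces published cluster-member tables", {
  # dme-miR-303 against neighbouring sites: D/P = 3.750, p = 7.89e-3
  r303 <- mk_test(mk_table(15, 4, 31, 38))
  expect_equal(r303$dp_sel, 3.750)
  expect_lt(abs(r303$p_value - 7.89e-3), 5e-6)

  # dme-miR-983: D/P = 14.000, p = 4.63e-4
  r983 <- mk_test(mk_table(14, 1, 31, 38))
  expect_equal(r983$dp_sel, 14.000)
  expect_lt(abs(r983$p_value - 4.63e-4), 5e-7)

  # equal D/P ratios carry no signal in the excess-divergence tail
  req <- mk_test(mk_table(10, 10, 100, 100))
  expect_gt(req$p_value, 0.4)

  # zero polymorphism in the test class reports an infinite ratio
  r982 <- mk_test(mk_table(14, 0, 31, 38))
  expect_true(is.infinite(r982$dp_sel))

  expect_error(mk_test(mk_table(0, 0, 0, 0)), "all-zero")
})

test_that("MK test stays exact with neutral counts in the 1e5 range", {
  r <- mk_test(mk_table(86, 4, 378361, 83996))
  expect_lt(abs(r$p_value - 1.1e-4), 5e-6)
  expect_equal(r$dp_sel, 21.50)
  expect_equal(r$dp_neut, 378361 / 83996)
  expect_true(is.finite(r$p_value) && r$p_value > 0)
})

test_that("MK one-sided p equals the hypergeometric-tail oracle on small tables", {
  set.seed(7)
  for (rep in 1:50) {
    tot <- sample(4:40, 1)
    x <- as.vector(stats::rmultinom(1, tot, prob = rep(0.25, 4)))
    if (sum(x) == 0) next
    tab <- mk_table(x[1], x[2], x[3], x[4])
    expect_equal(mk_test(tab)$p_value,
                 oracle_fisher_upper(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-12)
  }
})

test_that("two-sided MK test delegates to Fisher and verbose adds other tail", {
  tab <- mk_table(12, 3, 20, 30)
  r2 <- mk_test(tab, tail = "two-sided")
  expect_equal(r2$p_value,
               stats::fisher.test(matrix(c(12, 20, 3, 30), 2))$p.value)
  rv <- mk_test(tab, verbose = TRUE)
  expect_true(!is.null(rv$p_value_other_tail))
  # tails overlap on the observed table, so they sum to > 1
  expect_gte(rv$p_value + rv$p_value_other_tail, 1)
})

test_that("alpha ratio estimator matches published values and edge cases", {
  # 0-4 Myr precursor class: 79.1% adaptive fixations
  t_prec <- mk_table(86, 4, 378361, 83996)
  expect_equal(mk_alpha(t_prec, as_percent = TRUE), 79.1, tolerance = 0.05)
  # zero selected polymorphism attains the upper bound
  expect_equal(mk_alpha(mk_table(18, 0, 378361, 83996), as_percent = TRUE),
               100.0)
  # equal ratios: no adaptive excess
  expect_equal(mk_alpha(mk_table(10, 10, 100, 100)), 0)
  expect_error(mk_alpha(mk_table(0, 4, 100, 100)), "undefined")
  expect_error(mk_alpha(mk_table(10, 4, 100, 0)), "undefined")
})

test_that("BH adjustment equals reference step-up and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(11)
  for (rep in 1:20) {
    p <- stats::runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 0)), "validation")
  expect_error(bh_adjust(c(0.5, 1.2)), "validation")
})

test_that("haploid Weir-Cockerham Fst behaves at the differentiation extremes", {
  fixed <- weir_fst(data.frame(derived = 10, n = 10),
                    data.frame(derived = 0, n = 10))
  expect_equal(fixed$per_site, 1)
  expect_equal(fixed$regional, 1)

  same <- weir_fst(data.frame(derived = 5, n = 10),
                   data.frame(derived = 5, n = 10))
  expect_lte(same$regional, 0)

  expect_message(
    mono <- weir_fst(data.frame(derived = c(0, 3), n = 10),
                     data.frame(derived = c(0, 7), n = 10)),
    "monomorphic")
  expect_equal(mono$n_sites_used, 1L)
  expect_true(is.na(mono$per_site[1]))
})

test_that("per-site Fst equals the variance-component oracle", {
  set.seed(19)
  for (rep in 1:40) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    d1 <- sample(0:n1, 1); d2 <- sample(0:n2, 1)
    if ((d1 + d2) == 0 || (d1 + d2) == (n1 + n2)) next
    got <- suppressMessages(
      weir_fst(data.frame(derived = d1, n = n1),
               data.frame(derived = d2, n = n2)))
    expect_equal(got$per_site, oracle_wc_fst_site(d1, n1, d2, n2),
                 tolerance = 1e-12)
  }
})

test_that("rank-sum comparison is exact for small samples", {
  r <- fst_rank_comparison(3, c(1, 2))
  expect_equal(unname(r$U), 2)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)

  r2 <- fst_rank_comparison(6:10, 1:5)
  expect_equal(r2$p_value, 1 / choose(10, 5), tolerance = 1e-9)

  expect_warning(r3 <- fst_rank_comparison(rep(1, 3), rep(1, 4)), "tied")
  expect_equal(r3$p_value, 1)

  expect_error(fst_rank_comparison(numeric(), 1:3), "nonempty")
})

test_that("rank-sum p-values are roughly uniform under the null", {
  set.seed(23)
  ps <- replicate(200, {
    x <- stats::rnorm(30)
    fst_rank_comparison(x[1:10], x[11:30])$p_value
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})
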