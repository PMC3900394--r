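test_that("mirtron calls require exact splice-site matches at both ends", {
  prec <- list(chrom = "X", start = 100L, end = 180L, strand = "+")
  intr <- data.frame(feature_id = "in1", chrom = "X", start = 100L,
                     end = 180L, strand = "+", feature_class = "intron")
  expect_equal(classify_gene(prec, intr), "mirtron")

  off5 <- intr; off5$start <- 95L
  expect_equal(classify_gene(prec, off5), "canonical")
  expect_equal(classify_gene(prec, NULL), "canonical")
  other_chrom <- intr; other_chrom$chrom <- "2L"
  expect_equal(classify_gene(prec, other_chrom), "canonical")
})

test_that("cluster detection applies the strict more-than-three rule", {
  mk_prec <- function(ids, starts, chrom = "X")
    data.frame(feature_id = ids, chrom = chrom, start = starts,
               end = starts + 80L, strand = "+",
               feature_class = "precursor")

  four <- detect_clusters(mk_prec(paste0("m", 1:4),
                                  c(0L, 5000L, 10000L, 15000L)))
  expect_equal(length(unique(four)), 1L)
  expect_false(any(is.na(four)))

  three <- detect_clusters(mk_prec(paste0("m", 1:3),
                                   c(0L, 4000L, 9000L)))
  expect_true(all(is.na(three)))

  five <- detect_clusters(mk_prec(paste0("m", 1:5),
                                  c(0L, 5000L, 10000L, 15000L, 40000L)))
  expect_equal(sum(!is.na(five)), 4L)
  expect_true(is.na(five[["m5"]]))

  # chromosomes never chain together
  two_chrom <- detect_clusters(
    mk_prec(paste0("m", 1:6), rep(c(0L, 1000L, 2000L), 2),
            chrom = rep(c("X", "2L"), each = 3)))
  expect_true(all(is.na(two_chrom)))
})

test_that("RPM normalization conserves per-library totals and splits multireads", {
  raw <- matrix(c(400, 1600, 100, 900), nrow = 2,
                dimnames = list(c("g1", "g2"), c("lib1", "lib2")))
  em <- rpm_normalize(raw)
  expect_equal(colSums(em$rpm), c(lib1 = 1e6, lib2 = 1e6))
  expect_equal(em$rpm["g1", "lib1"], 1e6 * 400 / 2000)

  # a read matching 2 precursors contributes 0.5 to each
  mm <- matrix(c(2, 1, 1, 1), nrow = 2, dimnames = dimnames(raw))
  em2 <- rpm_normalize(raw, mm)
  expect_equal(em2$weighted["g1", "lib1"], 200)
  expect_equal(colSums(em2$rpm), c(lib1 = 1e6, lib2 = 1e6))

  zero <- raw; zero[, 2] <- 0
  expect_error(rpm_normalize(zero), "zero total")
  expect_error(rpm_normalize(raw, matrix(0.5, 2, 2)), ">= 1")
})

test_that("expression classification is strict at 200 RPM and monotone", {
  rpm <- rbind(exactly = c(200, 10), above = c(201, 0), zero = c(0, 0))
  colnames(rpm) <- c("a", "b")
  cls <- classify_expression(rpm)
  expect_equal(unname(cls["exactly"]), "low")
  expect_equal(unname(cls["above"]), "high")
  expect_equal(unname(cls["zero"]), "low")

  # adding reads never demotes a gene
  bumped <- rpm
  bumped["exactly", "a"] <- 500
  expect_equal(unname(classify_expression(bumped)["exactly"]), "high")
})

test_that("expression breadth grows with age on synthetic fixtures", {
  sim <- sim_expression(sim_params(seed = 31), genes_per_group = 12)
  em <- rpm_normalize(sim$raw_counts)
  breadth <- expression_breadth(em)
  mean_by_group <- tapply(breadth[names(sim$truth)], sim$truth, mean)
  ordered_groups <- c("0-4", "4-30", "30-60", "60-250", ">250")
  expect_true(all(diff(mean_by_group[ordered_groups]) >= 0))
  expect_gt(mean_by_group[">250"], mean_by_group[["0-4"]])
})

test_that("profile clustering separates age groups and ignores library order", {
  sim <- sim_expression(sim_params(seed = 32), genes_per_group = 6)
  em <- rpm_normalize(sim$raw_counts)
  res <- cluster_expression_profiles(em, group_by_age = sim$truth)
  expect_s3_class(res$hclust, "hclust")
  expect_equal(nrow(res$group_means), 5L)

  # young genes' mean profile is empty outside their configured tissues
  young <- res$group_means["0-4", ]
  expect_equal(unname(young[c("ovary", "embryo", "adult_head",
                              "adult_body")]),
               rep(0, 4))

  # permuting libraries leaves merge heights unchanged
  perm <- sample(ncol(em$rpm))
  res_p <- cluster_expression_profiles(em$rpm[, perm])
  res_o <- cluster_expression_profiles(em$rpm)
  expect_equal(sort(res_p$hclust$height), sort(res_o$hclust$height))

  # identical profiles merge at height zero
  dup <- rbind(a = c(10, 20, 30), b = c(10, 20, 30), c = c(500, 0, 0))
  colnames(dup) <- c("l1", "l2", "l3")
  res_d <- cluster_expression_profiles(dup)
  expect_equal(min(res_d$hclust$height), 0)

  # single profile: identity ordering, no tree
  one <- cluster_expression_profiles(dup[1, , drop = FALSE])
  expect_null(one$hclust)
  expect_equal(one$order, 1L)
})
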