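#' Construct an MK contingency table
#'
#' The 2x2 substrate of the McDonald-Kreitman framework: fixed divergence
#' (D) and within-species polymorphism (P) counts for a test class of
#' sites (e.g. a miRNA precursor) against a neutral reference class (e.g.
#' flanking sites or genome-wide 4-fold degenerate sites).
#'
#' @param d_sel,p_sel divergence and polymorphism counts in the test class.
#' @param d_neut,p_neut divergence and polymorphism counts in the neutral
#'   class.
#' @param labels length-2 character: names of the two classes.
#' @return object of class \code{mk_table}.
#' @export
mk_table <- function(d_sel, p_sel, d_neut, p_neut,
                     labels = c("test", "neutral")) {
  counts <- c(d_sel, p_sel, d_neut, p_neut)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("MK counts must be non-negative integers")
  structure(list(d_sel = d_sel, p_sel = p_sel, d_neut = d_neut,
                 p_neut = p_neut, labels = labels),
            class = "mk_table")
}

#' @export
print.mk_table <- function(x, ...) {
  m <- matrix(c(x$d_sel, x$p_sel, x$d_neut, x$p_neut), nrow = 2,
              byrow = TRUE,
              dimnames = list(x$labels, c("D", "P")))
  print(m)
  invisible(x)
}

## Upper hypergeometric tail P(X >= d_sel) with margins fixed; phyper
## works on log-gamma internally so neutral-class counts in the 1e5-1e6
## range stay exact.
mk_tail_p <- function(d_sel, p_sel, d_neut, p_neut, tail) {
  D <- d_sel + d_neut          # divergence column total
  P <- p_sel + p_neut          # polymorphism column total
  k <- d_sel + p_sel           # test-class row total
  switch(tail,
    greater = stats::phyper(d_sel - 1, D, P, k, lower.tail = FALSE),
    less = stats::phyper(d_sel, D, P, k, lower.tail = TRUE),
    stop("unknown tail: ", tail))
}

#' McDonald-Kreitman test
#'
#' Fisher's exact test on the 2x2 table
#' \code{[[d_sel, p_sel], [d_neut, p_neut]]}. The default tail tests for
#' an excess of fixed divergence in the test class (positive selection);
#' \code{tail = "two-sided"} delegates to \code{stats::fisher.test}.
#' A test class with zero polymorphism reports an infinite D/P ratio.
#'
#' @param table an \code{\link{mk_table}}.
#' @param tail \code{"one-sided-excess-divergence"} (default),
#'   \code{"one-sided-deficit-divergence"} or \code{"two-sided"}.
#' @param verbose also report the opposite one-sided p-value.
#' @return object of class \code{mk_result}: list with \code{dp_sel},
#'   \code{dp_neut}, \code{p_value}, \code{tail}, \code{table} and, when
#'   \code{verbose}, \code{p_value_other_tail}.
#' @export
mk_test <- function(table, tail = c("one-sided-excess-divergence",
                                    "one-sided-deficit-divergence",
                                    "two-sided"),
                    verbose = FALSE) {
  stopifnot(inherits(table, "mk_table"))
  tail <- match.arg(tail)
  with(table, {
    if (d_sel + p_sel + d_neut + p_neut == 0)
      stop("all-zero MK table")
    p <- switch(tail,
      `one-sided-excess-divergence` =
        mk_tail_p(d_sel, p_sel, d_neut, p_neut, "greater"),
      `one-sided-deficit-divergence` =
        mk_tail_p(d_sel, p_sel, d_neut, p_neut, "less"),
      `two-sided` = stats::fisher.test(
        matrix(c(d_sel, d_neut, p_sel, p_neut), nrow = 2))$p.value)
    res <- list(dp_sel = if (p_sel == 0) Inf else d_sel / p_sel,
                dp_neut = if (p_neut == 0) Inf else d_neut / p_neut,
                p_value = p, tail = tail, table = table)
    if (verbose && tail != "two-sided")
      res$p_value_other_tail <- mk_tail_p(
        d_sel, p_sel, d_neut, p_neut,
        if (tail == "one-sided-excess-divergence") "less" else "greater")
    structure(res, class = "mk_result")
  })
}

#' @export
print.mk_result <- function(x, ...) {
  cat(sprintf("MK test (%s): D/P[test] = %s, D/P[neutral] = %.3f, p = %.3g\n",
              x$tail,
              if (is.infinite(x$dp_sel)) "Inf." else sprintf("%.3f", x$dp_sel),
              x$dp_neut, x$p_value))
  invisible(x)
}

#' Proportion of adaptive fixations (alpha)
#'
#' The ratio estimator
#' \deqn{\alpha = 1 - \frac{P_{sel}}{D_{sel}} \cdot \frac{D_{neut}}{P_{neut}}.}
#' With zero polymorphism in the test class the estimator attains its
#' upper bound of 1 (all fixations adaptive).
#'
#' @param table an \code{\link{mk_table}} with \code{d_sel > 0},
#'   \code{d_neut > 0} and \code{p_neut > 0}.
#' @param as_percent return percent instead of a fraction?
#' @return numeric; at most 1 (100 when \code{as_percent}).
#' @export
mk_alpha <- function(table, as_percent = FALSE) {
  stopifnot(inherits(table, "mk_table"))
  with(table, {
    if (d_sel == 0) stop("alpha undefined: no divergence in test class")
    if (d_neut == 0 || p_neut == 0)
      stop("alpha undefined: neutral class must have divergence and polymorphism")
    a <- 1 - (p_sel / d_sel) * (d_neut / p_neut)
    if (as_percent) 100 * a else a
  })
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement, capped at 1. Inputs are validated to lie in (0, 1].
#'
#' @param p_values numeric vector of raw p-values.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("validation error: p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Weir-Cockerham Fst for haploid allele samples
#'
#' Variance-component estimator of population differentiation for two
#' populations of sequenced inbred lines, treated as haploid allele
#' samples (no heterozygosity terms). Per site, with sample sizes
#' \eqn{n_1, n_2}, weighted mean frequency \eqn{\bar p}, and
#' \eqn{n_c = (n_T - \sum n_i^2/n_T)/(r-1)}:
#' \deqn{MSP = \sum_i n_i (p_i - \bar p)^2 / (r - 1),\quad
#'       MSG = \sum_i n_i p_i (1 - p_i) / \sum_i (n_i - 1)}
#' and \eqn{\hat F_{st} = (MSP - MSG) / (MSP + (n_c - 1) MSG)}.
#' The regional estimate is the ratio of sums of the numerator and
#' denominator components across sites (small negative values are normal
#' under no differentiation).
#'
#' @param counts_pop1,counts_pop2 data.frames (or lists) with vectors
#'   \code{derived} (derived/alternate allele count per site) and
#'   \code{n} (haplotypes sampled per site).
#' @return object of class \code{fst_result}: list with \code{per_site}
#'   (NA for sites monomorphic across both populations, which are
#'   excluded), \code{regional}, \code{n_sites_used}, \code{pop_sizes}.
#' @export
weir_fst <- function(counts_pop1, counts_pop2) {
  d1 <- counts_pop1$derived; n1 <- counts_pop1$n
  d2 <- counts_pop2$derived; n2 <- counts_pop2$n
  if (length(d1) != length(d2))
    stop("populations must report the same sites")
  if (any(d1 > n1) || any(d2 > n2) || any(c(d1, d2) < 0))
    stop("allele counts must lie in [0, n]")
  r <- 2
  p1 <- d1 / n1; p2 <- d2 / n2
  nT <- n1 + n2
  pbar <- (d1 + d2) / nT
  mono <- (d1 + d2) == 0 | (d1 + d2) == nT
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nT - r)
  n_c <- (nT - (n1^2 + n2^2) / nT) / (r - 1)
  num <- msp - msg
  den <- msp + (n_c - 1) * msg
  per_site <- ifelse(mono | den == 0, NA_real_, num / den)
  use <- !mono
  if (any(mono))
    message(sum(mono), " site(s) monomorphic across both populations excluded")
  regional <- if (any(use)) sum(num[use]) / sum(den[use]) else NA_real_
  structure(list(per_site = per_site, regional = regional,
                 n_sites_used = sum(use),
                 pop_sizes = list(pop1 = n1, pop2 = n2)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham Fst (haploid): regional = %.4f over %d sites\n",
              x$regional, x$n_sites_used))
  invisible(x)
}

#' Rank-sum comparison of focal vs background Fst values
#'
#' One-sided Mann-Whitney U test of whether the focal values (e.g.
#' per-SNP Fst inside one precursor) are shifted above the background
#' (all SNPs in the region). Exact when the combined sample size is at
#' most 20 and there are no ties; otherwise the normal approximation with
#' tie correction is used.
#'
#' @param focal_values,background_values nonempty numeric vectors.
#' @return list with \code{U} (focal-vs-background statistic) and
#'   \code{p_value}.
#' @export
fst_rank_comparison <- function(focal_values, background_values) {
  if (!length(focal_values) || !length(background_values))
    stop("both samples must be nonempty")
  all_vals <- c(focal_values, background_values)
  if (length(unique(all_vals)) == 1L) {
    warning("all values tied; no rank information")
    return(list(U = length(focal_values) * length(background_values) / 2,
                p_value = 1))
  }
  n_tot <- length(all_vals)
  has_ties <- anyDuplicated(all_vals) > 0L
  wt <- suppressWarnings(stats::wilcox.test(
    focal_values, background_values, alternative = "greater",
    exact = (n_tot <= 20L && !has_ties), correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}
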