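#' Construct a polarized site set
#'
#' The substrate of all unfolded site-frequency-spectrum statistics:
#' the ingroup sample size \code{n}, the derived-allele count of every
#' segregating site, and the number of callable monomorphic+polymorphic
#' sites \code{L}.
#'
#' @param n ingroup sample size (number of haplotypes), >= 2.
#' @param site_counts integer vector of derived counts, each in
#'   \code{[1, n-1]}.
#' @param L callable length in sites; must be >= number of segregating
#'   sites.
#' @return object of class \code{polarized_sites}.
#' @export
polarized_sites <- function(n, site_counts = integer(), L = length(site_counts)) {
  n <- as.integer(n)
  if (n < 2L) stop("sample size n must be >= 2")
  site_counts <- as.integer(site_counts)
  if (length(site_counts) && (any(site_counts < 1L) || any(site_counts > n - 1L)))
    stop("derived counts must lie in [1, n-1]")
  if (L < length(site_counts))
    stop("callable length L smaller than number of segregating sites")
  structure(list(n = n, site_counts = site_counts, L = as.integer(L)),
            class = "polarized_sites")
}

#' @export
print.polarized_sites <- function(x, ...) {
  cat("polarized_sites: n =", x$n, ", S =", length(x$site_counts),
      ", L =", x$L, "\n")
  invisible(x)
}

## Column split of an alignment into a character matrix; '-'/'N' kept as is.
alignment_matrix <- function(block) {
  m <- do.call(rbind, strsplit(block$sequences, "", fixed = TRUE))
  rownames(m) <- block$sequence_ids
  m
}

#' Polarize an alignment against its outgroup
#'
#' Scans each alignment column. Columns where any ingroup or outgroup base
#' is a gap or \code{N} are uncallable and skipped entirely. Monomorphic
#' ingroup columns add to the callable length only. Biallelic ingroup
#' columns where the outgroup carries one of the two alleles yield a
#' derived-allele count (the count of the non-outgroup allele); columns
#' where the outgroup matches neither allele, and columns with three or
#' more ingroup alleles, are discarded from both the segregating sites and
#' the callable length.
#'
#' @param block an \code{\link{alignment_block}} with a designated
#'   outgroup row and >= 2 ingroup rows.
#' @return a \code{\link{polarized_sites}} object.
#' @export
polarize <- function(block) {
  if (is.null(block$outgroup_id))
    stop("configuration error: no outgroup designated in alignment")
  m <- alignment_matrix(block)
  og <- m[block$outgroup_id, ]
  ing <- m[setdiff(block$sequence_ids, block$outgroup_id), , drop = FALSE]
  if (nrow(ing) < 2L) stop("need >= 2 ingroup rows for population statistics")
  n <- nrow(ing)
  counts <- integer(0)
  L <- 0L
  for (j in seq_len(ncol(m))) {
    col <- ing[, j]
    if (any(col %in% c("-", "N")) || og[j] %in% c("-", "N")) next
    alleles <- unique(col)
    if (length(alleles) == 1L) {
      L <- L + 1L
    } else if (length(alleles) == 2L) {
      if (!og[j] %in% alleles) next       # misdirected polarization risk
      derived <- alleles[alleles != og[j]]
      counts <- c(counts, sum(col == derived))
      L <- L + 1L
    }                                      # tri-allelic: drop
  }
  polarized_sites(n = n, site_counts = counts, L = L)
}

#' Nucleotide diversity (Tajima's pi) from the unfolded spectrum
#'
#' \deqn{\theta_\pi = \sum_i 2 i (n-i) S_i / (n(n-1))}
#' equivalently the mean number of pairwise differences among the
#' \code{n} sampled haplotypes.
#'
#' @param sites a \code{\link{polarized_sites}} object.
#' @param per_site divide by callable length?
#' @return non-negative numeric.
#' @export
theta_pi <- function(sites, per_site = FALSE) {
  stopifnot(inherits(sites, "polarized_sites"))
  n <- sites$n
  i <- sites$site_counts
  v <- sum(2 * i * (n - i)) / (n * (n - 1))
  if (per_site) v / sites$L else v
}

#' Watterson's theta from the number of segregating sites
#'
#' \deqn{\theta_W = S / a_n,\quad a_n = \sum_{k=1}^{n-1} 1/k}
#'
#' @inheritParams theta_pi
#' @return non-negative numeric.
#' @export
theta_w <- function(sites, per_site = FALSE) {
  stopifnot(inherits(sites, "polarized_sites"))
  a_n <- harmonic_number(sites$n - 1L)
  v <- length(sites$site_counts) / a_n
  if (per_site) v / sites$L else v
}

harmonic_number <- function(k) sum(1 / seq_len(k))

#' Fay and Wu's theta_H and the H statistic
#'
#' \deqn{\theta_H = \sum_i 2 S_i i^2 / (n(n-1)),\qquad H = \theta_\pi - \theta_H}
#' \code{theta_H} weights variants by the square of their derived-allele
#' count, so an excess of high-frequency derived alleles (the hitchhiking
#' footprint of a selective sweep) inflates it above \code{theta_pi},
#' driving \code{H} negative.
#'
#' @inheritParams theta_pi
#' @return list with elements \code{theta_h} and \code{H}.
#' @export
theta_h <- function(sites, per_site = FALSE) {
  stopifnot(inherits(sites, "polarized_sites"))
  n <- sites$n
  i <- sites$site_counts
  th <- sum(2 * i^2) / (n * (n - 1))
  tp <- sum(2 * i * (n - i)) / (n * (n - 1))
  if (per_site) {
    th <- th / sites$L
    tp <- tp / sites$L
  }
  list(theta_h = th, H = tp - th)
}

#' Derived-allele-frequency filter for MK polymorphisms
#'
#' Keeps SNPs detected on strictly more than \code{min_samples} haplotypes
#' and with derived allele frequency strictly above \code{min_daf}. Both
#' thresholds are strict inequalities.
#'
#' @param snps SNP record data.frame (see \code{\link{read_snp_table}}).
#' @param min_daf minimum DAF, exclusive (default 0.05).
#' @param min_samples minimum sample size, exclusive (default 30).
#' @return filtered data.frame (possibly zero rows).
#' @export
daf_filter <- function(snps, min_daf = 0.05, min_samples = 30L) {
  keep <- snps$sample_size > min_samples &
    snps$derived_count / snps$sample_size > min_daf
  snps[keep, , drop = FALSE]
}

#' Sliding-window scan of a population alignment
#'
#' Computes a statistic in windows \code{[s, s+window)} for
#' \code{s = 0, step, 2*step, ...} while \code{s + window <= L} (alignment
#' columns, 0-based). Statistics \code{"theta_pi"}, \code{"theta_w"},
#' \code{"theta_h"} and \code{"H"} polarize each window against the
#' outgroup; \code{"k2p"} computes Kimura 2-parameter divergence between
#' the ingroup consensus-free first row and the outgroup per window.
#'
#' @param block an \code{\link{alignment_block}} (outgroup required for
#'   polarized statistics and for \code{"k2p"}).
#' @param stat one of \code{"theta_pi"}, \code{"theta_w"}, \code{"theta_h"},
#'   \code{"H"}, \code{"k2p"}.
#' @param window window size in alignment columns (default 100).
#' @param step step width in columns (default 25).
#' @param per_site scale theta statistics by callable sites in the window?
#' @param allow_partial if the region is shorter than \code{window}, emit a
#'   single truncated window instead of erroring.
#' @return data.frame of class \code{window_track} with columns
#'   \code{start}, \code{end}, \code{stat}, \code{value},
#'   \code{n_callable}.
#' @export
sliding_scan <- function(block, stat = c("theta_pi", "theta_w", "theta_h",
                                         "H", "k2p"),
                         window = 100L, step = 25L, per_site = FALSE,
                         allow_partial = FALSE) {
  stat <- match.arg(stat)
  L <- block$length
  if (L < window) {
    if (!allow_partial)
      stop("region length ", L, " shorter than window ", window,
           " (set allow_partial = TRUE for a single truncated window)")
    starts <- 0L
    ends <- L
  } else {
    starts <- seq.int(0L, L - window, by = step)
    ends <- starts + window
  }
  m <- alignment_matrix(block)
  values <- numeric(length(starts))
  callable <- integer(length(starts))
  for (w in seq_along(starts)) {
    cols <- (starts[w] + 1L):ends[w]            # 1-based matrix columns
    sub <- subset_block(block, m, cols)
    if (stat == "k2p") {
      values[w] <- window_k2p(sub)
      callable[w] <- sub$length
    } else {
      ps <- polarize(sub)
      callable[w] <- ps$L
      values[w] <- switch(stat,
        theta_pi = theta_pi(ps, per_site = per_site),
        theta_w = theta_w(ps, per_site = per_site),
        theta_h = theta_h(ps, per_site = per_site)$theta_h,
        H = theta_h(ps, per_site = per_site)$H)
    }
  }
  out <- data.frame(start = starts, end = ends, stat = stat, value = values,
                    n_callable = callable, stringsAsFactors = FALSE)
  class(out) <- c("window_track", "data.frame")
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "per_site") <- per_site
  out
}

subset_block <- function(block, m, cols) {
  seqs <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
  alignment_block(setNames(seqs, block$sequence_ids),
                  outgroup_id = block$outgroup_id)
}

## K2P between the first ingroup row and the outgroup, 0 when saturated
## columns are absent and no sites remain.
window_k2p <- function(sub) {
  if (is.null(sub$outgroup_id))
    stop("k2p scan requires a designated outgroup")
  ing_id <- setdiff(sub$sequence_ids, sub$outgroup_id)[1L]
  a <- sub$sequences[match(ing_id, sub$sequence_ids)]
  b <- sub$sequences[match(sub$outgroup_id, sub$sequence_ids)]
  k2p_distance(a, b)$k
}

#' Write a window track as TSV
#' @param track a \code{window_track} data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_window_track <- function(track, path) {
  utils::write.table(as.data.frame(track), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
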