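#' Classify a miRNA gene as canonical or mirtron
#'
#' A mirtron is a precursor whose 5' and 3' ends both coincide exactly
#' with the splice sites of a host intron; everything else is canonical.
#' Coordinates are 0-based half-open on the same chromosome and strand.
#'
#' @param precursor one feature row (list/data.frame row with
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}).
#' @param host_introns feature data.frame of introns (may be empty or
#'   \code{NULL}).
#' @return \code{"mirtron"} or \code{"canonical"}.
#' @export
classify_gene <- function(precursor, host_introns = NULL) {
  if (is.null(host_introns) || nrow(host_introns) == 0L) return("canonical")
  hit <- host_introns$chrom == precursor$chrom &
    host_introns$strand == precursor$strand &
    host_introns$start == precursor$start &
    host_introns$end == precursor$end
  if (any(hit)) "mirtron" else "canonical"
}

#' Detect genomic miRNA clusters
#'
#' Chains precursors along each chromosome: consecutive precursors whose
#' starts lie within \code{span} bp extend the chain. Chains with strictly
#' more than \code{min_members_strictly_more_than} members become named
#' clusters; all other genes stay unclustered (\code{NA}).
#'
#' @param precursors feature data.frame with \code{feature_id},
#'   \code{chrom}, \code{start}.
#' @param span chaining window in bp (default 20000).
#' @param min_members_strictly_more_than minimum chain size, exclusive
#'   (default 3: a cluster needs more than three members).
#' @return character vector of cluster ids (\code{NA} = unclustered),
#'   named by feature_id.
#' @export
detect_clusters <- function(precursors, span = 20000L,
                            min_members_strictly_more_than = 3L) {
  ord <- order(precursors$chrom, precursors$start)
  df <- precursors[ord, , drop = FALSE]
  chain <- integer(nrow(df))
  if (nrow(df)) {
    chain[1L] <- 1L
    for (i in seq_len(nrow(df))[-1L]) {
      same <- df$chrom[i] == df$chrom[i - 1L] &&
        (df$start[i] - df$start[i - 1L]) <= span
      chain[i] <- if (same) chain[i - 1L] else chain[i - 1L] + 1L
    }
  }
  sizes <- table(chain)
  keep <- as.integer(names(sizes)[sizes > min_members_strictly_more_than])
  out <- rep(NA_character_, nrow(df))
  for (k in seq_along(keep))
    out[chain == keep[k]] <- paste0("cluster_", k)
  names(out) <- df$feature_id
  out[match(precursors$feature_id, names(out))]
}

#' Normalize small-RNA counts to reads per million (RPM)
#'
#' Each read count is first divided by its number of matches to miRNA
#' precursors (multireads contribute fractionally), then each library is
#' scaled so the weighted counts sum to one million.
#'
#' @param raw_counts numeric matrix (rows: miRNA ids, columns: library
#'   ids) of read counts.
#' @param multimap_counts matrix of the same shape (or a per-gene vector)
#'   giving the number of precursor matches per read group; default 1
#'   (unique mappers).
#' @return object of class \code{expression_matrix}: list with
#'   \code{rpm}, \code{raw_counts}, \code{weighted}.
#' @export
rpm_normalize <- function(raw_counts, multimap_counts = 1) {
  if (any(raw_counts < 0)) stop("counts must be nonnegative")
  if (any(multimap_counts < 1)) stop("multimap divisor must be >= 1")
  w <- raw_counts / multimap_counts
  totals <- colSums(w)
  if (any(totals == 0))
    stop("library with zero total counts: ",
         paste(colnames(raw_counts)[totals == 0], collapse = ", "))
  rpm <- sweep(w, 2L, totals, "/") * 1e6
  structure(list(rpm = rpm, raw_counts = raw_counts, weighted = w),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$rpm), "miRNAs x", ncol(x$rpm),
      "libraries (RPM)\n")
  invisible(x)
}

#' Classify genes as highly or lowly expressed
#'
#' A gene is \code{"high"} iff its RPM exceeds the threshold (strictly) in
#' at least one library; otherwise \code{"low"}.
#'
#' @param em an \code{\link{expression_matrix}} (or a bare RPM matrix).
#' @param threshold RPM cutoff, exclusive (default 200).
#' @return named character vector (\code{high}/\code{low}) per gene.
#' @export
classify_expression <- function(em, threshold = 200) {
  rpm <- if (inherits(em, "expression_matrix")) em$rpm else em
  cls <- ifelse(apply(rpm, 1L, max) > threshold, "high", "low")
  setNames(cls, rownames(rpm))
}

#' Expression breadth per gene
#'
#' Number of libraries in which a gene has RPM above a floor (default 0,
#' i.e. any expression).
#'
#' @inheritParams classify_expression
#' @param floor exclusive RPM floor.
#' @return named integer vector.
#' @export
expression_breadth <- function(em, floor = 0) {
  rpm <- if (inherits(em, "expression_matrix")) em$rpm else em
  setNames(rowSums(rpm > floor), rownames(rpm))
}

#' Hierarchical clustering of expression profiles
#'
#' Log2-transforms RPM values (with a pseudocount), clusters profiles by
#' average-linkage agglomeration on Euclidean distances, and reports
#' per-age-group mean profiles across libraries when an age grouping is
#' supplied.
#'
#' @param em an \code{\link{expression_matrix}} (or RPM matrix).
#' @param group_by_age optional named character vector of age-group labels
#'   per gene.
#' @param pseudocount added before log2 (default 1).
#' @return list with \code{hclust} (a \code{stats::hclust} object, or
#'   \code{NULL} for a single profile), \code{order} (row ordering),
#'   \code{log2_rpm}, and \code{group_means} (age-group x library matrix
#'   of mean log2 RPM, when grouping supplied).
#' @export
cluster_expression_profiles <- function(em, group_by_age = NULL,
                                        pseudocount = 1) {
  rpm <- if (inherits(em, "expression_matrix")) em$rpm else em
  lg <- log2(rpm + pseudocount)
  if (nrow(lg) < 2L) {
    hc <- NULL
    ord <- seq_len(nrow(lg))
  } else {
    hc <- stats::hclust(stats::dist(lg, method = "euclidean"),
                        method = "average")
    ord <- hc$order
  }
  group_means <- NULL
  if (!is.null(group_by_age)) {
    groups <- group_by_age[rownames(lg)]
    group_means <- do.call(rbind, lapply(split(seq_len(nrow(lg)), groups),
      function(idx) colMeans(lg[idx, , drop = FALSE])))
  }
  list(hclust = hc, order = ord, log2_rpm = lg, group_means = group_means)
}
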