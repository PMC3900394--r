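#' @importFrom stats setNames
NULL

DNA_ALPHABET_STRICT <- c("A", "C", "G", "T", "N", "-")

#' Construct an alignment block
#'
#' An alignment block holds equal-length nucleotide sequences (population
#' haplotypes, optionally with one designated outgroup row) as plain
#' uppercase character strings over the alphabet \code{A,C,G,T,N,-}.
#' Coordinates into the alignment are 0-based half-open throughout the
#' package.
#'
#' @param sequences named character vector of equal-length sequences
#'   (names are the sequence ids).
#' @param outgroup_id optional id of the outgroup row; must match one name.
#' @return object of class \code{alignment_block} with elements
#'   \code{sequence_ids}, \code{sequences}, \code{outgroup_id},
#'   \code{length}.
#' @export
alignment_block <- function(sequences, outgroup_id = NULL) {
  if (length(sequences) == 0L) stop("empty alignment: no sequences")
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("all sequences must be named")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("alignment-format error: sequences have unequal lengths (",
         paste(unique(lens), collapse = ", "), ")")
  bad <- grepl(paste0("[^", paste(DNA_ALPHABET_STRICT, collapse = ""), "]"),
               sequences)
  if (any(bad))
    stop("non-DNA alphabet in sequence(s): ",
         paste(names(sequences)[bad], collapse = ", "),
         " (allowed: A,C,G,T,N,-)")
  if (!is.null(outgroup_id) && !outgroup_id %in% names(sequences))
    stop("outgroup_id '", outgroup_id, "' not among sequence ids")
  structure(
    list(sequence_ids = names(sequences),
         sequences = unname(sequences),
         outgroup_id = outgroup_id,
         length = lens[[1L]]),
    class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat("alignment_block:", length(x$sequence_ids), "sequences of length",
      x$length, "\n")
  if (!is.null(x$outgroup_id)) cat("  outgroup:", x$outgroup_id, "\n")
  invisible(x)
}

#' Read a multi-FASTA alignment
#'
#' @param path path to a multi-FASTA file of equal-length records.
#' @param outgroup_id optional record id to designate as outgroup.
#' @return an \code{\link{alignment_block}} preserving input order;
#'   lowercase bases are normalised to uppercase.
#' @export
read_fasta_alignment <- function(path, outgroup_id = NULL) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty-input error: no FASTA records in ", path)
  seqs <- setNames(as.character(ss), names(ss))
  alignment_block(seqs, outgroup_id = outgroup_id)
}

#' Write an alignment block as multi-FASTA
#'
#' @param block an \code{\link{alignment_block}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta_alignment <- function(block, path) {
  stopifnot(inherits(block, "alignment_block"))
  ss <- Biostrings::BStringSet(setNames(block$sequences, block$sequence_ids))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

SNP_COLUMNS <- c("position", "ancestral_allele", "derived_allele",
                 "derived_count", "sample_size", "population_label")

#' Read a SNP table
#'
#' Reads a TSV of polarized biallelic sites. Required header columns:
#' \code{position} (0-based), \code{ancestral_allele}, \code{derived_allele},
#' \code{derived_count}, \code{sample_size}, \code{population_label}.
#'
#' @param path TSV path.
#' @return data.frame of validated SNP records.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(SNP_COLUMNS, names(df))
  if (length(missing_cols))
    stop("SNP table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("SNP table ", path, " has a header but no rows")
    return(df[SNP_COLUMNS])
  }
  df <- df[SNP_COLUMNS]
  validate_snp_records(df, source = path)
  df
}

validate_snp_records <- function(df, source = "snp table") {
  bad <- which(df$derived_count > df$sample_size | df$derived_count < 0L)
  if (length(bad))
    stop("validation error in ", source, ": derived_count exceeds ",
         "sample_size (or is negative) at line(s) ",
         paste(bad + 1L, collapse = ", "))  # +1 for header line
  same <- which(df$derived_allele == df$ancestral_allele)
  if (length(same))
    stop("validation error in ", source, ": derived_allele equals ",
         "ancestral_allele at line(s) ", paste(same + 1L, collapse = ", "))
  invisible(df)
}

#' Write a SNP table
#' @param df SNP record data.frame.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_snp_table <- function(df, path) {
  validate_snp_records(df)
  utils::write.table(df[SNP_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read BED6 feature annotations
#'
#' BED is 0-based half-open, matching the package's internal convention,
#' so coordinates pass through unchanged. The BED name field carries the
#' feature id; the score field is re-used for the feature class.
#'
#' @param path BED6 path (columns chrom, start, end, name, class, strand).
#' @return data.frame with columns \code{feature_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{feature_class}.
#' @export
read_features_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("expected BED6 (6 columns), got ", ncol(df))
  out <- data.frame(feature_id = as.character(df[[4L]]),
                    chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]),
                    strand = as.character(df[[6L]]),
                    feature_class = as.character(df[[5L]]),
                    stringsAsFactors = FALSE)
  validate_features(out)
  out
}

FEATURE_CLASSES <- c("precursor", "mature", "star", "flank", "intron",
                     "neutral_4fold")

validate_features <- function(df) {
  if (any(df$start >= df$end))
    stop("feature with start >= end: ",
         paste(df$feature_id[df$start >= df$end], collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(df$feature_class %in% FEATURE_CLASSES))
    stop("unknown feature_class: ",
         paste(setdiff(df$feature_class, FEATURE_CLASSES), collapse = ", "))
  invisible(df)
}

#' Write BED6 feature annotations
#' @param df feature data.frame (see \code{\link{read_features_bed}}).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_features_bed <- function(df, path) {
  validate_features(df)
  utils::write.table(
    data.frame(df$chrom, df$start, df$end, df$feature_id, df$feature_class,
               df$strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert 1-based closed coordinates (GFF-style) to 0-based half-open
#' @param start,end 1-based closed interval.
#' @return list with 0-based half-open \code{start}, \code{end}.
#' @export
gff_to_bed_coords <- function(start, end) list(start = start - 1L, end = end)

#' Convert 0-based half-open coordinates to 1-based closed (GFF-style)
#' @param start,end 0-based half-open interval.
#' @return list with 1-based closed \code{start}, \code{end}.
#' @export
bed_to_gff_coords <- function(start, end) list(start = start + 1L, end = end)

#' Read a dated species tree (chronogram) from newick
#'
#' The tree must be rooted, binary or not, with branch lengths in Myr and
#' ultrametric (all root-to-tip path lengths equal within \code{tol}).
#' Node ages (Myr before present) are computed from the branch lengths.
#'
#' @param path newick file path.
#' @param tol ultrametricity tolerance in Myr.
#' @return object of class \code{species_chronogram}: a list with the
#'   \code{ape::phylo} tree in \code{$tree} and per-node ages in
#'   \code{$node_ages} (indexed by ape node number; tips have age 0).
#' @export
read_newick_chronogram <- function(path, tol = 1e-6) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("format error: could not parse newick in ", path)
  species_chronogram(tree, tol = tol)
}

#' Build a chronogram object from an ape tree
#' @param tree a rooted \code{ape::phylo} with branch lengths in Myr.
#' @param tol ultrametricity tolerance.
#' @return a \code{species_chronogram}.
#' @export
species_chronogram <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape phylo object")
  if (ape::Ntip(tree) < 2L) stop("need >= 2 taxa in the chronogram")
  if (is.null(tree$edge.length)) stop("format error: missing branch lengths")
  if (!ape::is.rooted(tree)) stop("format error: tree must be rooted")
  depths <- ape::node.depth.edgelength(tree)  # root-to-node path lengths
  tip_depths <- depths[seq_len(ape::Ntip(tree))]
  total <- max(tip_depths)
  off <- abs(tip_depths - total) > tol
  if (any(off))
    stop("tree is not ultrametric; offending leaf/leaves: ",
         paste(tree$tip.label[off], collapse = ", "))
  node_ages <- total - depths          # age in Myr before present
  node_ages[seq_len(ape::Ntip(tree))] <- 0
  structure(list(tree = tree, node_ages = node_ages,
                 taxa = tree$tip.label),
            class = "species_chronogram")
}

#' @export
print.species_chronogram <- function(x, ...) {
  cat("species_chronogram:", length(x$taxa), "taxa (",
      paste(x$taxa, collapse = ", "), ")\n")
  internal <- x$node_ages[-seq_along(x$taxa)]
  cat("  internal node ages (Myr):",
      paste(sort(round(internal, 4)), collapse = ", "), "\n")
  invisible(x)
}

#' The default five-species chronogram
#'
#' The dated backbone used for miRNA age grouping: D. melanogaster and
#' D. simulans split 4 Myr ago, the D. pseudoobscura lineage 30 Myr, the
#' D. virilis lineage 60 Myr, and the Culicinae (mosquito) outgroup
#' 250 Myr ago.
#'
#' @return a \code{\link{species_chronogram}} over
#'   \code{mel, sim, pse, vir, culicinae}.
#' @export
default_chronogram <- function() {
  nwk <- "((((mel:4,sim:4):26,pse:30):30,vir:60):190,culicinae:250);"
  species_chronogram(ape::read.tree(text = nwk))
}
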