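#' Confirm a miRNA homolog from small-RNA read evidence
#'
#' A genomic hit counts as an authentic, expressed homolog only when the
#' small-RNA libraries of the species contain at least one read matching
#' the mature arm and at least one matching the star arm.
#'
#' @param mature_read_count,star_read_count nonnegative read counts.
#' @return logical.
#' @export
confirm_homolog <- function(mature_read_count, star_read_count) {
  if (any(c(mature_read_count, star_read_count) < 0))
    stop("read counts must be nonnegative")
  mature_read_count >= 1 & star_read_count >= 1
}

PRESENCE_STATES <- c("present-expressed", "present-silent", "absent")

#' Construct a presence/absence matrix of miRNA homologs
#'
#' @param mat character matrix (rows: miRNA ids, columns: taxa) with cells
#'   in \code{present-expressed}, \code{present-silent}, \code{absent}.
#' @param focal_taxon taxon that must be present-expressed in every row.
#' @return object of class \code{presence_matrix}.
#' @export
presence_matrix <- function(mat, focal_taxon = colnames(mat)[1L]) {
  if (!all(mat %in% PRESENCE_STATES))
    stop("cells must be one of: ", paste(PRESENCE_STATES, collapse = ", "))
  if (!focal_taxon %in% colnames(mat))
    stop("focal taxon '", focal_taxon, "' not a column")
  if (nrow(mat) > 0L && !all(mat[, focal_taxon] == "present-expressed"))
    stop("every miRNA must be present-expressed in the focal taxon")
  structure(list(mat = mat, focal_taxon = focal_taxon),
            class = "presence_matrix")
}

#' Read a presence matrix from TSV
#' @param path TSV with rownames in the first column and taxa as headers.
#' @param focal_taxon see \code{\link{presence_matrix}}.
#' @return a \code{presence_matrix}.
#' @export
read_presence_matrix <- function(path, focal_taxon = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1L,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (is.null(focal_taxon)) focal_taxon <- colnames(m)[1L]
  presence_matrix(m, focal_taxon = focal_taxon)
}

#' Infer the origin branch and age group of one miRNA
#'
#' Maximum-parsimony dating: the gene is assumed to have emerged on the
#' branch above the most recent common ancestor of all taxa bearing an
#' authentic homolog. By default only \code{present-expressed} cells count
#' as presence (the expression cross-check); \code{count_silent = TRUE}
#' relaxes this for sensitivity analysis. Absent taxa inside the MRCA
#' clade are recorded as implied losses.
#'
#' @param presence_row named character vector of presence states (names
#'   are taxa on the tree).
#' @param chronogram a \code{\link{species_chronogram}}.
#' @param boundaries increasing age-interval boundaries in Myr
#'   (default \code{c(4, 30, 60, 250)}, giving groups 0-4, 4-30, 30-60,
#'   60-250, >250).
#' @param count_silent treat \code{present-silent} as present?
#' @return list with \code{origin_taxa}, \code{origin_age} (age of the
#'   MRCA node, Myr), \code{age_group} (label), \code{implied_losses}.
#' @export
infer_origin <- function(presence_row, chronogram,
                         boundaries = c(4, 30, 60, 250),
                         count_silent = FALSE) {
  stopifnot(inherits(chronogram, "species_chronogram"))
  present_states <- if (count_silent)
    c("present-expressed", "present-silent") else "present-expressed"
  taxa <- names(presence_row)[presence_row %in% present_states]
  if (length(taxa) == 0L) stop("empty presence row: no present taxon")
  unknown <- setdiff(taxa, chronogram$taxa)
  if (length(unknown))
    stop("taxa not on the chronogram: ", paste(unknown, collapse = ", "))
  tree <- chronogram$tree
  if (length(taxa) == 1L) {
    node <- match(taxa, tree$tip.label)
  } else {
    node <- ape::getMRCA(tree, taxa)
  }
  origin_age <- chronogram$node_ages[node]
  clade_tips <- if (length(taxa) == 1L) taxa else
    ape::extract.clade(tree, node)$tip.label
  losses <- setdiff(intersect(clade_tips, names(presence_row)), taxa)
  losses <- losses[!presence_row[losses] %in% present_states]
  list(origin_taxa = taxa,
       origin_age = unname(origin_age),
       age_group = age_group_label(origin_age, boundaries),
       implied_losses = losses)
}

#' Age-group label for an origin age
#'
#' Maps the age of the MRCA node (the lower end of the origin branch) to
#' the age interval the branch occupies. An origin age at or above the
#' last boundary falls in the open oldest group.
#'
#' @param age origin age in Myr.
#' @param boundaries increasing boundaries, e.g. \code{c(4, 30, 60, 250)}.
#' @return character label, e.g. \code{"0-4"} or \code{">250"}.
#' @export
age_group_label <- function(age, boundaries = c(4, 30, 60, 250)) {
  stopifnot(all(diff(boundaries) > 0))
  labels <- c(paste(c(0, boundaries[-length(boundaries)]), boundaries,
                    sep = "-"),
              paste0(">", boundaries[length(boundaries)]))
  idx <- findInterval(age, c(0, boundaries), rightmost.closed = FALSE)
  labels[idx]
}

#' Date a whole miRNA repertoire
#'
#' Applies \code{\link{infer_origin}} to every row of a presence matrix
#' and tabulates per-age-group counts, optionally split by an expression
#' class per gene.
#'
#' @param pm a \code{\link{presence_matrix}}.
#' @param chronogram a \code{\link{species_chronogram}}.
#' @param expression_class optional named character vector
#'   (\code{high}/\code{low}) per miRNA id for the marginal table.
#' @inheritParams infer_origin
#' @return list with \code{assignments} (data.frame: mirna_id, origin_age,
#'   age_group, implied_losses) and \code{counts} (table of age_group, or
#'   age_group x expression_class).
#' @export
date_repertoire <- function(pm, chronogram, boundaries = c(4, 30, 60, 250),
                            expression_class = NULL, count_silent = FALSE) {
  stopifnot(inherits(pm, "presence_matrix"))
  ids <- rownames(pm$mat)
  labels <- c(paste(c(0, boundaries[-length(boundaries)]), boundaries,
                    sep = "-"),
              paste0(">", boundaries[length(boundaries)]))
  if (length(ids) == 0L) {
    return(list(assignments = data.frame(mirna_id = character(),
                                         origin_age = numeric(),
                                         age_group = character(),
                                         implied_losses = character()),
                counts = table(factor(character(), levels = labels))))
  }
  rows <- lapply(ids, function(id) {
    o <- infer_origin(pm$mat[id, ], chronogram, boundaries = boundaries,
                      count_silent = count_silent)
    data.frame(mirna_id = id, origin_age = o$origin_age,
               age_group = o$age_group,
               implied_losses = paste(o$implied_losses, collapse = ","),
               stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  ag <- factor(assignments$age_group, levels = labels)
  counts <- if (is.null(expression_class)) table(ag) else
    table(expression_class[assignments$mirna_id], ag)
  list(assignments = assignments, counts = counts)
}
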