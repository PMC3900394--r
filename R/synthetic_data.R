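#' Simulation parameter set
#'
#' Collects the knobs of every generator with defaults matching the study
#' conditions the package emulates: samples of a few dozen haplotypes,
#' loci of a few kb, a birth rate of 3 genes/Myr anchored on the youngest
#' age interval, and a testis-anchored expression gradient with age.
#'
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @param n ingroup sample size (haplotypes).
#' @param L locus length in bp.
#' @param theta population mutation parameter per locus.
#' @param skew_mode \code{"neutral"} or \code{"hitchhiking"}.
#' @param hitchhiking_weight probability mass moved to high-frequency
#'   derived counts (> 0.8 n) under hitchhiking.
#' @param target_k expected substitutions/site for divergence pairs.
#' @param ts_tv_kappa transition/transversion rate ratio.
#' @param alpha_true true proportion of adaptive fixations for MK data.
#' @param fst_true target differentiation for two-population data.
#' @param birth_rate genes/Myr for presence histories.
#' @param loss_rate_per_myr per-lineage loss rate for presence histories.
#' @param tissue_breadth_by_age named list: per age-group label, a list
#'   with \code{libraries} (character) and \code{mean} (expected count).
#' @return list of class \code{sim_params}.
#' @export
sim_params <- function(seed = 1L, n = 40L, L = 2000L, theta = 5,
                       skew_mode = c("neutral", "hitchhiking"),
                       hitchhiking_weight = 0.5,
                       target_k = 0.1, ts_tv_kappa = 2,
                       alpha_true = 0.5, fst_true = 0.1,
                       birth_rate = 3, loss_rate_per_myr = 0.08,
                       tissue_breadth_by_age = default_breadth_config()) {
  skew_mode <- match.arg(skew_mode)
  stopifnot(theta >= 0, target_k >= 0, fst_true >= 0, fst_true <= 1,
            birth_rate >= 0, loss_rate_per_myr >= 0,
            hitchhiking_weight >= 0, hitchhiking_weight <= 1)
  structure(as.list(environment()), class = "sim_params")
}

#' Default tissue-breadth configuration for the expression generator
#'
#' Young genes are restricted to testis and larval libraries at low mean
#' expression; breadth and level grow with age until the oldest genes are
#' abundant in every library.
#'
#' @return named list keyed by age-group label.
#' @export
default_breadth_config <- function() {
  libs <- expression_library_metadata()$library_id
  list(
    `0-4` = list(libraries = c("testis", "larval_brain", "imaginal_disc"),
                 mean = 30),
    `4-30` = list(libraries = c("testis", "larval_brain", "imaginal_disc"),
                  mean = 80),
    `30-60` = list(libraries = c("testis", "ovary", "embryo",
                                 "larval_brain", "imaginal_disc"),
                   mean = 200),
    `60-250` = list(libraries = setdiff(libs, "adult_body"), mean = 400),
    `>250` = list(libraries = libs, mean = 1200))
}

#' Library metadata for the expression generator
#' @return data.frame with \code{library_id}, \code{tissue}, \code{stage}.
#' @export
expression_library_metadata <- function() {
  data.frame(
    library_id = c("testis", "ovary", "embryo", "larval_brain",
                   "imaginal_disc", "adult_head", "adult_body"),
    tissue = c("testis", "ovary", "whole", "brain", "disc", "head", "body"),
    stage = c("adult", "adult", "embryo", "larva", "larva", "adult",
              "adult"),
    stringsAsFactors = FALSE)
}

#' Simulate population haplotypes under the infinite-sites model
#'
#' Draws the number of segregating sites S from Poisson(theta * a_n) and
#' each variant's derived count from the neutral expectation P(i)
#' proportional to 1/i. Under \code{skew_mode = "hitchhiking"}, a fraction
#' of variants is instead placed uniformly on high-frequency counts
#' (> 0.8 n), the footprint of hitchhiking, so that on average theta_H
#' exceeds theta_pi and H < 0. The outgroup row carries the ancestral
#' state at every site.
#'
#' @param params a \code{\link{sim_params}} (uses \code{seed}, \code{n},
#'   \code{L}, \code{theta}, \code{skew_mode}, \code{hitchhiking_weight}).
#' @return list with \code{alignment} (an \code{\link{alignment_block}}
#'   with outgroup \code{"outgroup"}) and \code{truth} (list with
#'   \code{theta}, \code{S}, \code{derived_counts}, \code{positions}).
#' @export
sim_haplotypes <- function(params) {
  set.seed(params$seed)
  n <- params$n; L <- params$L
  a_n <- sum(1 / seq_len(n - 1))
  S <- stats::rpois(1L, params$theta * a_n)
  if (S > L) {
    warning("S > L; truncating to L segregating sites")
    S <- L
  }
  neutral_w <- 1 / seq_len(n - 1)
  counts <- integer(S)
  if (S > 0) {
    hi <- which(seq_len(n - 1) > 0.8 * n)
    for (s in seq_len(S)) {
      if (params$skew_mode == "hitchhiking" &&
          stats::runif(1) < params$hitchhiking_weight && length(hi)) {
        counts[s] <- sample(hi, 1L)
      } else {
        counts[s] <- sample.int(n - 1L, 1L, prob = neutral_w)
      }
    }
  }
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, L, replace = TRUE)
  m <- matrix(rep(anc, each = n), nrow = n)
  pos <- if (S > 0) sample.int(L, S) else integer(0)
  for (s in seq_len(S)) {
    derived <- sample(setdiff(bases, anc[pos[s]]), 1L)
    carriers <- sample.int(n, counts[s])
    m[carriers, pos[s]] <- derived
  }
  seqs <- c(apply(m, 1L, paste, collapse = ""), paste(anc, collapse = ""))
  names(seqs) <- c(paste0("hap", seq_len(n)), "outgroup")
  list(alignment = alignment_block(seqs, outgroup_id = "outgroup"),
       truth = list(theta = params$theta, S = S, derived_counts = counts,
                    positions = pos - 1L))
}

#' Simulate a diverged sequence pair at a target K2P distance
#'
#' Each site differs by a transition with probability P and a transversion
#' with probability Q, where (P, Q) are the Kimura 2-parameter
#' substitution probabilities at total expected distance \code{target_k}
#' and rate ratio \code{ts_tv_kappa}.
#'
#' @param params a \code{\link{sim_params}} (uses \code{seed}, \code{L},
#'   \code{target_k}, \code{ts_tv_kappa}).
#' @return list with \code{seq_a}, \code{seq_b} and \code{truth}
#'   (list with \code{target_k}, \code{P_expected}, \code{Q_expected}).
#' @export
sim_divergence_pair <- function(params) {
  set.seed(params$seed)
  L <- params$L; d <- params$target_k; kappa <- params$ts_tv_kappa
  b <- d / (kappa + 2)               # transversion branch-rate x time
  a <- kappa * b                     # transition branch-rate x time
  P <- 0.25 + 0.25 * exp(-4 * b) - 0.5 * exp(-2 * (a + b))
  Q <- 0.5 - 0.5 * exp(-4 * b)
  bases <- c("A", "C", "G", "T")
  transit <- c(A = "G", G = "A", C = "T", T = "C")
  transver <- list(A = c("C", "T"), G = c("C", "T"),
                   C = c("A", "G"), T = c("A", "G"))
  sa <- sample(bases, L, replace = TRUE)
  u <- stats::runif(L)
  sb <- sa
  is_ts <- u < P
  is_tv <- u >= P & u < P + Q
  sb[is_ts] <- transit[sa[is_ts]]
  if (any(is_tv))
    sb[is_tv] <- vapply(sa[is_tv], function(x) sample(transver[[x]], 1L), "")
  list(seq_a = paste(sa, collapse = ""), seq_b = paste(sb, collapse = ""),
       truth = list(target_k = d, P_expected = P, Q_expected = Q))
}

#' Simulate an aligned coding-sequence pair at a target K2P distance
#'
#' Codon-aware variant of \code{\link{sim_divergence_pair}}: codons are
#' drawn from the 61 sense codons and substituted site-wise at the K2P
#' probabilities; any codon that would become a stop in either sequence
#' is redrawn, so the pair is a valid ungapped CDS alignment.
#'
#' @param params a \code{\link{sim_params}} (uses \code{seed},
#'   \code{target_k}, \code{ts_tv_kappa}).
#' @param n_codons number of codons.
#' @return list with \code{cds_a}, \code{cds_b}, \code{truth}.
#' @export
sim_cds_pair <- function(params, n_codons = 500L) {
  set.seed(params$seed)
  d <- params$target_k; kappa <- params$ts_tv_kappa
  b <- d / (kappa + 2); a <- kappa * b
  P <- 0.25 + 0.25 * exp(-4 * b) - 0.5 * exp(-2 * (a + b))
  Q <- 0.5 - 0.5 * exp(-4 * b)
  sense <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
  bases <- c("A", "C", "G", "T")
  transit <- c(A = "G", G = "A", C = "T", T = "C")
  transver <- list(A = c("C", "T"), G = c("C", "T"),
                   C = c("A", "G"), T = c("A", "G"))
  mutate_codon <- function(codon) {
    ch <- strsplit(codon, "", fixed = TRUE)[[1L]]
    for (i in 1:3) {
      u <- stats::runif(1)
      if (u < P) ch[i] <- transit[[ch[i]]]
      else if (u < P + Q) ch[i] <- sample(transver[[ch[i]]], 1L)
    }
    paste(ch, collapse = "")
  }
  ca <- character(n_codons); cb <- character(n_codons)
  for (k in seq_len(n_codons)) {
    repeat {
      x <- sample(sense, 1L)
      y <- mutate_codon(x)
      if (GENETIC_CODE_TABLE[[y]] != "*") { ca[k] <- x; cb[k] <- y; break }
    }
  }
  list(cds_a = paste(ca, collapse = ""), cds_b = paste(cb, collapse = ""),
       truth = list(target_k = d))
}

#' Simulate an MK contingency table at a known true alpha
#'
#' Neutral-class counts are Poisson around per-site rates lambda_P
#' (polymorphism) and lambda_D (divergence) over \code{L_neut} sites; the
#' test class scales both by \code{c_sel} over \code{L_sel} sites, with
#' the divergence rate inflated by 1/(1 - alpha_true) to plant the
#' adaptive excess.
#'
#' @param params a \code{\link{sim_params}} (uses \code{seed},
#'   \code{alpha_true}).
#' @param L_neut,L_sel neutral and test-class site counts.
#' @param lambda_p,lambda_d per-site polymorphism and divergence rates.
#' @param c_sel constraint scaling of the test class.
#' @return list with \code{table} (an \code{\link{mk_table}}) and
#'   \code{truth} (\code{alpha_true}).
#' @export
sim_mk <- function(params, L_neut = 1e5, L_sel = 1e3,
                   lambda_p = 0.05, lambda_d = 0.1, c_sel = 1) {
  set.seed(params$seed)
  a <- params$alpha_true
  stopifnot(a < 1)
  p_neut <- stats::rpois(1L, lambda_p * L_neut)
  d_neut <- stats::rpois(1L, lambda_d * L_neut)
  p_sel <- stats::rpois(1L, c_sel * lambda_p * L_sel)
  d_sel <- stats::rpois(1L, c_sel * lambda_d * L_sel / (1 - a))
  list(table = mk_table(d_sel, p_sel, d_neut, p_neut,
                        labels = c("selected", "neutral")),
       truth = list(alpha_true = a))
}

#' Simulate a presence/absence history on a chronogram
#'
#' Gene births are placed uniformly in time on the lineage leading to the
#' focal taxon (constant birth rate per Myr); each gene then descends
#' through the tree, with loss events on every branch below the origin at
#' an exponential rate per Myr (a loss silences the whole subtree).
#' Genes lost in the focal taxon are unobservable and are discarded, so
#' every emitted row is present-expressed in the focal taxon.
#'
#' @param params a \code{\link{sim_params}} (uses \code{seed},
#'   \code{birth_rate}, \code{loss_rate_per_myr}).
#' @param chronogram a \code{\link{species_chronogram}}.
#' @param focal_taxon tip whose repertoire is observed (default
#'   \code{"mel"}).
#' @return list with \code{presence} (a \code{\link{presence_matrix}}),
#'   \code{truth} (data.frame: mirna_id, true_origin_age, true_age_group)
#'   and \code{n_born_total}.
#' @export
sim_presence <- function(params, chronogram = default_chronogram(),
                         focal_taxon = "mel") {
  set.seed(params$seed)
  tree <- chronogram$tree
  ages <- chronogram$node_ages
  root_age <- max(ages)
  n_born <- stats::rpois(1L, params$birth_rate * root_age)
  taxa <- chronogram$taxa
  labels <- c(paste(c(0, 4, 30, 60), c(4, 30, 60, 250), sep = "-"), ">250")
  rows <- list(); truths <- list()
  if (n_born > 0) for (g in seq_len(n_born)) {
    t_origin <- stats::runif(1L, 0, root_age)
    present <- descend_with_loss(tree, ages, t_origin, focal_taxon,
                                 params$loss_rate_per_myr)
    if (!present[[focal_taxon]]) next
    row <- ifelse(unlist(present[taxa]), "present-expressed", "absent")
    names(row) <- taxa
    id <- sprintf("mir%04d", g)
    rows[[id]] <- row
    truths[[id]] <- data.frame(
      mirna_id = id, true_origin_age = t_origin,
      true_age_group = age_group_label(
        origin_age_on_trunk(tree, ages, t_origin, focal_taxon)),
      stringsAsFactors = FALSE)
  }
  mat <- do.call(rbind, rows)
  if (is.null(mat))
    mat <- matrix(character(), ncol = length(taxa), nrow = 0L,
                  dimnames = list(NULL, taxa))
  list(presence = presence_matrix(mat, focal_taxon = focal_taxon),
       truth = if (length(truths)) do.call(rbind, truths) else
         data.frame(mirna_id = character(), true_origin_age = numeric(),
                    true_age_group = character()),
       n_born_total = n_born)
}

## Path of node numbers from the root to a tip.
root_to_tip_path <- function(tree, tip_label) {
  tip <- match(tip_label, tree$tip.label)
  root <- ape::Ntip(tree) + 1L
  path <- tip
  node <- tip
  while (node != root) {
    node <- tree$edge[tree$edge[, 2L] == node, 1L]
    path <- c(node, path)
  }
  path
}

## Age of the node at the lower end of the trunk branch containing an
## origin time t (Myr before present): the most recent trunk node older
## than... i.e. the first node on the root->focal path younger than t.
origin_age_on_trunk <- function(tree, ages, t_origin, focal_taxon) {
  path <- root_to_tip_path(tree, focal_taxon)
  path_ages <- ages[path]
  max(path_ages[path_ages < t_origin], 0)
}

## Simulate presence at every tip for a gene originating at age t on the
## focal lineage: walk the tree from the origin point, drawing loss
## events on each branch segment at rate mu per Myr.
descend_with_loss <- function(tree, ages, t_origin, focal_taxon, mu) {
  path <- root_to_tip_path(tree, focal_taxon)
  ntip <- ape::Ntip(tree)
  present <- setNames(vector("list", ntip), tree$tip.label)
  ## start node: the deepest node on the focal path younger than t_origin
  younger <- path[ages[path] < t_origin]
  start <- younger[1L]
  survive_to <- function(node, age_from) {
    ## loss on the segment from age_from down to this node's age
    seg <- age_from - ages[node]
    if (stats::runif(1) < 1 - exp(-mu * seg)) return(mark_subtree(node, FALSE))
    if (node <= ntip) {
      present[[tree$tip.label[node]]] <<- TRUE
      return(invisible())
    }
    children <- tree$edge[tree$edge[, 1L] == node, 2L]
    for (ch in children) survive_to(ch, ages[node])
  }
  mark_subtree <- function(node, value) {
    if (node <= ntip) {
      present[[tree$tip.label[node]]] <<- value
      return(invisible())
    }
    for (ch in tree$edge[tree$edge[, 1L] == node, 2L])
      mark_subtree(ch, value)
  }
  ## taxa outside the origin clade never carried the gene
  for (tip in seq_len(ntip)) present[[tree$tip.label[tip]]] <- FALSE
  survive_to(start, t_origin)
  present
}

#' Simulate allele counts for two populations at a target Fst
#'
#' Balding-Nichols model: per SNP an ancestral frequency p is drawn
#' uniformly on (0.1, 0.9) and each population's frequency from
#' Beta(p (1-F)/F, (1-p)(1-F)/F), which has mean p and variance
#' p(1-p) F. Counts are binomial draws of \code{n_per_pop} haploid
#' alleles.
#'
#' @param params a \code{\link{sim_params}} (uses \code{seed},
#'   \code{fst_true}).
#' @param n_snps number of SNPs.
#' @param n_per_pop haplotypes sampled per population.
#' @return list with \code{pop1}, \code{pop2} (each a data.frame with
#'   \code{derived}, \code{n}) and \code{truth} (\code{fst_true}).
#' @export
sim_fst <- function(params, n_snps = 1e4, n_per_pop = 20L) {
  set.seed(params$seed)
  F <- params$fst_true
  p <- stats::runif(n_snps, 0.1, 0.9)
  draw <- function(p) {
    if (F == 0) return(p)
    if (F == 1) return(as.numeric(stats::runif(length(p)) < p))
    stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  q1 <- draw(p); q2 <- draw(p)
  list(pop1 = data.frame(derived = stats::rbinom(n_snps, n_per_pop, q1),
                         n = n_per_pop),
       pop2 = data.frame(derived = stats::rbinom(n_snps, n_per_pop, q2),
                         n = n_per_pop),
       truth = list(fst_true = F))
}

#' Simulate an age-structured expression count matrix
#'
#' Each gene belongs to an age group; its counts are negative-binomial
#' in the libraries its group's breadth configuration allows and zero
#' elsewhere, with the group's mean expression. This reproduces the
#' qualitative gradient the package's expression analyses expect: young
#' genes narrow (testis/larval) and low, old genes broad and high.
#'
#' @param params a \code{\link{sim_params}} (uses \code{seed},
#'   \code{tissue_breadth_by_age}).
#' @param genes_per_group genes simulated per age group.
#' @param nb_size negative-binomial size (dispersion) parameter.
#' @return list with \code{raw_counts} (matrix), \code{metadata}
#'   (library data.frame) and \code{truth} (named age-group vector per
#'   gene).
#' @export
sim_expression <- function(params, genes_per_group = 10L, nb_size = 5) {
  set.seed(params$seed)
  cfg <- params$tissue_breadth_by_age
  meta <- expression_library_metadata()
  libs <- meta$library_id
  groups <- names(cfg)
  ids <- character(0); truth <- character(0)
  rows <- list()
  for (g in groups) {
    for (k in seq_len(genes_per_group)) {
      id <- sprintf("%s_g%02d", gsub("[^0-9a-zA-Z]", "_", g), k)
      counts <- setNames(numeric(length(libs)), libs)
      on <- cfg[[g]]$libraries
      counts[on] <- stats::rnbinom(length(on), size = nb_size,
                                   mu = cfg[[g]]$mean)
      rows[[id]] <- counts
      ids <- c(ids, id); truth <- c(truth, setNames(g, id))
    }
  }
  raw <- do.call(rbind, rows)
  list(raw_counts = raw, metadata = meta, truth = truth)
}
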