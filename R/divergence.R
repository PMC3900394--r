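#' Kimura 2-parameter distance between two aligned sequences
#'
#' Columns containing a gap or \code{N} in either sequence are masked.
#' Transitions (A<->G, C<->T) and transversions are counted as proportions
#' \eqn{\hat P} and \eqn{\hat Q} of the compared sites, and
#' \deqn{K = -\tfrac12 \ln(1 - 2\hat P - \hat Q) - \tfrac14 \ln(1 - 2\hat Q).}
#'
#' @param seq_a,seq_b equal-length aligned nucleotide strings.
#' @return list with \code{k} (substitutions/site), \code{P} (transition
#'   proportion), \code{Q} (transversion proportion), \code{sites}
#'   (compared sites after masking).
#' @export
k2p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1L]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1L]]
  if (length(a) != length(b))
    stop("sequences must be aligned to equal length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0L) stop("no comparable sites after masking gaps/N")
  diff <- a != b
  purine <- c("A", "G")
  transition <- diff & ((a %in% purine) == (b %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  k2p_from_pq(P, Q, sites = n)
}

#' Kimura 2-parameter distance from transition/transversion proportions
#'
#' @param P transition proportion.
#' @param Q transversion proportion.
#' @param sites number of compared sites (carried through for reporting).
#' @return list as in \code{\link{k2p_distance}}.
#' @export
k2p_from_pq <- function(P, Q, sites = NA_integer_) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0)
    stop("K2P saturation: 1 - 2P - Q = ", signif(w1, 4), " <= 0")
  if (w2 <= 0)
    stop("K2P saturation: 1 - 2Q = ", signif(w2, 4), " <= 0")
  list(k = -0.5 * log(w1) - 0.25 * log(w2), P = P, Q = Q, sites = sites)
}

GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

translate_codon <- function(codon) GENETIC_CODE_TABLE[[codon]]

## Synonymous site count of one codon: at each position, the fraction of
## the three single-nucleotide changes that preserve the amino acid.
## Changes creating a stop codon count as nonsynonymous.
codon_syn_sites <- function(codon) {
  aa <- translate_codon(codon)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "", fixed = TRUE)[[1L]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, chars[pos])) {
      mut <- chars
      mut[pos] <- b
      if (translate_codon(paste(mut, collapse = "")) == aa) s <- s + 1 / 3
    }
  }
  s
}

## All orderings of the differing positions between two codons; each
## pathway is walked one substitution at a time, tallying synonymous and
## nonsynonymous steps and the number of stop-codon intermediates/ends.
codon_pathways <- function(codon_a, codon_b) {
  ca <- strsplit(codon_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(codon_b, "", fixed = TRUE)[[1L]]
  pos <- which(ca != cb)
  if (length(pos) == 0L)
    return(data.frame(syn = 0, nonsyn = 0, stops = 0L))
  perms <- permutations_of(pos)
  out <- lapply(perms, function(ord) {
    cur <- ca
    syn <- 0; nonsyn <- 0; stops <- 0L
    for (p in ord) {
      nxt <- cur
      nxt[p] <- cb[p]
      aa1 <- translate_codon(paste(cur, collapse = ""))
      aa2 <- translate_codon(paste(nxt, collapse = ""))
      if (aa2 == "*" || aa1 == "*") stops <- stops + 1L
      if (aa1 == aa2) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    data.frame(syn = syn, nonsyn = nonsyn, stops = stops)
  })
  do.call(rbind, out)
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutations_of(x[-i]))
      out <- c(out, list(c(x[i], rest)))
  out
}

#' Nei-Gojobori synonymous divergence (NG86 with Jukes-Cantor correction)
#'
#' Counts synonymous sites per codon (averaged over the two sequences) and
#' synonymous differences by equal-weight averaging over all substitution
#' pathways between differing codons. Pathways passing through a stop
#' codon are excluded; if every pathway hits a stop, the pathways with the
#' fewest stop intermediates are used. The proportion
#' \eqn{p_S = S_d / S} is corrected as
#' \deqn{K_S = -\tfrac34 \ln(1 - \tfrac43 p_S).}
#'
#' @param cds_a,cds_b aligned coding sequences, lengths divisible by 3,
#'   no internal stop codons. Codons containing a gap or \code{N} in
#'   either sequence are dropped entirely.
#' @return list with \code{ks}, \code{syn_sites} (S), \code{syn_diffs}
#'   (S_d), \code{nonsyn_sites}, \code{nonsyn_diffs}, \code{codons}
#'   (codons compared).
#' @export
nei_gojobori_ks <- function(cds_a, cds_b) {
  a <- toupper(cds_a); b <- toupper(cds_b)
  if (nchar(a) != nchar(b)) stop("CDS pair must be aligned to equal length")
  if (nchar(a) %% 3L != 0L) stop("CDS length must be divisible by 3")
  n_codons <- nchar(a) %/% 3L
  S <- 0; Sd <- 0; N <- 0; Nd <- 0; used <- 0L
  for (k in seq_len(n_codons)) {
    ca <- substr(a, 3L * k - 2L, 3L * k)
    cb <- substr(b, 3L * k - 2L, 3L * k)
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    aa_a <- translate_codon(ca); aa_b <- translate_codon(cb)
    if (k < n_codons && (aa_a == "*" || aa_b == "*"))
      stop("internal stop codon at codon ", k)
    if (aa_a == "*" || aa_b == "*") next   # terminal stop: not a site
    used <- used + 1L
    s_k <- (codon_syn_sites(ca) + codon_syn_sites(cb)) / 2
    S <- S + s_k
    N <- N + (3 - s_k)
    if (ca != cb) {
      paths <- codon_pathways(ca, cb)
      keep <- paths[paths$stops == min(paths$stops), , drop = FALSE]
      Sd <- Sd + mean(keep$syn)
      Nd <- Nd + mean(keep$nonsyn)
    }
  }
  if (used == 0L) stop("no comparable codons after masking")
  p_s <- if (S > 0) Sd / S else 0
  if (p_s >= 3 / 4)
    stop("synonymous saturation: p_S = ", signif(p_s, 4), " >= 3/4")
  ks <- if (p_s == 0) 0 else -(3 / 4) * log(1 - (4 / 3) * p_s)
  list(ks = ks, syn_sites = S, syn_diffs = Sd,
       nonsyn_sites = N, nonsyn_diffs = Nd, codons = used)
}

#' Precursor conservation score K_miR / K_S
#'
#' Measures how fast a miRNA precursor evolves relative to the neutral
#' synonymous rate: \code{k_mir} is the Kimura 2-parameter distance over
#' the precursor alignment and \code{k_s} the Nei-Gojobori synonymous
#' divergence over one or more control coding alignments (concatenated).
#' Values below 0.5 are taken as evidence of selective constraint
#' (conservative evolution).
#'
#' @param precursor_a,precursor_b aligned precursor sequences of the two
#'   species.
#' @param cds_pairs list of \code{c(a, b)} aligned CDS pairs used for the
#'   synonymous control (concatenated before counting).
#' @return object of class \code{divergence_result}: list with
#'   \code{k_mir}, \code{k_s}, \code{ratio} and the underlying
#'   \code{k2p}/\code{ng86} component lists.
#' @export
kmir_ks <- function(precursor_a, precursor_b, cds_pairs) {
  k2p <- k2p_distance(precursor_a, precursor_b)
  if (!length(cds_pairs)) stop("need at least one CDS control pair")
  cds_a <- paste(vapply(cds_pairs, `[[`, "", 1L), collapse = "")
  cds_b <- paste(vapply(cds_pairs, `[[`, "", 2L), collapse = "")
  ng <- nei_gojobori_ks(cds_a, cds_b)
  if (ng$ks == 0)
    stop("undefined-ratio error: K_S = 0 for the CDS control")
  structure(list(k_mir = k2p$k, k_s = ng$ks, ratio = k2p$k / ng$ks,
                 k2p = k2p, ng86 = ng),
            class = "divergence_result")
}

#' @export
print.divergence_result <- function(x, ...) {
  cat(sprintf("K_miR = %.4f  K_S = %.4f  K_miR/K_S = %.3f\n",
              x$k_mir, x$k_s, x$ratio))
  invisible(x)
}
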