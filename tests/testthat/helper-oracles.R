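# Independent reference implementations used to cross-check the package.
# Each oracle is written from the statistic's definition, not from the
# package code paths it checks.

# Average pairwise difference count across all haplotype pairs of an
# alignment (ingroup rows only), counting columns where both bases are
# plain nucleotides.
oracle_pairwise_pi <- function(block) {
  ing <- setdiff(block$sequence_ids, block$outgroup_id)
  rows <- lapply(block$sequences[match(ing, block$sequence_ids)],
                 function(s) strsplit(s, "", fixed = TRUE)[[1]])
  n <- length(rows)
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- rows[[i]]; b <- rows[[j]]
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    total <- total + sum(a[ok] != b[ok])
  }
  total / choose(n, 2)
}

# Upper-tail Fisher p by explicit summation of the hypergeometric pmf
# over all tables at least as divergence-enriched as observed.
oracle_fisher_upper <- function(d_sel, p_sel, d_neut, p_neut) {
  D <- d_sel + d_neut; P <- p_sel + p_neut; k <- d_sel + p_sel
  xs <- max(0, k - P):min(k, D)
  sum(vapply(xs[xs >= d_sel],
             function(x) stats::dhyper(x, D, P, k), numeric(1)))
}

# Textbook step-up Benjamini-Hochberg, written sort-first.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Weir & Cockerham (1984) variance components specialised to haploid
# samples, written from the ANOVA mean squares for r = 2 populations.
oracle_wc_fst_site <- function(d1, n1, d2, n2) {
  p1 <- d1 / n1; p2 <- d2 / n2
  nT <- n1 + n2
  pbar <- (d1 + d2) / nT
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2   # r - 1 = 1
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (nT - 2)
  nc <- nT - (n1^2 + n2^2) / nT
  (msp - msg) / (msp + (nc - 1) * msg)
}

# NG86 synonymous/nonsynonymous difference counts for one codon pair by
# graph-walk path enumeration over intermediate codons, using the
# Biostrings genetic code as an independent code source.
oracle_ng86_codon <- function(ca, cb) {
  code <- Biostrings::GENETIC_CODE
  aa <- function(x) unname(code[x])
  walk <- function(cur, target) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(pos))
      return(data.frame(syn = 0, nonsyn = 0, stops = 0))
    res <- list()
    for (p in pos) {
      ch <- strsplit(cur, "")[[1]]
      ch[p] <- strsplit(target, "")[[1]][p]
      nxt <- paste(ch, collapse = "")
      step_stop <- as.integer(aa(nxt) == "*")
      step_syn <- as.integer(aa(cur) == aa(nxt))
      sub <- walk(nxt, target)
      sub$syn <- sub$syn + step_syn
      sub$nonsyn <- sub$nonsyn + (1 - step_syn)
      sub$stops <- sub$stops + step_stop
      res[[length(res) + 1]] <- sub
    }
    do.call(rbind, res)
  }
  paths <- walk(ca, cb)
  keep <- paths[paths$stops == min(paths$stops), , drop = FALSE]
  c(syn = mean(keep$syn), nonsyn = mean(keep$nonsyn))
}

# Synonymous site count of a codon from the Biostrings genetic code.
oracle_syn_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
    mut <- ch; mut[p] <- b
    if (unname(code[paste(mut, collapse = "")]) == unname(code[codon]))
      s <- s + 1 / 3
  }
  s
}

# Parsimony origin age on the default 5-taxon chronogram from the split
# times with the focal species, by set logic (no tree library).
oracle_origin_age <- function(present_taxa) {
  splits <- c(mel = 0, sim = 4, pse = 30, vir = 60, culicinae = 250)
  max(splits[present_taxa])
}

random_sense_codon <- function() {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  sample(sense, 1)
}
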