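# mirfate

Evolutionary analysis of microRNA gene birth, adaptation and death.

New miRNA genes emerge constantly — a 70–90 nt hairpin is easy to form —
but most disappear again within tens of millions of years. `mirfate` is
an R package for the population-genetic and phylogenetic accounting that
tracks such genes through their life cycle, aimed at molecular
evolutionists working with *Drosophila*-style data: population alignments
with an outgroup, polarized SNP tables, presence/absence matrices of
homologs across species, and small-RNA count tables.

## What it computes

- **Origin dating.** Maximum-parsimony assignment of each gene to the
  branch above the MRCA of homolog-bearing species on a dated tree
  (default splits: 4, 30, 60, 250 Myr), binned into five age groups.
  Homologs require small-RNA evidence on both the mature and the star
  arm.
- **Selection tests.** The McDonald–Kreitman framework on a test class
  versus a neutral class: one-tailed Fisher's exact test (exact up to
  genome-scale neutral counts), derived-allele-frequency filtering
  (DAF > 5% on > 30 samples), Benjamini–Hochberg adjustment, and the
  proportion of adaptive fixations
  `alpha = 1 − (P_sel/D_sel)·(D_neut/P_neut)`.
- **SFS statistics and scans.** Watterson's θ_W, nucleotide diversity
  θ_π, Fay & Wu's θ_H and H = θ_π − θ_H from outgroup-polarized
  alignments, with 100 bp / 25 bp sliding-window scans (negative H flags
  hitchhiking).
- **Population differentiation.** Weir–Cockerham Fst specialized to
  haploid line samples, per site and as a regional ratio-of-sums, with a
  rank-sum comparison of focal versus background SNPs.
- **Conservation scoring.** Kimura 2-parameter precursor divergence
  (K_miR) against Nei–Gojobori synonymous divergence (K_S);
  K_miR/K_S < 0.5 marks conservative evolution.
- **Fate classification.** adaptive (significant MK excess) →
  conservative (low K_miR/K_S) → transitional, in that screening order.
- **Birth–death ledger.** Constant-birth-rate turnover accounting:
  newborns = rate × interval, deaths = newborns − survivors, per age
  interval.
- **Expression analysis.** RPM normalization with fractional multiread
  splitting, the strict 200 RPM high/low rule, expression breadth, and
  hierarchical clustering of log2 profiles.
- **Synthetic data.** Generators for every input above with planted,
  machine-readable truth (infinite-sites haplotypes with optional
  hitchhiking skew, K2P divergence pairs, MK tables at known alpha,
  gain/loss presence histories, Balding–Nichols Fst data, age-graded
  expression tables), so the whole pipeline runs offline.

## Worked example

Pooled MK test for the youngest precursor class against genome-wide
4-fold degenerate sites, and the turnover ledger anchored on 12 genes in
the last 4 Myr:

```r
library(mirfate)

tab <- mk_table(86, 4, 378361, 83996,
                labels = c("precursor 0-4 Myr", "4-fold sites"))
mk_test(tab)
#> MK test (one-sided-excess-divergence): D/P[test] = 21.500, D/P[neutral] = 4.505, p = 0.000113
mk_alpha(tab, as_percent = TRUE)
#> [1] 79.04878

led <- build_ledger(estimate_birth_rate(12, 4),
  data.frame(start = c(0, 4, 30, 60), end = c(4, 30, 60, 250),
             survivors = c(12, 10, 9, 34)))
led
#> birth-death ledger (rate = 3 genes/Myr)
#>  start end survivors newborns deaths death_fraction survival_fraction
#>      0   4        12       12      0             0%            100.0%
#>      4  30        10       78     68            87%             12.8%
#>     30  60         9       90     81            90%             10.0%
#>     60 250        34      570    536            94%              6.0%
```

Read: the test class fixes divergence 4.8× faster than neutral sites
relative to its polymorphism (p ≈ 1.1e-4), with ~79% of its fixations
estimated adaptive; under a constant birth rate of 3 genes/Myr, 87% of
genes born 4–30 Myr ago are gone (68 of 78) and only 6.0% born before
60 Myr survive (34 of 570).

An end-to-end run on synthetic inputs:

```r
res <- run_pipeline(run_config(seed = 1, outdir = "demo"))
```

writes age assignments, an RPM matrix with expression classes, a sliding
θ_H track, the MK and fate reports and the ledger (TSV/JSON) into
`demo/`, byte-identically for a fixed seed.

## Documentation

The methods vignette (`vignettes/mirna-evolution-methods.Rmd`) documents
the models, the parameter defaults and why they hold, the design of the
synthetic generators and what passing tests do and do not establish, and
numerical edge-case policies.
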