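---
title: "Methods: dating, selection testing and turnover modelling of miRNA genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dating, selection testing and turnover modelling of miRNA genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirfate)
```

## The problem

New microRNA genes arise easily — a hairpin of 70–90 nt is not hard to
form — and most of them vanish again. `mirfate` implements the
evolutionary accounting needed to follow such genes through their life
cycle in a *Drosophila*-style setting: dating each gene's origin on a
species phylogeny, asking whether its early sequence evolution was driven
by positive selection, scoring long-term conservation against the neutral
synonymous rate, classifying each gene's current evolutionary mode, and
tallying births and deaths per age interval under a constant birth rate.
Every stage can be fed either real inputs (alignments, SNP tables,
presence/absence matrices, count tables) or data from the package's own
generators, so the full pipeline runs and is testable with no external
downloads.

## Dating gene origins

Homologs are accepted only with expression evidence: at least one
small-RNA read on the mature arm *and* one on the star arm
(`confirm_homolog()`). Given a presence/absence matrix over the five
lineages (mel, sim, pse, vir, Culicinae) and the dated backbone tree
(`default_chronogram()`: splits at 4, 30, 60 and 250 Myr), a gene is
assumed to have emerged on the branch above the most recent common
ancestor of the taxa bearing authentic homologs (`infer_origin()`).
Origins are binned into the five age groups 0–4, 4–30, 30–60, 60–250 and
>250 Myr. Losses inside the MRCA clade are recorded but do not move the
origin: presence-MRCA dating is exact when no informative clade has lost
the gene entirely, and otherwise can only under-estimate the age — a
property the test suite asserts by simulation. Genomic homologs without
expression (`present-silent`) count as absent by default, because the
expression cross-check is part of the homolog definition; a
`count_silent` flag exists for sensitivity analysis.

## Population-genetic tests of adaptive evolution

**SFS statistics.** Alignments are polarized against a designated
outgroup row (`polarize()`): biallelic ingroup sites where the outgroup
carries one of the two alleles yield derived-allele counts; sites where
the outgroup matches neither allele, tri-allelic sites, and any column
touching a gap or `N` are excluded from both the segregating sites and
the callable length — polarizing such sites would more often mislead than
inform, and the callable mask keeps per-site scaling honest. From the
unfolded spectrum the package computes

$$\theta_\pi = \sum_i \frac{2\,i\,(n-i)\,S_i}{n(n-1)}, \qquad
  \theta_W = \frac{S}{\sum_{k=1}^{n-1} 1/k}, \qquad
  \theta_H = \sum_i \frac{2\,S_i\,i^2}{n(n-1)},$$

with $H = \theta_\pi - \theta_H$. All three estimate the same population
mutation parameter under neutrality; an excess of high-frequency derived
alleles — the hitchhiking footprint of a recent sweep — inflates
$\theta_H$ and drives $H$ negative. Sliding scans (`sliding_scan()`) use
100 bp windows with a 25 bp step, anchored at the region start; trailing
partial windows are dropped by default (edge handling is a convention,
and windows of unequal size would not be comparable). $\theta_H$ is
reported unnormalized; variance normalization is deliberately out of
scope.

**MK framework.** `mk_test()` contrasts fixed divergence ($D$) with
polymorphism ($P$) in a test class (a precursor, a pooled age class)
against a neutral class (flanking sites or genome-wide 4-fold degenerate
sites) by Fisher's exact test, one-tailed toward excess divergence in the
test class. The implementation evaluates the hypergeometric tail on the
log scale, so neutral classes with counts in the $10^5$–$10^6$ range stay
exact. Polymorphisms can first be filtered with `daf_filter()`: only SNPs
seen on strictly more than 30 haplotypes with derived allele frequency
strictly above 5% are kept, which strips low-frequency (likely slightly
deleterious) variants that would otherwise dilute the test. The
proportion of adaptive fixations is the ratio estimator

$$\alpha = 1 - \frac{P_{sel}}{D_{sel}}\cdot\frac{D_{neut}}{P_{neut}},$$

which attains its upper bound of 1 when the test class carries no
filtered polymorphism. Multiple tests are adjusted with
Benjamini–Hochberg (`bh_adjust()`).

**Population differentiation.** `weir_fst()` implements the
Weir–Cockerham variance-component estimator specialized to haploid
samples — sequenced inbred lines contribute alleles, not genotypes, so
the heterozygosity terms of the diploid formulation drop out. Per-site
values and a ratio-of-sums regional estimate are returned; small negative
values under no differentiation are expected behaviour of this estimator,
not an error. `fst_rank_comparison()` ranks focal per-SNP values against
a background with a one-sided Mann–Whitney test, exact for combined
samples of at most 20 without ties.

## Divergence and conservation

Precursor divergence $K_{miR}$ is the Kimura 2-parameter distance
(`k2p_distance()`), computed on the annotated precursor span only (the
50 bp flanks enter the MK screen, not the conservation score). The
synonymous control $K_S$ uses the Nei–Gojobori method
(`nei_gojobori_ks()`): per-codon synonymous site counts averaged over the
two sequences, differences resolved by equal-weight averaging over all
substitution pathways, and a Jukes–Cantor correction of $p_S$. Pathways
through stop codons are excluded; in the degenerate case where every
ordering hits a stop, the orderings with the fewest stop intermediates
are used, so the count is always defined. Codons touching a gap or `N`
are dropped whole. The conservation score is the ratio
$K_{miR}/K_S$ (`kmir_ks()`); values below 0.5 are read as selective
constraint.

## Fate classification and the birth–death ledger

`classify_fate()` applies the screening order: **adaptive** if the
BH-adjusted MK p-value is below 0.05 with the divergence excess in the
precursor (a two-stage screen, `adaptive_screen()`, additionally
re-validates flank-inclusive hits with the precursor alone); otherwise
**conservative** if $K_{miR}/K_S < 0.5$; otherwise **transitional**.
Adaptive takes precedence — a gene under ongoing positive selection is
not "conserved" however low its ratio.

The turnover model assumes a constant birth rate estimated from the
youngest age interval (`estimate_birth_rate()`), where death has had the
least time to act. For each interval, newborns = rate × interval length;
deaths = newborns − observed survivors (`build_ledger()`). Newborn counts
are kept real-valued and only rounded for display; the ledger enforces
the conservation identity deaths + survivors = newborns and refuses
intervals where survivors exceed inferred newborns (a symptom of a
misestimated rate). Ledger counts should be built from highly expressed
canonical genes only, matching how the observed survivor counts are
defined.

## Expression analysis

Counts are normalized to reads per million miRNA-mapped reads
(`rpm_normalize()`), with multireads split fractionally across their
precursor matches; each library's RPM column sums to $10^6$ by
construction. Genes exceeding 200 RPM (strictly) in at least one library
are "highly expressed" (`classify_expression()`). Profiles are
log2-transformed with a pseudocount of 1 (zeros are ubiquitous in
small-RNA tables and the transform must be total) and clustered with
average-linkage hierarchical clustering on Euclidean distances
(`cluster_expression_profiles()`); linkage and metric are configurable
conventions, chosen as the common defaults for expression heatmaps.
Mirtrons are precursors whose ends both coincide exactly with a host
intron's splice sites (`classify_gene()`); genomic clusters are chains of
more than three precursors whose consecutive members lie within 20 kb
(`detect_clusters()`), reading "within a 20 kb region" as a transitive
sliding window.

## The synthetic-data generators

The generators (`sim_*`) produce inputs with exactly the statistical
structure each stage assumes, plus a machine-readable truth record:

- `sim_haplotypes()`: infinite-sites samples; $S \sim
  \mathrm{Poisson}(\theta a_n)$ and derived counts $\propto 1/i$
  (neutral), with an optional high-frequency mixture component (counts
  $> 0.8\,n$) emulating hitchhiking. This is an SFS-level shortcut, not a
  coalescent with linkage: sufficient for testing estimator calibration
  and the direction of $H$, silent about LD, recombination and
  demography.
- `sim_divergence_pair()` / `sim_cds_pair()`: site-wise K2P substitution
  at the target distance and transition bias; the CDS variant redraws
  codons that would create stops.
- `sim_mk()`: Poisson counts with the test-class divergence rate inflated
  by $1/(1-\alpha)$, so the planted $\alpha$ is recoverable.
- `sim_presence()`: births uniform in time on the focal lineage at a
  constant rate, branch-wise exponential losses silencing whole subtrees,
  conditioned on survival in the focal species (unobservable genes are
  not rows). Defaults: birth rate 3 genes/Myr (the rate implied by 12
  genes in the youngest 4 Myr interval) and loss rate 0.08/Myr, which
  reproduces turnover of the observed order (death fractions near 90%
  over tens of Myr).
- `sim_fst()`: Balding–Nichols frequencies at the target $F_{st}$,
  binomial allele counts.
- `sim_expression()`: negative-binomial counts under an age-graded
  breadth/level configuration — young genes restricted to testis and
  larval libraries at low mean, old genes broad and abundant — mirroring
  the qualitative gradient real repertoires show. Passing tests on these
  fixtures demonstrates the pipeline's logic, not the biology of any real
  library set.

Problem sizes used in the test suite (for example 2000 replicates for
estimator-unbiasedness checks, 200 for $\alpha$ recovery, $10^4$ SNPs for
$F_{st}$ recovery) were chosen as the smallest sizes at which the checked
standard errors are meaningfully tight.

## Numerical and degenerate-input choices

- Fisher p-values are computed from `phyper` (log-gamma internally); no
  normal approximation is ever substituted.
- K2P raises a saturation error when a log argument is non-positive,
  naming the offending term; NG86 does the same at $p_S \ge 3/4$.
- $D/P$ with $P = 0$ propagates as `Inf` and prints as "Inf.".
- Zero-total libraries, all-zero MK tables, empty presence rows and
  unrooted/non-ultrametric trees are rejected with named errors rather
  than coerced.
- All coordinates are 0-based half-open internally (BED dialect);
  converters to 1-based closed GFF coordinates are exact inverses.
- Statistics are strand-agnostic; strand is carried for reporting only.

## Known limitations

- Parsimony dating cannot see a gene older than the span of taxa that
  retain it; ages are lower bounds under heavy loss.
- The $\alpha$ ratio estimator ignores segregating slightly-deleterious
  variants beyond what the DAF filter removes; DFE-based estimators are
  out of scope.
- The hitchhiking generator is phenomenological: it tests detection
  direction, not sweep parameters.
- The birth–death ledger treats the birth rate as exactly constant;
  uncertainty in the rate is not propagated.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(seed = 1, outdir = "mirfate_demo")
res <- run_pipeline(cfg)
res$ledger
res$fate_report
```

The pipeline writes per-stage TSVs (age assignments, RPM matrix with
expression classes, a sliding $\theta_H$ track, the MK report with the
exact 2×2 tables logged, the fate report) and JSON summaries into the
output directory; rerunning with the same seed reproduces them
byte-for-byte.
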