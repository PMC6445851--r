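---
title: "Methods: integrative GWAS-locus target-gene identification"
author: "gwastargets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative GWAS-locus target-gene identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwastargets)
```

## The problem

Most risk variants found by genome-wide association studies (GWAS) of
autoimmune disease fall outside protein-coding exons, so the gene a
locus acts through is rarely obvious. A widely used strategy is to
triangulate: a SNP is linked to a candidate *target gene* when (i) its
genotype correlates with that gene's expression (an eQTL), (ii) the gene
is differentially expressed between patients and controls in the cell
type of interest, and (iii) epigenetic evidence — histone-mark overlap at
the SNP, or a genotype effect on DNA methylation in the gene — supports a
regulatory mechanism. The candidate genes are then placed in their
protein-interaction context and tested for pathway enrichment.

`gwastargets` implements that whole chain as composable, seeded,
testable stages, together with a synthetic-data generator that emulates
the statistical structure of every input, so the pipeline can be
validated end to end without access to the external databases such an
analysis normally draws on (eQTL portals, expression repositories,
epigenome atlases, interactome and pathway databases).

## Stages and their models

### Preprocessing (`log2_transform`, `quantile_normalize`, `median_polish`)

Microarray-style intensities are log2-transformed for variance
stabilization, then quantile-normalized across arrays (each column's
sorted values are replaced by per-rank means; tied values receive the
mean of the tied ranks' reference values, a convention fixed here for
bit-reproducibility). Probe-level tables can be summarized to gene level
by Tukey median polish, which decomposes a probe-by-sample table into
`overall + row + column + residual` by alternately sweeping row and
column medians (rows first, tolerance `1e-6`, at most 20 iterations —
a deterministic convergence contract); the per-sample gene summary is
`overall + column effect`. Full convolution-model background correction
is deliberately not implemented: the pipeline operates from
series-matrix-level values, which are already background-adjusted.

### Differential expression: rank product with permutation PFP

For two unpaired classes the rank-product statistic is built from
single-sample case-minus-control log2 fold-change vectors. Within each
comparison genes are ranked (descending for up-regulation, ascending
for down; ties get mid-ranks) and gene *g*'s rank product over *k*
comparisons is the geometric mean rank

$$RP_g = \Big(\prod_{c=1}^{k} r_{g,c}\Big)^{1/k}.$$

Significance is attached by permutation: in each of *B* rounds the rank
vector of every comparison is permuted uniformly and independently
(within, never across, studies), null rank products are computed, and
with `x(g)` the average number of null genes at or below gene *g*'s
observed RP, the *proportion of false positives* is
`PFP(g) = x(g) / rank(g)` — an FDR-type quantity, reported untruncated
together with a monotone cumulative-minimum variant. Genes pass at
`PFP < 0.05` and pooled signed fold change `|FC| > 1.2` (both strict).
The signed fold change is the case/control ratio of geometric-mean
intensities, pooled across studies by unweighted mean of per-study log2
ratios, and reported as `r` when `r >= 1` and `-1/r` otherwise so the
threshold is symmetric.

**Comparison scheme.** This permutation null treats comparisons as
independent. All case × control pairs within a study share samples and
are therefore positively correlated; feeding them to this null makes
PFP anti-conservative (we measured ~21% of null genes called at
PFP < 0.05 in a pure-null simulation). The default scheme is therefore
a seeded *disjoint* 1:1 matching of cases to controls per study — each
sample used at most once, so comparisons are mutually independent under
the null, in the spirit of the original rank-product formulation's
independent replicate comparisons. Under this scheme the measured null
call fraction is ≈ 0 and sensitivity for two-fold planted genes is ≈ 1
(see the acceptance suite). The all-pairs scheme remains available via
`scheme = "all"` (capped at `cap` seeded pairs per study) for users who
want the exhaustive enumeration and will attach their own null.

### eQTL filtering

Associations between SNP dosage (0/1/2) and expression are ordinary
least squares with intercept and a two-sided t-test on the slope — the
standard additive eQTL model. The pipeline filters at a *nominal*
`p < 0.05` with no multiple-testing correction at this stage: GWAS
variants and their true targets need not show extreme eQTL significance,
and this stage is an evidence filter, not a discovery scan. Constant
genotypes are flagged untestable rather than raising, so batch scans
continue.

### Integration and histone annotation

The target table keeps one row per (SNP, gene) pair passing all three
filters (eQTL p, PFP, |FC|; all strict inequalities), sorted by
chromosome and position; a gene reached by several SNPs keeps one row
per SNP, and direction counts are per distinct gene. SNP positions are
1-based; histone-mark intervals follow the BED convention (0-based,
half-open), and the single coordinate conversion in the package happens
inside `annotate_histone_overlap` — a SNP at position *p* overlaps
`[start, end)` iff `start <= p - 1 < end`. Gene location classes
(5′/3′/intron/exon) are read from annotation input, not computed.

### Methylation (meQTL)

Each SNP is tested against every methylation probe in its target
gene(s): the probe's M-value (log2 methylated/unmethylated intensity
ratio, taken as given) is regressed on genotype dosage adjusted for sex,
age and 10 genotype-derived principal components; the genotype slope's
two-sided t-test is the reported P-value. Designs with `n` at or below
the 13 predictors + intercept, constant genotypes, or rank deficiency
are flagged untestable with a diagnostic. The experiment-wide cutoff is
Bonferroni, `alpha / n_tests`, displayed at 2 significant figures — with
0.05 over 144 tested pairs this is `3.5 x 10^-4`, which is how the
package reproduces the published cutoff.

### Network enrichment and the empirical pathway P

The first-order network is the induced subgraph on the target genes
present in the interactome plus their direct interactors (absent seeds
are reported, never silently dropped). Pathway enrichment is the
upper-tail hypergeometric test: population = background universe,
successes = pathway size, draws = network genes in the universe, with
`Expected = Total × draws/|universe|`; P-values are adjusted by
Benjamini–Hochberg step-up over all `m` tested pathways (`m` may exceed
the number of P-values passed in, for consistency with reports that
print only the significant rows).

The *empirical pathway P* repeats the entire analysis on `R = 100`
random gene lists of the observed size: a pathway's empirical P is
`b/R`, the fraction of resamples in which it reaches FDR < 0.05, with
`b = 0` rendered as the censored token `"<1/R"` (`"<0.01"` at R = 100)
rather than 0. Random lists are drawn from the pathway-annotated
universe by default so the null matches the enrichment background; this
deviates from drawing from the whole genome and is configurable
(`draw_from = "interactome"`).

**Background universe.** The published analysis never states its
universe size. The package defaults to the genes present in the
interactome that carry at least one pathway annotation — the standard
choice that keeps the test conditional on annotatability — and the
universe is an explicit, configurable field of `pathway_db()`.

## The synthetic-data generator

`sim_config()` fixes every generator parameter; all randomness flows
from one master seed through named sub-streams (expression, genotypes,
methylation, interactome, pathways, ...), so a fixed configuration gives
byte-identical outputs regardless of call order. What it emulates:

- **Expression**: per-gene baselines uniform on log2 6–12, Gaussian
  log2-scale noise (default SD 0.3, a typical residual spread for
  processed two-channel or oligo arrays), planted DE genes shifted by
  `log2(FC)` in cases, then exponentiated so the log2 preprocessing step
  is exercised. Default design: two studies totalling 36 cases and 26
  controls, split 18/13 per study — the split is a free parameter
  because only the totals are fixed by the emulated design.
- **Genotypes**: `Binomial(2, maf)` per SNP, i.e. Hardy–Weinberg
  genotype frequencies; default MAF 0.3, a common variant.
- **Methylation**: M-values linear in dosage, sex, age, 10 PCs, plus
  Gaussian noise (default SD 0.5, typical M-value residual spread), 11
  probes per gene by default.
- **Interactome**: preferential attachment (2 edges per new node),
  giving a connected, simple, scale-free graph; node labels are drawn
  from the synthetic gene universe `G0001...` (no real annotation is
  shipped).
- **Pathways**: uniform draws from the interactome node set, plus one
  optional planted set overlapping the seed genes' first-order
  neighborhood far above chance.

What it does *not* emulate — and what passing tests therefore cannot
show about real data: linkage disequilibrium between SNPs, probe-level
microarray artifacts, batch effects, correlated co-expression modules,
sex chromosomes, and the literature-driven topology of curated
interactomes. The generator validates the *machinery* (calibration,
power on planted effects, determinism, format round-trips), not
biological discovery.

## Numerical choices

- Quantile-normalization ties: mean of tied ranks' reference values.
- Median polish: rows swept first, `tol = 1e-6`, `maxiter = 20`.
- PFP rank denominator uses `ties.method = "max"` (conservative for
  tied rank products); the monotone variant is a step-down cumulative
  minimum over genes ordered by RP.
- All filter thresholds are strict inequalities; a boundary value
  (e.g. PFP exactly 0.05) is excluded.
- Degenerate inputs fail loudly with coordinates (non-positive
  intensity at log2; malformed intervals; namespace mismatches) except
  inside batch regressions, where untestable records are flagged.

## Problem sizes used for validation

The acceptance suite and `scripts/acceptance.R` validate calibration at
desk scale, chosen once as representative of the emulated designs:
rank-product calibration on 1000 genes, two studies of 5 + 5 samples,
B = 100 permutations, 20 replicates (null fraction and sensitivity for
20 planted two-fold genes at noise SD 0.3); planted-pathway recovery on
a 400-node interactome with 50 pathways, R = 100 resamples, 20
replicates; meQTL recovery at n = 200 subjects. Published-table replays
(the 13-pair target table, the 0.05/144 cutoff, the four-pathway BH
check) are exact fixture computations.

## Known limitations

- The rank-product PFP, like any permutation FDR estimate, is noisy for
  small B; B = 100 matches the resampling scale used elsewhere in the
  pipeline but can be raised.
- With the disjoint comparison scheme, `min(n_case, n_control)`
  comparisons per study are used; very unbalanced studies contribute
  few comparisons.
- Replaying published summary tables validates the filtering and
  adjustment logic, not the upstream estimates in those tables; and
  published FDR columns derived from unrounded P-values can only be
  matched to within the rounding of their printed inputs (~0.5%
  relative here).
- Dataset-level counts of a real analysis (numbers of GWAS regions,
  eQTL genes, specific gene identities) depend on external database
  versions and are out of scope; the distinct-gene count the pipeline
  reports is its own, and where published prose gives two totals for
  the same set the pipeline simply reports what it computed.

## A minimal run

```{r, eval = FALSE}
cfg <- demo_config(seed = 1, n_genes = 500, interactome_size = 400)
pc <- pipeline_config(seed = 1, sim = cfg, out_dir = "out")
res <- run_pipeline(pc)
res$target_table
res$enrichment
```
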