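---
title: "Methods: epimutation discovery in CIMP tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epimutation discovery in CIMP tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimutr)
```

## The analysis problem

A subset of gastric (and other) tumors displays the CpG island methylator
phenotype (CIMP): pervasive hypermethylation of CpG islands, including
gene promoters. When promoter hypermethylation silences an otherwise
expressed gene without any change to its sequence, the event is an
*epimutation*. epimutr implements the complete discovery workflow for such
events from methylation-array beta values plus expression (and optionally
protein) matrices, and the companion workflow for testing whether a
gene knockout *induces* CIMP-like methylation drift in clonal cell lines
cultured across passages.

The package deliberately contains its own synthetic-data generator with
machine-readable planted truth. Every statistical claim the package makes
can therefore be exercised end to end against data whose ground truth is
known exactly.

## Cohort workflow

### Subtyping

Samples are classified as CIMP-high / CIMP-low / non-CIMP by unsupervised
clustering:

1. Eligible probes are CpG-island probes, excluding sex chromosomes and
   flagged (e.g. SNP-overlapping) probes, and excluding probes with any
   missing beta value (standard deviations and Ward distances both require
   complete vectors; the upstream array pipeline's treatment of masked
   probes is not knowable, so exclusion is this package's declared
   policy).
2. Probes are ranked by standard deviation across all samples (n − 1
   denominator, the sample SD convention) with ties broken by probe id,
   and the top k = 10,000 kept.
3. Samples are clustered by Ward's minimum-variance linkage on Euclidean
   distances (`hclust` method `ward.D2`, the standard definition of
   Ward's criterion) and the tree is cut into B = 4 branches.
4. Branches are ordered by mean beta over the selected probes: the
   highest becomes CIMP-high, the lowest non-CIMP, the middle two
   CIMP-low. Labeling by mean methylation rather than by manual
   inspection of the dendrogram makes the assignment automatic while
   preserving the semantics (CIMP = hypermethylated). Exactly tied means
   are broken toward the lower branch index, with a warning.

### Differential calling and the tri-omic intersection

All two-group tests use one engine: the Mann–Whitney/Wilcoxon rank-sum
test with Benjamini–Hochberg control. Negative-binomial count modeling is
deliberately **not** used, even where a practitioner might reach for it:
the scientific content of the workflow is the thresholded intersection
logic, not the per-gene test, and a rank-based test keeps the engine
assumption-free on matrices of RPKM/FPKM or LFQ intensities. The cost of
this choice is granularity: with n_A = 6 vs n_B = 8 samples the smallest
achievable two-sided exact p is 2/choose(14,6) ≈ 6.7e−4, so BH q-values
over a large feature family have a hard floor (see *Numerical choices*).
Absolute p/q values will not match a parametric pipeline; membership of
strongly affected features in the thresholded sets will.

Calls are conjunctions of explicit thresholds (all mandatory, all echoed
to the run log):

* promoter hypermethylation: Δβ = mean(CIMP-high) − mean(non-CIMP) ≥ 0.3
  on the promoter-mean methylation (unweighted mean over a gene's
  promoter probes, missing values ignored), q ≤ 0.1;
* RNA downregulation: fold difference FD = (mean_A + ε)/(mean_B + ε)
  ≤ 0.6 with ε = 0.01 guarding zeros, q ≤ 0.05, and reference-group
  median ≥ 1 RPKM (a gene cannot be "downregulated" if the reference
  barely expresses it);
* protein downregulation: log2 FD ≤ −2, q ≤ 0.05. A printed threshold of
  "log2 FD ≤ 2" for a *down*-regulation filter is read as magnitude 2 in
  the downward direction; the package exposes the signed value.

A candidate epimutation is a gene passing all provided filters (two-way
when no protein data exist). The recurrence stage then reports, per gene
and subtype, the fraction of samples with expression strictly below
1 RPKM ("silenced"), as percentages *truncated* to two decimals — the
convention that reproduces published panel values such as 12/14 = 85.71%
and 2/23 = 8.69% — plus the Spearman correlation between promoter beta
and expression across all samples (midranks, t-approximation p; one
documented convention rather than the method switching `cor.test`
performs under ties).

## Clone workflow

### The consensus caller

The knockout design measures one parental line, one CRISPR control, and
two knockout clones at each of five passages. A probe is part of the
conserved signature when, at **every** passage and for **every**
(clone, control) pair at that passage, the difference clone β − control β
has magnitude ≥ 0.2 with one common sign. "All controls" means both the
parental and the CRISPR control at the matched passage. Requiring the
threshold in both clones at all passages is what removes clone-private
(clonal bottleneck) and passage-private (culture drift) events, and sign
consistency is required by default because hyper- and hypomethylated
sites are reported disjointly. The threshold is inclusive (≥ 0.2) with a
`strict` flag for the > reading, since both readings appear in common
usage.

Significance is assessed by a random-pairing permutation null: within
each passage the four role labels are shuffled uniformly among that
passage's samples (any per-passage identity assignment is redrawn), the
caller is rerun, and the called-probe count recorded. The empirical p
uses the add-one convention (1 + #{null ≥ observed})/(1 + N). Shuffling
within passage preserves the longitudinal pairing structure of the
design; this scheme is a declared choice.

### Downstream characterization

The signature is profiled for CpG-context composition (island / shore /
shelf / open sea) against the annotated array background with exact
binomial tails — both one-sided tails are reported so either reading of
a "binomial test" is reproducible. Probe signatures map to CGI level by
majority vote over each island's probes (ties dropped with a warning),
with a minimum-1-probe overlap rule, and CGI-level overlap against a
cohort-derived CIMP signature is tested by bootstrap: each iteration
draws |A| CGIs uniformly without replacement from the testable universe
and counts the overlap with B. Resampling the A side against a fixed B
from the union universe is the most conservative standard construction;
the universe choice matters for the p-value and is therefore explicit in
the API. Genes with hypermethylated promoter probes are finally split
into non-passengers (expression FD ≤ 0.6 in *both* clones) and
passengers.

## The synthetic-data generator

`simulate_manifest()` lays out a deterministic array: islands are runs
of consecutive probes sharing a CGI id, flanked by shore then shelf
probes, with open-sea probes between blocks; context counts follow
largest-remainder apportionment so they are exact and testable. Context
proportions default to the approximate 450K-array breakdown (31% island,
23% shore, 10% shelf, 36% open sea). The first 1,000 islands are gene
promoters with 7 flagged probes each (TSS offsets within ±2 kb).

Beta noise is Beta(m·s, (1 − m)·s) around the per-probe mean m: this
respects the [0, 1] support and the mean-dependent variance of array beta
values. Means are clipped to [0.02, 0.98] before sampling so the Beta
parameters stay proper. The concentration defaults to s = 100 in cohort
mode — distinct cell lines, biological heterogeneity, per-probe SD ≈
0.035 at island baseline — and s = 500 in clone mode, where the same
line is measured repeatedly and replicate-level array precision (SD ≈
0.02) is the realistic regime. At s = 500 the Beta tail bound puts the
probability that a planted Δβ = 0.3 shift clears all twenty ≥ 0.2
comparisons above 99.5% per probe; at s = 100 it would be ~30%, i.e. the
consensus rule would be testing the noise model rather than the caller.

Cohort structure: a configured fraction (20%) of island probes gains
Δβ = 0.35 in CIMP-high samples. CIMP-low is planted as two equal
sub-populations at 0.4 and 0.6 of the CIMP-high effect (mean = half the
effect). The two sub-levels are deliberate: the subtyping procedure cuts
four branches and maps the middle two to CIMP-low, so the emulated cohort
must actually contain two CIMP-low clouds for that topology to be real;
with a single intermediate level the fourth branch would be an arbitrary
split of the unmethylated cloud and the fixed rank-to-label rule would
mislabel it. Non-malignant (normal) samples share the non-CIMP
distribution and are expected to co-cluster with non-CIMP tumors.

Planted epimutation genes couple all three layers in CIMP-high samples:
promoter probes gain Δβ = 0.35, expression drops to Uniform(0, 1) RPKM,
and protein log2 intensity drops by 3 (≥ 2 defines co-downregulation).
Outside CIMP-high their expression is log-normal *truncated to ≥ 1
RPKM*: an epimutation target is by definition an otherwise-expressed
gene, and the truncation encodes exactly that (published recurrence
panels show 0% silencing in non-CIMP lines). Background expression is
log-normal (meanlog 2, sdlog 1) independently per gene and sample; genes
other than planted epimutations have expression independent of their
methylation, which is what makes planted-recovery precision a meaningful
test of passenger rejection. The protein matrix covers 30% of genes
(always including the planted ones) with noise SD 0.5 log2 units —
shotgun-proteomics depth and replicate precision, respectively.

Clone mode plants hyper DMPs on island probes (including the promoters
of a configured set of genes whose expression then drops in both clones)
and hypo DMPs on open-sea probes, mirroring the CIMP-like context bias
the workflow is meant to detect; clone-private and passage-private
decoys exercise the consensus rule's rejection logic. When the cohort's
planted CIMP probes are supplied, 35% of the hyper DMPs are drawn from
them so the clone-vs-cohort CGI overlap has a known planted value.

Every output object draws from its own RNG stream derived from the
master seed (documented integer keys), so generating an additional
output never perturbs the others, and runs are bit-reproducible.

What the generator does *not* emulate: probe-level covariation along the
genome (neighboring CpGs are independent given their means), cell-line
heterogeneity in global methylation level, batch effects, detection-p
missingness structure (masking is uniform), and count noise in
expression. Passing recovery tests therefore demonstrates the
correctness of the implemented logic under the declared noise model, not
performance on raw array data.

## Numerical choices

* **Rank-sum p-values.** Exact whenever n_A·n_B ≤ 400: via the closed
  form (`pwilcox`) without ties, and by a subset-sum dynamic program
  over the doubled midranks with ties — `wilcox.test` has no exact tied
  path. Above that, the normal approximation with tie-corrected variance
  and continuity correction. Two-sided p is twice the smaller tail,
  capped at 1 (the tied null distribution need not be symmetric).
* **The q floor.** With 6 vs 8 samples the minimum exact p is 2/3003;
  over an m-feature family the best attainable BH q is (2/3003)·m/k
  where k features share the floor. This is why a genuinely silenced
  gene can fail q ≤ 0.05 in a small design no matter how large its
  effect — a property of rank tests at these sample sizes, stated here
  so users do not read such misses as implementation error.
* **Fisher's exact test** uses the conditional-MLE odds ratio and the
  usual two-sided convention (sum of hypergeometric probabilities ≤ the
  observed table's). The all-zero table returns p = 1 with an undefined
  odds ratio rather than an error.
* **Degenerate inputs.** Features with fewer than 2 usable values in
  either group are dropped (reported, not imputed); probes with any
  missing value in a required clone-design sample are "not callable"
  and excluded from the signature universe; genes with zero eligible
  promoter probes are omitted from aggregation and listed.
* **Coordinates** are 1-based inclusive internally (array annotation
  convention); BED export converts to 0-based half-open. Strand is
  ignored throughout: CpG methylation is strand-symmetric at probe
  resolution.
* **Empirical p-values** always use the add-one convention, so they are
  never zero and are honest about Monte-Carlo resolution (1/(N + 1)).

## Problem sizes used by the test suite

The package's own validation uses cohorts of 50,000 probes × 30 samples
(6 CIMP-high, 8 CIMP-low, 8 non-CIMP, 8 normal) and clone series of
50,000 probes × 20 samples (4 roles × 5 passages) — the emulated study's
design scale — for the recovery suites (10 seeds each), and 8,000-probe
versions of the same designs for per-module unit tests. Calibration
checks use 200-seed bootstrap-uniformity runs and 20-seed null cohorts.
These sizes were chosen so that the complete suite documents the
workflow's behavior at realistic scale while remaining comfortably
runnable on a laptop.

## Known limitations

* The subtyping label rule assumes the four-branch topology with two
  CIMP-low branches; cohorts whose true structure differs (e.g. no CIMP
  samples at all) will still receive the three labels. Inspect the
  dendrogram (`plot()` on the result) before trusting labels.
* The rank-sum engine's q floor (above) makes the published q-thresholds
  conservative at small n; the package reports p and q so users can see
  when the floor binds.
* The random-pairing null and bootstrap overlap schemes are declared
  constructions: alternatives (cross-passage shuffles; resampling the B
  side; other universes) are supported through the API but change the
  p-values, so comparisons across studies must fix these choices.
* The generator's independence assumptions (above) mean FDR estimates
  from simulation are optimistic relative to spatially correlated real
  arrays.
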