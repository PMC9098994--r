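---
title: "Methods: allele-specific CNA calling, KRAS LOH, and survival integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific CNA calling, KRAS LOH, and survival integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lohcna` analyzes tumor cohorts downstream of allele-specific
copy-number segmentation. This vignette documents the model, the
conventions and tunable parameters, the synthetic-data generator used
throughout the test suite, and the design choices made where the
methodology left genuine freedom.

## The calling model

The unit of input is one tumor's **segment profile**: a partition of
each chromosome into regions of constant allele-specific copy number
(major copies `n_major` ≥ minor copies `n_minor` ≥ 0), together with an
estimate of tumor **ploidy** ψ (average tumor copy number, a real
number) and **cellularity** (tumor cell fraction). Profiles of this
shape are what ASCAT-style pipelines emit; segmentation itself is out
of scope here, and cohort QC keeps tumors with cellularity strictly
above 20% (`filter_by_cellularity()`, threshold configurable).

For a segment of total copy number `n = n_major + n_minor`:

* **ploidy-adjusted copy number** `a = round(n − ψ)`, with ψ used
  unrounded and ties at exactly ±.5 rounded half away from zero.
  Half-away rounding keeps gains and losses symmetric; banker's
  rounding would call `n − ψ = 0.5` neutral but `−0.5` a loss.
* **state**: gain if `a ≥ 1`, loss if `a ≤ −1`, neutral if `a = 0`.
* **LOH** iff `n_minor = 0` and `n_major ≥ 1` — only one allele
  remains. **Copy-neutral LOH** is LOH with `a = 0` (one allele lost,
  the other duplicated up to ploidy). Total copy number 0 is a
  **homozygous deletion**: state loss, but *not* LOH, since no allele
  remains; it carries its own flag. None of these rules depends on
  cellularity — the allele-specific integers are assumed already
  purity-corrected upstream.

The **genome instability index** of a tumor is the fraction of probes
lying in gained or lost segments, among probes lying in any segment.
Probes in unsegmented gaps carry no call and are excluded from both
numerator and denominator; whether this matters in practice depends on
how completely the upstream segmentation tiles the genome. GII is
dichotomized at the cohort median by default (`dichotomize_gii()`,
ties low; the cutoff is an argument because no canonical threshold
exists).

## Coordinates and gene projection

All internal coordinates are 1-based and inclusive on both ends —
the convention of SNP-array probe annotations. refFlat transcript
starts (0-based) are shifted on read; BED-like outputs are converted
back to 0-based half-open on write. Transcripts sharing a gene symbol
are collapsed to their union span, strand is ignored (copy number is
strand-agnostic), and genes annotated on several chromosomes are
dropped with a warning rather than silently assigned one locus.

A gene takes the call of the overlapping segment with the **largest
base-pair overlap**. The tie-break chain — more extreme
|adjusted copy number|, then LOH = TRUE, then leftmost segment — makes
the assignment deterministic and permutation-invariant; the fraction of
the gene covered by the assigning segment is reported so borderline
assignments are visible. Genes overlapping no segment get an explicit
no-coverage marker, never an imputed neutral. Any-overlap and
majority-overlap rules are both defensible for genes spanning
breakpoints; largest-overlap was chosen as the single-call rule and is
declared rather than inferred from published percentages, which do not
pin it down.

## Frequency tracks and per-interval testing

Genome-wide aberration frequency is computed on fixed-width tilings
(default 15 kb) anchored at position 1 of each chromosome. A sample
counts as gained or lost in an interval iff the segment containing the
**interval midpoint** carries that state — a 15-kb window is then a
single position query, and a window straddling a breakpoint is never
double-counted. Group comparison per interval is the two-proportion
test with continuity correction (algebraically the Yates-corrected 2×2
chi-square; a flag disables the correction). Raw p-values are the
primary output, matching the convention of reporting `p < 0.05`
per interval; a BH-adjusted column is emitted alongside, clearly
labelled, because thousands of intervals are tested. Intervals with an
empty denominator in either group give missing p; intervals with
identical degenerate proportions (0% or 100% in both groups) give
p = 1 rather than NaN.

## Association statistics

`chi_square()`, `fisher_exact_2x2()`, `two_sample_t()` and
`bh_adjust()` wrap the standard R machinery (`chisq.test`,
`fisher.test`, `t.test`, `p.adjust`) behind validated interfaces. Two
conventions deserve explicit statement:

* **Which 2×2 test.** Published clinicopathological tables rarely say
  per row whether Yates correction or an exact test was used.
  `table2_association()` applies a fixed policy: 2×2 tables get the
  continuity-corrected chi-square unless some expected count is below
  5 (then Fisher), larger tables the uncorrected Pearson chi-square.
  This policy reproduces every recoverable printed p-value of the
  motivating cohort tables. Notably, for the KRAS LOH × mutation
  table the value printed as a Fisher p (0.057) is in fact the
  corrected chi-square / `prop.test` p-value; the genuine two-sided
  Fisher p for those counts is 0.045. Both are available — the policy
  value via `table2_association()`, the exact-hypergeometric value via
  `fisher_exact_2x2()` — and the test suite pins the latter to an
  exhaustive enumeration oracle.
* **Which odds ratio.** `fisher_exact_2x2()` reports the sample odds
  ratio ad/bc (0.510 for the table above), not the conditional
  maximum-likelihood estimate `fisher.test` prints (0.512): the
  published value matches the former, and ad/bc is the estimand the
  two-sided hypergeometric p is usually paired with in clinical
  tables.

BH adjustment validates its inputs to (0, 1] and is applied across
whichever family the caller supplies; for the hotspot panel the family
is the 13 non-KRAS genes (`hotspot_association()`), which reproduces
the printed adjusted values to their displayed precision (one printed
value, NTRK3, differs from recomputation in the last digit — 4.75e-5
printed vs 4.77e-5 from the printed raw p — consistent with a
truncated raw p in print; it is documented, not fitted).

## Expression integration

Copy-number–expression coupling is measured by per-gene Pearson
correlation between the gene's copy-number value and its log2
expression across shared samples, with the t-transform p-value on
n − 2 degrees of freedom and BH q across all tested genes. Genes with
zero copy-number variance are reported with a reason code and excluded
from the family. The copy-number value defaults to the total gene-level
copy number; published phrasing ("allele-specific copy number values")
does not disambiguate a single choice, so the caller can pass any
per-gene matrix (adjusted, major, or minor allele). Selection uses
strict thresholds r > 0.4 and q < 0.05 by default.

Differential expression between LOH groups is the per-gene Welch
t-test with BH — the simplest method consistent with "significantly
differentially expressed" when no method is named; the module surface
makes it replaceable. Cross-cohort reproducibility is plain set
intersection of the significant genes.

Molecular subtypes (TRU / PP / PI) are assigned by nearest centroid
over a signature-gene panel after per-gene median-centering, with
Pearson correlation as the closeness measure — the convention of the
centroid-classifier family this follows; Spearman and Euclidean are
offered. Exact ties break by centroid column order and are flagged.
The 506-gene published centroids are an external data file supplied by
the user; the package ships no copy, and tests use synthetic centroids
labelled as such.

## Survival analysis

Kaplan–Meier estimation, the log-rank test and Cox proportional-
hazards regression wrap the `survival` package. Conventions: events
precede censorings at tied times (product-limit standard); Cox partial
likelihood uses **Efron** tie handling; the reported median is the
smallest observed time with survival ≤ 0.5. Covariates measured on
arbitrary scales (expression values) can be standardized to unit
variance so hazard ratios read per standard deviation; stage enters
models as the binary contrast II + III vs I. Non-convergence,
separation and collinearity raise errors instead of returning fragile
estimates. `bivariate_scan()` fits one two-covariate model per
candidate confounder with the LOH flag fixed, reporting the flag's
hazard ratio from each model — a stability check, not a joint model.
Missing covariate values are dropped per analysis, never imputed.

## The synthetic cohort generator

`cohort_spec()` fixes the study conditions; `generate_cohort()` emits
a complete cohort plus ground truth. Defaults encode the cohort the
pipeline targets: 233 tumors, KRAS LOH prevalence 0.27, KRAS mutation
prevalence 0.365, mean aberrant-genome fraction 0.57 (LOH) vs 0.46
(no LOH) with between-tumor sd 0.10, copy-neutral LOH in 12/62 ≈ 19%
of LOH tumors, overall-survival hazard ratio 0.65 for LOH with a
60-month baseline median and ~30% independent exponential censoring,
expression = baseline + 0.6 × copy number + N(0, 0.6²) log2 units,
ten genes with a planted 2-log2 LOH expression shift, and a 60-gene
three-centroid subtype signature (mixing 0.55/0.26/0.19, noise sd
0.3). The genome model is five chromosomes (25–50 Mb) with probes
every 20 kb and ~5 segments per chromosome — large enough for stable
probe fractions, small enough that a 2000-tumor cohort generates in
seconds.

Mechanically, each chromosome is partitioned at uniform breakpoints;
each segment is aberrant with the tumor's target probability (gain or
loss equally, allele counts drawn so the intended state survives the
rounding rule for any real ploidy in [1.6, 4.5]). Segment boundaries
are then carved at the KRAS gene so the planted LOH state occupies
exactly the gene span — forcing whole segments would leak the planted
state into several megabases and visibly bias the GII group contrast.
The truth record stores the *realized* aberrant probe fraction
computed by independent probe-count arithmetic, so GII recovery can be
asserted exactly; survival hazard depends only on LOH status, keeping
the planted marginal hazard ratio recoverable by a univariate Cox fit
(a deliberately simple world — adding independent stage or age effects
would attenuate the marginal estimate through non-collapsibility).
Cellularity is drawn in (0.3, 0.95): the generator emulates the
post-QC cohort, and the retention filter is exercised on explicit
fixtures instead. Planted differentially expressed genes use stable
symbols (`BG0001`, ...) so independently seeded cohorts share the
truth set for intersection tests.

What the generator does **not** emulate: linkage and haplotype
structure, platform-specific probe noise, wavy LogR artifacts,
subclonal (non-integer) states, missing clinical values, cohort batch
effects, and correlation between clinical covariates and genotype.
Passing recovery tests therefore demonstrates the pipeline's
correctness on data satisfying its model assumptions, not robustness
to the full messiness of array data.

## Numerical choices and degenerate inputs

* Rounding: half away from zero everywhere a copy number is rounded.
* GII is an error, not 0/0, when no probe falls inside any segment.
* `two_sample_t()` returns p = 1 for two constant groups with equal
  means, and errors when both are constant with different means.
* Zero-margin contingency tables error in `fisher_exact_2x2()`; a zero
  expected cell errors in `chi_square()`.
* Fisher two-sidedness is hypergeometric-probability ordering (with
  the customary 1 + 1e-7 tie slack), not doubling of the smaller tail.
* Log-rank requires at least one event; pairwise strata tests with no
  events give NA rather than an error.
* Seeds: generation is fully deterministic given (spec, seed); derived
  seeds stay below 2^31.

## Problem sizes used in the checks

The suite verifies GII against a brute-force per-probe oracle on 1000
random profiles, Fisher p against exhaustive enumeration for tables
with total ≤ 60, and BH against a reference step-up on 10^4 random
vectors. Recovery runs use n = 500 (LOH prevalence, GII contrast),
n = 2000 (hazard ratio, the size at which the Cox estimator's sampling
error comfortably resolves 0.65 from 1), n = 200 (differential
expression) and n = 300 (subtypes); Cox calibration uses 200 cohorts
of n = 300. These sizes were chosen so the whole suite runs in a few
minutes on one CPU while keeping Monte-Carlo error well inside each
assertion's margin.

## Known limitations

* Calling assumes integer allele counts from upstream purity/ploidy
  correction; subclonal fractions are out of scope.
* The gene-assignment rule yields one call per gene; focal intragenic
  events smaller than the dominant overlap are invisible at gene level.
* Frequency testing treats intervals independently; no spatial
  smoothing or peak calling (GISTIC-style significance is a non-goal).
* The per-interval midpoint rule can mislabel an interval whose
  midpoint sits in a short neutral segment inside a larger aberration.
* Proportional hazards is assumed, not tested, beyond the errors the
  fitter raises; time-varying effects and competing risks are out of
  scope.
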