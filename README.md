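# lohcna

Downstream analysis of allele-specific copy-number profiles in tumor
cohorts, built around the question of whether **loss of heterozygosity
(LOH) at a driver locus — KRAS in early-stage lung adenocarcinoma —
carries prognostic information** beyond mutation status.

The package consumes ASCAT-style segment tables (per-segment major and
minor allele copy numbers, plus per-tumor ploidy ψ and tumor cell
fraction) and implements the full analysis chain:

- **Ploidy-adjusted calling.** For a segment with total copy number
  *n* = n_major + n_minor, the ploidy-adjusted copy number is
  round(*n* − ψ) (half away from zero). Values ≥ 1 are gains, ≤ −1
  losses, 0 neutral. A segment has **LOH** when n_minor = 0 and
  n_major ≥ 1; **copy-neutral LOH** when additionally the adjusted copy
  number is 0; total copy number 0 is flagged as homozygous deletion
  (not LOH — no allele remains).
- **Genome instability index.** GII = (probes in gained or lost
  segments) / (probes in any segment), per tumor.
- **Gene-level projection.** Each gene takes the call of the segment
  with the largest base-pair overlap (ties: more extreme |adjusted CN|,
  then LOH, then leftmost), yielding a gene × sample call matrix and
  hotspot-panel summaries (KRAS, EGFR, TP53, ALK, ERBB2, BRAF, MET,
  RET, ROS1, NTRK1-3, STK11, PIK3CA).
- **Genome-wide frequency tracks.** Per 15-kb interval, the fraction of
  samples gained/lost (midpoint rule), compared between KRAS-LOH groups
  with the two-proportion z-test (`prop.test` semantics).
- **Association statistics.** Pearson chi-square (with or without Yates
  correction), Fisher's exact test with the sample odds ratio ad/bc,
  Welch t-test, and Benjamini–Hochberg FDR adjustment.
- **Expression integration.** Per-gene Pearson correlation of copy
  number with log2 expression (BH q-values, r and q selection
  thresholds), LOH-group differential expression with cross-cohort
  intersection, and nearest-centroid molecular subtyping (TRU / PP /
  PI).
- **Survival analysis.** Kaplan–Meier curves, log-rank tests, Cox
  proportional-hazards models (Efron ties; univariate, multivariate,
  and bivariate scans with KRAS LOH fixed), and stratified reports over
  LOH × mutation combinations.
- **Synthetic cohorts.** A generator that emits complete cohorts
  (segments, probes, refFlat annotation, expression, clinical tables)
  with planted, recorded ground truth — KRAS LOH prevalence, GII group
  means, copy-number–expression slope, differential-expression shifts,
  subtype structure, and a proportional-hazards LOH effect — so the
  whole pipeline is testable end to end without external data.

## Worked example

```r
library(lohcna)

spec   <- cohort_spec(n_samples = 150, seed = 20)
cohort <- generate_cohort(spec)

profiles <- filter_by_cellularity(cohort$profiles, min_fraction = 0.20)
called   <- call_profiles(profiles)
calls    <- cohort_gene_matrix(called, cohort$genome$genes)

kras_loh <- gene_flag(calls, "KRAS", "loh")
mean(kras_loh)                         # 0.253 -> 25.3% KRAS LOH

gii <- sapply(called, function(p)
  genome_instability_index(p, cohort$genome$probes)$value)
round(c(mean(gii[kras_loh]), mean(gii[!kras_loh])), 2)  # 0.62 vs 0.45
two_sample_t(gii[kras_loh], gii[!kras_loh])$p_value     # 1.3e-06

tab <- build_contingency(ifelse(kras_loh, "LOH", "no_LOH"),
                         cohort$clinical$kras_mut)
fisher_exact_2x2(tab)[c("estimate", "p_value")]  # OR 1.43, p 0.43

cox_fit(cohort$clinical$os_time, cohort$clinical$os_event,
        data.frame(kras_loh = unname(kras_loh[cohort$clinical$sample])))
#> Cox PH fit (Efron ties): n = 150, events = 102
#>          term    hr            ci p_value
#>  kras_lohTRUE 0.614 (0.379-0.996)  0.0481
```

Reading of the output: a quarter of the synthetic tumors carry KRAS
LOH; those tumors are measurably more unstable (higher GII); LOH and
mutation are not significantly associated in this small draw; and the
Cox model recovers the protective LOH effect planted by the generator
(hazard ratio 0.61, true value 0.65).

For real data, replace the generator by the readers:
`read_segment_profiles()`, `read_gene_annotation()` (refFlat),
`read_probe_map()`, `read_expression_matrix()`, `read_clinical()`.

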