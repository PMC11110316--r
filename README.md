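# semimeth

Methylome landscape and telomere-length analysis for large B-cell lymphoma
(LBCL) cohorts.

Large B-cell lymphomas carry an unusually large fraction of *semimethylated*
CpGs — sites whose beta value (the methylated fraction of DNA copies,
0 ≤ β ≤ 1) falls between the two peaks of the normally bimodal array
distribution — and subgroups with heavy global hypomethylation or short
telomeres have worse outcomes. `semimeth` implements the computational
chain needed to measure and stratify these features on a cohort:

- **CpG exclusion filtering** — sex chromosomes, detection p > 0.05, SNP
  proximity, multi-mapping probes, mQTLs, duplicates — with a per-rule
  removal report (`filter_cpgs()`).
- **Methylation partition** — hypomethylated (β < 0.15), semimethylated
  (0.15 ≤ β ≤ 0.8), hypermethylated (β > 0.8), per sample and per CpG, with
  mean-β and IQR summaries, plus quartile/median cohort grouping
  (`sample_partition()`, `cpg_partition()`, `quantile_groups()`).
- **Methylation Variability Score (MVS)** — each sample's Δβ against a
  normal B-cell baseline is kernel-density estimated (Gaussian kernel,
  bandwidth 0.01, 1024 grid points on [−1, 1]) and scored against a normal
  germinal-center B-cell reference density by the trapezoid-rule area
  between the curves: MVS = ∫|f_case − f_ref|dx ∈ [0, 2], 0 meaning
  no difference from the reference (`mvs_scores()`).
- **CIMP classification** — CIMP− iff at most 25% of a fixed panel's CpGs
  have β > 0.4 (`classify_cimp()`).
- **Differential methylation** — DM-CpGs at mean |Δβ| ≥ 0.2 (or 0.3 / 0.4),
  entity-unique sets, and the CGI enrichment filter retaining islands
  hypermethylated in ≥ 70% of the high-hypomethylation group and ≤ 30% of
  the rest (`select_dm_cpgs()`, `unique_dm_cpgs()`,
  `cgi_enrichment_filter()`, `cgi_metrics()`).
- **Relative telomere length** — qPCR triplicates to T/S = 2^−ΔCT, per-run
  calibrator division to RTL, then double-LOESS age standardization against
  a control cohort: RTL_sres = (RTL − μ̂(age)) / σ̂(age), categorized
  short (< −3) / normal / long (> 3) (`ts_ratio()`, `compute_rtl()`,
  `fit_rtl_controls()`, `standardize_rtl()`, `rtl_pipeline()`).
- **Survival analysis** — disease-specific and progression-free survival
  tables, reverse Kaplan–Meier follow-up, univariable/multivariable Cox
  proportional-hazards screens with log-rank tests (`survival_table()`,
  `median_followup()`, `fit_cox_models()`).
- **Synthetic data** — seeded generators for every input the pipeline
  consumes: beta matrices with controlled mixture archetypes, annotations
  and detection p values, qPCR plates with calibrators, age-structured
  control cohorts, and clinical outcome sheets with exact proportional
  hazards (`simulate_methylome()`, `simulate_telomere()`,
  `simulate_clinical()`).

The methods vignette (`vignettes/methylome-telomere-methods.Rmd`) documents
the model assumptions, parameter choices and numerical conventions in
detail.

## Worked example

```r
library(semimeth)

cfg <- methylome_sim_config(
  n_cpgs = 20000,
  n_samples_per_group = c("normal-B" = 10, "normal-GC-B" = 1,
                          "DLBCL-GC" = 8, "DLBCL-nonGC" = 6, "PCNSL" = 4),
  seed = 2024)
x <- simulate_methylome(cfg)
flt <- filter_cpgs(x)
flt
#> <cpg_filter_result> 20000 CpGs in, 18402 surviving
#>   sex_chrom: 600
#>   detection: 557
#>   snp: 178
#>   multimap: 100
#>   mqtl: 163
```

Per-sample partition, MVS against the normal baseline, and quartile groups:

```r
part <- sample_partition(flt$data)
head(part[, c("sample_id", "pct_hypo", "pct_semi", "pct_hyper", "mean_beta")], 2)
#>     sample_id pct_hypo pct_semi pct_hyper mean_beta
#> 1 normal-B_01    26.75    20.49     52.76    0.6119
#> 2 normal-B_02    26.70    20.57     52.73    0.6130

mv <- mvs_scores(flt$data, baseline_group = "normal-B",
                 reference_sample = "normal-GC-B_01")
head(mv, 2)
#>     sample_id   mvs n_cpgs
#> 1 DLBCL-GC_01 0.335  18402
#> 2 DLBCL-GC_02 0.337  18402

quantile_groups(setNames(part$pct_hypo, part$sample_id))
#> <quantile_groups> scheme=quartile; cutpoints: Q1=24.818, Q3=26.753
#>   <Q1 Q1-Q3   >Q3
#>     6    17     6
```

The percentages are each sample's share of hypo/semi/hypermethylated CpGs
(they sum to 100 over non-missing sites); an MVS of 0.34 means about a
sixth of the maximal possible density separation (2) from the reference
profile; the quartile labels stratify the cohort by hypomethylation burden.

Telomere chain, from simulated CT plates to categories:

```r
sim <- simulate_telomere(telomere_sim_config(
  n_cases = 6, case_sres_targets = c(-4, -1, 0, 1, 4, 10), seed = 3))
model <- fit_rtl_controls(sim$controls)
rtl_pipeline(sim$plate, sim$cases, model)
#>   sample_id   rtl  age rtl_sres category
#> 1  case_001 0.204 65.2  -4.0124    short
#> 2  case_002 0.686 61.2  -1.0914   normal
#> 3  case_003 1.141 26.4  -0.0647   normal
#> 4  case_004 1.329 15.1   1.0367   normal
#> 5  case_005 1.601 26.7   3.6725     long
#> 6  case_006 2.446 35.7  10.0820     long
```

The recovered standardized residuals track the configured targets up to the
0.05-cycle CT noise. Survival stratification by a methylation group label:

```r
ccfg <- clinical_sim_config(
  hazard_multipliers = c("Hypo<Q1-Q3" = 1, "Hypo>Q3" = 4),
  baseline_hazard = 0.05, censoring_rate = 0.25,
  follow_up_horizon = 17, seed = 5)
cl <- simulate_clinical(ccfg, rep(c("Hypo<Q1-Q3", "Hypo>Q3"), c(42, 14)))
st <- survival_table(cl, endpoint = "dss")
median_followup(st)
#> [1] 17
fit_cox_models(st, "entity")
#> Proportional-hazards screen (univariable, endpoint DSS)
#>  covariate   level  n events  hr ci_low ci_high   p_wald p_logrank
#>     entity Hypo>Q3 14     11 4.3   1.92    9.67 0.000409   0.00014
```

A hazard ratio of 4.3 (95% CI 1.9–9.7) against the configured 4 shows the
estimator recovering the simulated excess risk of the high-hypomethylation
group.

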