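---
title: "Methods: semimethylation landscape, methylation variability, and age-standardized telomere length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semimethylation landscape, methylation variability, and age-standardized telomere length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semimeth)
```

# Scope and model of the data

`semimeth` analyses two kinds of measurements made on the same lymphoma
cohort: genome-wide methylation-array beta values and qPCR telomere
measurements, and carries both through to survival stratification. The
substrate of the methylation half is a CpG-by-sample matrix of beta values —
the fraction of methylated copies of each CpG in each sample, in [0, 1] —
with a manifest-style CpG annotation (chromosome, position, relation to CpG
islands, gene-region labels, exclusion flags) and a sample sheet. Array data
are assumed to be normalized upstream; this package starts where
normalization ends, at the exclusion filters, and deliberately implements
no probe-chemistry correction.

# CpG exclusion filtering

`filter_cpgs()` applies the standard pre-processing exclusions in a fixed
order: sex-chromosome CpGs, CpGs with a detection p value above 0.05,
CpGs within 5 bp of a known SNP, multi-mapping probes, mQTL CpGs, and
duplicated CpGs mapping to the same gene and position. Each CpG is counted
under the first rule that removes it, so per-rule counts plus survivors
always equal the input count, and filtering is idempotent.

Two choices here were genuinely open. The detection rule is applied
per-any-sample: a CpG fails if any sample's detection p exceeds the
threshold. A single stated threshold admits both a per-any-sample and a
per-proportion reading; the strictest one is used because it is the only one
that needs no additional parameter. Duplicate resolution keeps the
lexicographically smallest CpG id, a deterministic tie-break with no
scientific content. SNP, multimap and mQTL provenance lists are external;
the package consumes boolean flags in the annotation rather than performing
database lookups.

# The hypo/semi/hyper partition

The beta distribution of a methylation array is bimodal, with peaks near 0
and 1. The partition names the peak near 0 *hypomethylated* (beta < 0.15),
the peak near 1 *hypermethylated* (beta > 0.8) and the low-density region
between them *semimethylated* (0.15 <= beta <= 0.8, both boundaries
included); semimethylation indicates that copies of a CpG are differentially
methylated within a sample, and its inflation is the lymphoma-specific
signal this package is organized around. `sample_partition()` computes
per-sample class counts and percentages over non-missing values (so
percentages stay comparable across samples with different missingness);
`cpg_partition()` reassigns classes from each CpG's cohort mean and reports
the per-CpG interquartile range, the cohort's measure of intertumor
variability. Both thresholds are parameters of `partition_thresholds()`,
not constants, but the defaults are the definition.

Cohort stratification uses `quantile_groups()`: quartile labels
(`<Q1`, `Q1-Q3`, `>Q3`) for the partition percentages and mean beta, and
median labels for age-like scores. Quantiles use linear interpolation
between order statistics (R's default type 7); the exact convention is not
externally fixed, so it is pinned and documented here for reproducibility.
Quantiles are always computed on a reference cohort — the full cohort — even
when only a treated subset is being labeled, which is why the function
separates `values` from `reference`.

# CpG island metrics and the enrichment filter

`cgi_metrics()` restricts to island-annotated CpGs (optionally further to
promoter-associated CpGs: TSS1500, TSS200, 5'UTR, 1stExon), computes each
sample's island mean beta, and calls an island hypermethylated in a sample
when its per-sample aggregate exceeds the hyper threshold. The aggregate is
the island's mean beta by default, mirroring the island-mean usage of the
headline metric; whether the published percent-of-hypermethylated-CGIs
figure is island-mean-based or any-CpG-based is not stated, so both rules
are implemented (`island_rule = "mean"` / `"any"`) with mean as default.
Islands are grouped by an `island_id` column when the manifest provides one,
else by contiguous runs of island annotation within a chromosome — manifests
differ in island keys, and the run rule is the weakest assumption that still
yields islands.

`cgi_enrichment_filter()` then retains islands hypermethylated in at least
70% of a high-risk group (hypomethylation above the cohort's third quartile)
and in at most 30% of the remaining cases, both boundaries inclusive, and
reports the unique genes touched. Gene association of an island is the union
of its member CpGs' gene symbols, since manifests map CpGs, not islands, to
genes.

# The Methylation Variability Score

For each sample, the per-CpG difference against a baseline profile (the
per-CpG mean over normal B-cell samples) is summarized as a kernel density:
Gaussian kernel, bandwidth 0.01, evaluated at 1024 equally spaced points
spanning [-1, 1] inclusive — 1023 subintervals, which is why both endpoints
are on the grid. The Methylation Variability Score of a sample is the
trapezoid-rule integral of the absolute difference between its density and
the reference density (a normal germinal-center B-cell sample's density
against the same baseline):

$$\mathrm{MVS} = \int_{-1}^{1} \left| f_{\text{case}}(x) - f_{\text{ref}}(x) \right| \, dx$$

Reading "difference in area under the curve" as the area *between* the
curves is a design decision: both densities integrate to ~1, so a signed
difference of areas would be ~0 for every sample, incompatible with scores
spanning 0 to ~0.9 across a cohort. Under the absolute reading the score is
a bounded pseudometric: zero exactly on identical curves, symmetric,
triangle inequality on the grid, and at most 2 (plus a negligible term for
kernel mass smoothed past the grid ends; with bandwidth 0.01 this matters
only for |delta-beta| within ~0.03 of the boundaries, which cannot occur for
beta-valued differences below 0.97 in magnitude). Moving a fraction f of the
case's delta-beta mass to a location disjoint from the reference mode raises
the score by about 2f, which is the calibration the tests check at
f = 0.1, 0.5, 1. No boundary correction is applied at the grid ends, and
the kernel and bandwidth are not adaptive — the fixed-grid, fixed-bandwidth
estimator *is* the statistic.

# CIMP classification

`classify_cimp()` evaluates a fixed promoter-CGI panel: per sample, the
fraction of evaluable panel CpGs with beta strictly above 0.4; at most 25%
means CIMP-negative, otherwise CIMP-positive. Both boundaries matter and are
tested: a fraction of exactly 0.25 is negative, and beta exactly 0.4 does
not count as exceeding. Panel CpGs absent from the filtered matrix are
dropped from the denominator rather than imputed — panels are intersected
with filtered array data in practice — and a coverage guard warns when less
than half the panel is present, since a fraction over a handful of CpGs is
not a phenotype call. How missing within-sample panel values were originally
handled is unstated; dropping them from the denominator is the assumption
used throughout.

# Differential methylation

`select_dm_cpgs()` selects CpGs by inclusive threshold on the absolute
difference of group means (missing values excluded per group; CpGs with
fewer than two evaluable samples in either group are skipped with a
warning). Thresholds are nested by construction — the 0.3 set is a subset of
the 0.2 set — and the selection is verified against an exhaustive loop in
the tests. `unique_dm_cpgs()` computes entity-unique sets as plain set
differences against the union of the other entities' sets; uniqueness makes
the outputs pairwise disjoint, which is asserted rather than assumed.

# Relative telomere length and age standardization

The qPCR chain is: replicate cycle thresholds are aggregated per target
(arithmetic mean by default; a median mode exists because triplicates are
stated but the aggregator is not), `ts_ratio()` forms
$T/S = 2^{-\Delta CT}$ with $\Delta CT = CT_T - CT_S$, `compute_rtl()`
divides by the calibrator line's T/S within each run and averages the runs.
Per-run division before averaging is adopted; the alternative order is not
fully explicit in the source method, and per-run division is the one that
cancels run-level efficiency shifts.

Age standardization is the one component with a genuinely model-like
interface, and it is exposed in the classic R idiom: `fit_rtl_controls()`
returns an `"rtl_control_model"` with `predict()`, `residuals()`,
`summary()` and `plot()` methods. The model is a double local regression on
a healthy control cohort: LOESS of RTL on age gives the local mean and
residuals; LOESS of the squared residuals on age gives the local variance,
whose square root is the local SD; a case is standardized as
$(\mathrm{RTL} - \hat\mu(\text{age})) / \hat\sigma(\text{age})$, and
categorized short / normal / long at standardized residuals below -3,
between -3 and 3 inclusive, and above 3.

LOESS settings are span 0.75, locally quadratic. The mean curve uses robust
(bisquare) reweighting with two iterations so single outlying controls do
not bend it. The variance curve deliberately does **not**: squared residuals
are strongly right-skewed, and bisquare downweighting of their tail would
estimate something well below the local variance — by roughly a third in SD
terms for Gaussian noise — breaking the property that controls standardized
against their own model have unit SD. Plain least squares is unbiased for
the local variance and is used instead. Fitted variances are floored at
1e-8 before the square root (local quadratic fits can dip below zero), and
ages outside the control support are evaluated at the nearest boundary
rather than extrapolated, since local regression extrapolation is unstable.
All settings are recorded in the fitted object.

# Survival analysis

`survival_table()` derives the two endpoints from a clinical sheet.
Disease-specific survival counts only lymphoma deaths as events; deaths
from other causes censor at the death date — the endpoint definition names
only lymphoma deaths, and censoring is the conventional reading of that
definition (a competing-risks treatment is explicitly out of scope).
Progression-free survival counts progression or relapse at the first
qualifying time. Tables are restricted to one treatment group (default the
R-CHOP-like stratum, the only one analyzed for outcome), while covariate
labels are computed upstream on the full cohort and merged in afterwards —
the order matters, and the interface enforces it by separating `labels`
from the restriction.

`median_followup()` is the reverse Kaplan-Meier estimator (censorings become
events). When the inverted survivor function sits exactly at 0.5 over an
interval, the median is the average of the interval's endpoints — the
quantile convention of the `survival` package, which this package adopts
wholesale rather than reimplementing. `fit_cox_models()` wraps
`survival::coxph` with Efron tie handling (the accurate standard choice) in
univariable mode (one model and one log-rank test per covariate) or
multivariable mode (one joint model); covariate levels with zero events are
retained with a warning, matching how such levels are usually reported
rather than silently dropped.

# The synthetic-data generators

The generators exist so that every stage of the pipeline is exercisable
end to end without any external download, and their defaults are the study
conditions, not tuning knobs.

**Methylome** (`simulate_methylome()`): by default 670,233 CpGs — the
post-filtration CpG count of the cohort — across 28 normal B-cell samples,
one normal GC B-cell sample and 93 lymphoma cases in five entities
(36/30/7/8/12). Each group has a beta-mixture archetype with components
parameterized by (mode, concentration), a bounded-support family that is
natural for beta values; the mode/concentration parameterization
(`shape1 = mode(c-2)+1`) keeps the stated mode the density mode. Default
class weights follow the reported per-entity medians of hypo/semi/hyper
percentages; the source states no distributional parameters beyond figure
shapes, so the extreme-peak concentration (150) and mid-component
concentration (10) are illustrative choices that reproduce the qualitative
picture: sharply bimodal normals, semimethylation-inflated lymphomas. Each
CpG is assigned one component per group (the group's state at that CpG),
and samples within the group draw independently from that component — this
gives coherent per-CpG classes and group-level mean differences, which the
differential-methylation stage needs; `component_links` lets one group
reuse another's assignment so that two groups differ only by sampling
noise, which the MVS ordering tests use. What the generator does *not*
emulate: probe chemistry, batch effects, realistic genomic coordinates,
spatial correlation along the genome, or biologically structured
missingness. Tests passing on this generator show the pipeline's arithmetic
and contracts are right; they do not show the archetypes are calibrated to
any real cohort.

**Telomere** (`simulate_telomere()`): a 174-person control cohort over ages
0-84 (the study's control design) with a linearly declining mean RTL and
mildly age-increasing scatter; 93 cases whose intended standardized
residuals span the reported lymphoma range (-4.7 to 18.9); triplicate T and
S wells in two runs with per-well CT noise (default SD 0.05 cycles, a
realistic qPCR triplicate scatter), and calibrator wells in every run. Case
RTLs are placed at mean + target x SD of the control model *fitted to the
generated controls*, then inverted through the T/S and calibrator
relations into CT values. Construction against the fitted rather than the
true curves is deliberate: it makes the expected recovered residual equal
the target exactly, so the end-to-end CT-to-category round trip is testable
to 1e-6 at zero CT noise instead of only to the O(n^-1/2) fit error. A
run-level CT offset is included and must cancel through the calibrator
division.

**Clinical** (`simulate_clinical()`): disease-death times are exponential
with group-multiplied hazards, so proportional hazards holds exactly and a
configured hazard ratio is a recoverable truth; progression and other-cause
death are independent exponentials scaled off the same group hazard;
censoring is an administrative horizon (default 17 years, matching a
2005-2018 accrual window followed to 2022) plus a random early-censoring
fraction. Because progression is independent rather than forced to precede
death, the data do not guarantee that every lymphoma death has a prior
progression; the event-count ordering between endpoints is therefore tested
on data constructed to satisfy that premise, not on generator output.

All three generators run under a seed that fully determines their output and
is restored afterwards, with substreams derived from one master seed where
several generators share a run.

# Numerical choices and problem sizes

Fixed seeds are used throughout the test suite. Simulation sizes were
chosen as the smallest at which the targeted properties are
well-conditioned: 100,000 CpGs for mixture-weight recovery (binomial SE
0.16 percentage points at weight 0.5, against a 1-point tolerance), 500
controls for variance-curve recovery (SD-of-SD about 3%, against a 10%
band), 500 subjects per group for hazard-ratio recovery (log-HR SE about
0.09, against the [2.5, 3.6] acceptance window), and 20 replicates for the
null log-rank calibration check. Boundary behavior (class cutoffs, the
CIMP fraction, RTL categories) is always tested at the boundary value
itself, and floating-point-exact fixtures are used where an inclusive
threshold is the point (e.g. binary-representable means in the
differential-methylation toy cases).

# Known limitations

The archetype parameters are illustrative, not calibrated; cohort-level
published statistics (per-entity score tables, fitted hazard ratios) are
not reproducible without the patient-level data, and the package does not
attempt them. The MVS absolute-difference reading cannot be verified
against per-sample published values for the same reason, though it is the
only reading consistent with the published score range. Epigenetic-clock
models and the pan-B-cell classifier are consumed, if at all, as external
per-sample scores in the sample sheet; gene-ontology enrichment and figure
pipelines (PCA, heatmaps) are out of scope. Raw-intensity preprocessing and
normalization are upstream of this package by design.
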