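---
title: "Methods: spectral-counting differential expression and survival validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-counting differential expression and survival validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speccount)
```

## The discovery-stage model

Spectral counting treats the number of MS/MS spectra assigned to a protein
as a semi-quantitative abundance measure. `speccount` compares two tissue
groups (primary tumor, PT, and paired liver metastasis, LT) after pooling
counts across all samples of a group. Pooling is the default because the
statistics below are defined on one count pair per protein; with only a
handful of paired cases, a per-case analysis has almost no power at the
protein level. A per-case mode (`mode = "per_case"` in `spectral_dea()`)
is provided for sensitivity analysis: it averages per-case Rsc values,
each computed against that case's own column totals, but keeps the pooled
G-test since the per-case ratios have no tractable null at typical depths.

For protein $i$ with pooled counts $n_{PT}, n_{LT}$ and group totals
$t_{PT}, t_{LT}$:

* **Rsc** $= \log_2\dfrac{n_{LT}+f}{n_{PT}+f} +
  \log_2\dfrac{t_{PT}-n_{PT}+f}{t_{LT}-n_{LT}+f}$. The second term is a
  depth correction, so a protein with the same *relative* abundance in a
  shallower and a deeper run gets Rsc near 0. The pseudo-count $f$ keeps
  one-group-only proteins finite; we use $f = 0.5$, the usual convention
  for this ratio, exposed as an argument because no single value is
  canonical. Reported fold change is $2^{|Rsc|}$.
* **G-test**: the likelihood-ratio test of independence on
  $[(n_{PT}, n_{LT}), (t_{PT}-n_{PT}, t_{LT}-n_{LT})]$, $G = 2\sum O
  \ln(O/E)$ with $0\ln 0 = 0$, referred to $\chi^2_1$. No Williams or
  continuity correction by default (a `correction = "williams"` flag
  exists); at proteome-scale totals the corrections are negligible, and
  the uncorrected statistic is the standard form. Selection uses raw
  $p < 0.05$; Benjamini–Hochberg q-values are always reported alongside
  but deliberately not used for the gate, which reproduces the
  conventional candidate-screening rule rather than a genome-wide error
  control.
* **Candidate gate**: selected $\iff |Rsc| > 1$ **and** $p < 0.05$, both
  strict, so `Rsc = 1.0` exactly is *not* selected. The gate is a pure
  intersection — the two filters are computed independently and composed,
  with no order dependence.
* **NSAF** within each group: $(n_i/L_i)/\sum_j (n_j/L_j)$, with sequence
  length $L_i$ in amino acids from an annotation table or protein FASTA.
  Undetected proteins get NSAF 0; detected proteins with no length are an
  error, never silently dropped.
* **SpI**: with $d$ = number of samples of a group in which the protein
  was detected and $m$ = group size,
  $SpI = \frac{\sum c_{LT}}{\sum c}\frac{d_{LT}}{m_{LT}} -
  \frac{\sum c_{PT}}{\sum c}\frac{d_{PT}}{m_{PT}} \in [-1, 1]$,
  $+1$ iff seen in every LT and no PT sample. The exact published form of
  this index varies; we use the detection-frequency-weighted form above,
  which satisfies the boundary and symmetry behavior expected of it (±1 at
  pure one-group detection, 0 for identical blocks). A protein with no
  detection anywhere has no defined SpI and is returned as `NA`, never 0,
  since 0 means "balanced", not "absent".
* **Sign convention**: positive Rsc and SpI mean LT-enriched. The
  convention is arbitrary and stated here once; both statistics negate
  exactly under group relabeling (property-tested).

NSAF and SpI are reported as secondary screens. No default threshold is
applied to them because no canonical cutoff exists; `spi_min` and
`nsaf_ratio_min` let a user impose one.

Identification ("Venn") summaries call a protein identified in a group iff
its pooled group count is positive — absence must be an explicit zero in
the input, which is why the readers reject missing count cells rather than
imputing 0.

## The validation-stage procedure

The clinical stage evaluates one immunohistochemistry marker (binary
positivity, thresholded upstream at ≥ 10 % stained tumor cells) against
liver recurrence-free survival (liver RFS): time from resection of the
primary tumor to first liver metastasis, in months. Patients with
*synchronous* metastasis (already metastatic at resection) have no liver
RFS by definition and are excluded first.

* **Kaplan–Meier / log-rank** go through `survival::survfit()` /
  `survdiff()`. The KM step function is right-continuous: $S(t)$ at an
  event time already includes that drop, which is the standard
  product-limit convention and what `summary.survfit` reports. Landmark
  survival (default 120 months = 10-year liver RFS) is read off this step
  function; beyond the last follow-up time the last value is carried
  forward. The all-censored cohort is a defined degenerate case
  ($S \equiv 1$, log-rank p = 1), not an error.
* **Cox proportional hazards** via `survival::coxph()` with Efron tie
  handling by default — month-resolution follow-up produces heavy ties,
  where Efron is clearly preferable; Breslow is a flag for comparison.
  Wald 95 % CIs and p-values are reported. Constant covariates are
  flagged non-identifiable (not dropped silently); monotone likelihood
  (perfect separation) is detected from the coxph convergence warnings
  and runaway coefficients and flagged per covariate instead of letting
  an absurd hazard ratio pass; a cohort with zero events raises an
  explicit degeneracy error.
* **ROC cutoffs** for continuous covariates (Ki-67 %, tumor size mm):
  classification is `value >= cutoff`, candidate cutoffs are observed-value
  midpoints plus the all-positive boundary, the chosen cutoff maximizes
  Youden's $J$, and ties in $J$ break toward the *lower* cutoff (the
  conservative choice under a ≥ rule). The AUC is the area under the
  empirical ROC polygon, identical to the Mann–Whitney probability with
  ties counted ½ (asserted against a pair-counting oracle); its p-value
  against 0.5 is the two-sided Mann–Whitney test.
* **Univariate → multivariate gate**: every covariate is screened
  univariately; those with Wald $p < 0.05$ (configurable, plus a
  force-in list) enter the multivariate model. This replicates the common
  clinical-paper procedure; it is not a recommendation of univariate
  screening as model selection.
* **Three-group cohort comparisons** (synchronous / metachronous / none)
  use Pearson χ² without Yates correction by default, falling back to the
  exact (Fisher) test when any expected cell is below 5, where the χ²
  approximation is unreliable. All three groups are tested
  jointly (one p per factor), matching the one-p-value-per-row layout of
  clinical baseline tables. Continuous factors use Kruskal–Wallis
  (Mann–Whitney for two groups).

## What the simulators emulate — and what they do not

`simulate_counts()` draws a per-protein expected per-sample count from a
log-normal law (the long right tail of spectral counts), applies the
planted fold to one group of a `de_fraction` of proteins, adds Poisson
sampling per sample, and then a per-sample Bernoulli detection dropout
whose probability *decreases* with expected count,
$\delta(\lambda) = \delta_{max} e^{-\lambda/s}$. Dropout is what produces
proteins identified in one group only, mechanically reproducing the
identification Venn partition; an `lt_depth_factor` > 1 reproduces the
deeper metastasis proteome and hence the asymmetry of the partition.
Lengths are drawn independently of counts by default (median ≈ 400
residues), with a `length_coupling` option making expected counts
proportional to length, so the NSAF length correction is exercised both
ways.

The packaged calibrated configuration
(`calibrated_count_config()`, frozen in
`inst/extdata/calibrated_count_config.json`) was tuned *once*, by
simulation, so that a 7-case paired experiment yields ~2,600–3,000
identified proteins per group with roughly 20 % / 30 % / 50 %
PT-only / LT-only / shared fractions — the shape of a real paired FFPE
discovery set — and then frozen.

Deliberate simplifications: no correlation between paired samples of a
case beyond the shared expected count; no peptide- or spectrum-level
structure (the simulation starts at per-protein counts); dropout
independent across samples; no batch or run-order effects. Consequently,
passing calibration and recovery tests shows the *statistics* behave as
designed under their own assumptions — it does not show that real FFPE
spectral counts satisfy those assumptions. In particular, abundance-
dependent dropout makes pooled counts over-dispersed relative to the
G-test's implicit binomial model, and with dropout switched on the null
false-selection rate rises above the nominal α, as in real data; the
calibration suites therefore run with dropout off, and the recovery suite
reports the realized false-selection rate.

`simulate_cohort()` assigns synchronous status at baseline
(probability 8/70 by default, matching a 70-patient surgical cohort with
8 synchronous cases), then draws time to liver recurrence for the others
from an exponential proportional-hazards model with planted log hazard
ratios for marker positivity (default $\ln 6.19$) and large tumors
(default $\ln 4.63$ for size ≥ 42 mm), under administrative censoring
(uniform on 6–240 months by default, the span of realistic follow-up).
Whether a patient is "metachronous" or "none" is an *outcome* of this
race; marker positivity is therefore parameterized by a synchronous rate
and a single baseline rate, and the enrichment of positives among
metachronous patients emerges from the planted hazard — specifying a
metachronous-specific positivity rate would be circular. The default
baseline hazard (5 × 10⁻⁴ per month) puts roughly a fifth of
non-synchronous patients into the metachronous group over follow-up,
matching the 12-of-62 shape of the motivating cohort. Overall survival is
an independent exponential clock and carries no planted effect.

## Numerical choices and degenerate inputs

* Pseudo-count $f = 0.5$; strict inequalities at both gate thresholds.
* G computed cell-wise with $0\ln 0 = 0$ and clipped at 0 against
  floating-point underflow; totals are coerced to double to avoid integer
  overflow at proteome-scale depths.
* Candidate ordering: $|Rsc|$ descending, ties by ascending p, then
  accession — a total, reproducible order.
* Empty candidate sets, all-censored cohorts and empty marker strata are
  defined outcomes (empty selection, $S \equiv 1$ with log-rank p = 1,
  flagged stratum with the log-rank skipped); zero-event Cox fits and
  single-class ROC outcomes are errors with explicit diagnostics.
* Reports echo their configuration (minus the output path) and carry an
  MD5 content hash; reruns with the same config and seed are
  bit-identical. All simulator randomness flows through one integer seed,
  and the generators restore the caller's RNG state.

## Problem sizes used by the test and acceptance suites

Chosen as the smallest sizes at which the Monte-Carlo bands are sharp:
G-test size on 10,000 null proteins at ≥ 500 pooled counts per group
(band 0.05 ± 2SE); gate recovery on 4,000 proteins with 5 % planted at
4-fold (sensitivity ≥ 90 % among planted proteins with pooled count ≥ 10,
null false-selection ≤ 5 %); hazard-ratio recovery on 200 cohorts of
n = 2000 with ~35–40 % events (median HR within ±30 % of the planted
6.19, Wald CI coverage ≥ 90 %); exhaustive G-test enumeration over all
2×2 tables with margins ≤ 30; Cox grid-search oracle on ≤ 8 subjects at
step 10⁻⁴.

## Known limitations

* The pooled G-test inherits the usual spectral-counting caveat: pooling
  discards between-case variability, so its p-values are calibrated
  against sampling noise only, not biological replication — the reason
  modern count pipelines model per-sample dispersion. Here the pooled
  test *is* the method being provided; the per-case Rsc mode and the SpI
  (which does use replicate detection frequency) are the mitigations.
* Univariate-gated multivariate Cox models at n ≈ 60 with ~12 events are
  fragile; the wide CIs in the README example are the honest picture.
* The ROC cutoff is a point estimate; no resampling uncertainty is
  attached to it.
* No competing-risks treatment of death before liver recurrence; censoring
  is assumed non-informative.
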