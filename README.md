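# speccount

Label-free spectral-counting differential expression for paired
primary-tumor / metastasis proteomics, with a clinical survival-validation
stage.

## What it does, and for whom

Shotgun (LC-MS/MS) proteomics of paired tissue samples — here primary
pancreatic neuroendocrine tumors (**PT**) and their matched liver
metastases (**LT**) — yields, per protein, a *spectral count*: the number
of MS/MS spectra assigned to it, a label-free proxy for abundance.
`speccount` implements the semi-quantitative comparison stage used to
nominate metastasis-associated candidate proteins from such counts, and the
clinicopathological stage used to validate a candidate as a prognostic
marker in a surgical cohort.

**Discovery stage.** For protein *i* with counts pooled within groups
(`n` per protein, `t` per group), the package computes:

- the spectral-count log2 ratio with pseudo-count `f` (default 0.5),

  `Rsc = log2((n_LT + f) / (n_PT + f)) + log2((t_PT − n_PT + f) / (t_LT − n_LT + f))`

  whose second term corrects for unequal group depth; the reported fold
  change is `2^|Rsc|`, and positive Rsc means LT-enriched;
- the **NSAF** (normalized spectral abundance factor): length-corrected
  relative abundance `(n_i/L_i) / Σ_j(n_j/L_j)` within each group;
- the **SpI** (spectral index), a score in [−1, +1] combining relative
  abundance with detection frequency across the paired cases;
- a per-protein likelihood-ratio **G-test** on the 2×2 table
  `[(n_PT, n_LT), (t_PT − n_PT, t_LT − n_LT)]` with χ²(1) p-values and BH
  q-values;
- the candidate gate: selected ⇔ `|Rsc| > 1` **and** `p < 0.05` (both
  strict), plus identification Venn summaries (identified in a group ⇔
  pooled group count > 0).

**Validation stage.** Given a cohort table with per-patient
immunohistochemistry positivity (positive ⇔ ≥ 10 % of tumor cells
stained), `liver_rfs_analysis()` excludes patients whose liver metastasis
was already present at resection (synchronous), then runs Kaplan–Meier
liver recurrence-free survival by marker positivity with a log-rank test,
ROC/Youden cutoff discovery for Ki-67 and tumor size, univariate Cox
screening of all covariates, and a multivariate Cox model over the
univariately significant ones (Efron ties, Wald 95 % CIs, with
separation/degeneracy diagnostics).

Seeded generators (`simulate_counts()`, `simulate_cohort()`) produce
synthetic count matrices and cohorts with known planted effects, so every
stage can be tested for calibration and parameter recovery.

## Worked example

```r
library(speccount)

# a 7-case paired experiment with 5% of proteins planted at 4-fold
cfg <- count_sim_config(n_proteins = 2000, n_cases = 7,
                        baseline_meanlog = log(5), baseline_sdlog = 1.2,
                        de_fraction = 0.05, de_fold = 4,
                        dropout = list(type = "expcount", max = 0.5, scale = 10),
                        seed = 42)
sim <- simulate_counts(cfg)
fit <- spectral_dea(sim$matrix, sim$annotation)
fit
#> Spectral-counting differential expression
#>   samples: 7 PT + 7 LT; pooled depth 131111 (PT) / 181995 (LT)
#>   proteins: 1991 (PT only 33, LT only 24, shared 1934)
#>   gate: |Rsc| > 1 and G-test p < 0.05 (f = 0.5, pooled mode)
#>   selected: 294 (137 PT-overexpressed, 157 LT-overexpressed)

head(summary(fit)[, c("accession", "n_PT", "n_LT", "Rsc", "fold_change",
                      "direction", "p", "SpI")], 3)
#>      accession n_PT n_LT   Rsc fold_change direction        p    SpI
#> 1628   SP01628    0   47  6.10        68.5        LT 9.21e-13  0.857
#> 1836   SP01836   23    0 -6.03        65.3        PT 2.48e-10 -0.714
#> 1666   SP01666   13    0 -5.23        37.5        PT 1.96e-06 -0.429
```

The fit prints the identification partition, the pooled depths that enter
the Rsc depth correction, and how many proteins pass the candidate gate in
each direction; the summary table is sorted by |Rsc| (top rows here are
one-group-only proteins kept finite by the pseudo-count). From published
set sizes alone, the same Venn arithmetic is available directly:

```r
venn_from_sizes(2622, 2993, 1893)
#> Identified proteins: 3722 total
#>   PT only:   729 (19.6%)
#>   LT only:  1100 (29.6%)
#>   shared :  1893 (50.9%)
```

Validation on a simulated 70-patient cohort with a planted marker hazard
ratio of 6.19:

```r
co  <- simulate_cohort(cohort_sim_config(n_patients = 70, seed = 7))
res <- liver_rfs_analysis(co$cohort, "M1")
res
#> Liver recurrence-free survival analysis: marker M1
#>   64 patients analyzed (6 synchronous excluded), 14 recurrences
#>   cutoffs: Ki-67 >= 3.55%, tumor size >= 36 mm
#>   negative stratum: S_120m = 91.3%
#>   positive stratum: S_120m = 66.6%
#>   log-rank p = 0.03593
#>   ...
```

`S_120m` is the Kaplan–Meier estimate read off the step function at 120
months, i.e. 10-year liver RFS per stratum; the multivariate block lists
hazard ratios with Wald 95 % CIs for every covariate that passed the
univariate `p < 0.05` gate. At n = 64 the marker CI is wide — recovery of
the planted hazard ratio is demonstrated at n = 2000 in the test suite and
acceptance script.

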