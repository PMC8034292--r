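---
title: "memscreen: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{memscreen: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memscreen)
```

This vignette documents the statistical models the package implements, the
thresholds and parameters a user can turn, the numerical choices made where
the method descriptions left room, and what the synthetic-data generators do
and do not emulate.

## Label-free normalization

Protein-level quantification tables exported from an identification engine
carry one raw precursor peak-area column per biological replicate. Signal
intensity differs between LC-MS/MS runs for reasons unrelated to biology
(injection amount, spray stability), so each replicate column is scaled to
parts-per-10⁶ of its own total identified area:

$$\mathrm{NormalizedArea}_{ij} = \frac{\mathrm{Area}_{ij}}{\sum_k \mathrm{Area}_{kj}} \times 10^6 .$$

Two representational decisions matter here:

* **Missing versus zero.** A search engine reports *no* area for a protein
  it did not identify in a run, so an empty cell means "not identified",
  not "abundance zero". Literal zeros are coerced to missing on ingest, and
  missing cells are excluded from the total-area denominator, from means
  and from SDs. This keeps the normalization denominator an honest
  "total identified signal of this run".
* **Per-run totals.** Normalization is per replicate column, never per cell
  line: the denominator is a property of one LC-MS/MS run.

Normalization is exactly conserving (each column sums to 10⁶ over present
values), scale-invariant, and idempotent; the test suite asserts all three
on randomized tables (100 tables of 10–80 proteins × 2–6 replicates) at
10⁻⁹ relative tolerance.

## Replicate summaries

Per protein the package reports the number of replicates at or above the
detection floor, the mean and the sample standard deviation (n − 1
denominator) over *identified* replicates, and the percent coefficient of
variation 100·SD/mean. The n − 1 choice is the package's own: with four
biological replicates the sample SD is the standard estimator, though
published candidate tables rarely state which denominator they used. CV is
reported as undefined (NA) with fewer than two identified replicates or a
zero mean, and a protein with an undefined CV can never pass the CV filter.

## The candidate screen

The screen composes four rules, all thresholds inclusive and configurable
via `screen_config()`:

| parameter | default | meaning |
|---|---|---|
| `detection_threshold` | 70 | normalized-area floor (ppm-like units) for calling one replicate a detection |
| `presence_fraction` | 0.75 | fraction of cancer replicates that must reach the floor (3 of 4 passes: the comparison is ≥) |
| `control_min_detected_reps` | 3 | replicates at the floor that define *expression* in the benign control line |
| `cv_max_percent` | 40 | ceiling on replicate %CV of a candidate |
| `top_n` | 30 | length of the ranked candidate table |

"Exclusive to the cancer line" is operationalized as *failure of the
control expression rule* — fewer than three control replicates at the
floor — not as total absence from the control table. A protein seen once
at trace level in the control is still a candidate; this matches how
detection limits are actually used in label-free screens, and the
threshold-based reading is exactly what the trace mode of the synthetic
generator exercises.

Unannotated proteins are dropped from the membrane refinement (and
counted); candidates are ranked by mean normalized area descending with
ties broken lexicographically by accession so tables are reproducible.
Because every rule is a threshold on a per-protein statistic, the
candidate count is non-increasing as any threshold tightens; the test
suite asserts this monotonicity over randomized configurations.

## Tissue-microarray association

IHC scores on the 1–4 ordinal scale are dichotomized two ways: the
*intensity* rule (1–2 low, 3–4 high) follows the usual low/high expression
convention, while the *positivity* rule (1 negative, 2–4 positive) is the
default for positive-versus-negative association tables. The mapping of
score 2 is genuinely underdetermined by most published table footings; the
package makes it configurable and records the rule in every report. For the
bundled STEAP4 cohort, only the positivity rule reproduces the published
20-of-41 positive carcinoma count.

Association uses the Pearson chi-square statistic with **no continuity
correction**, p from the upper chi-square tail at (r−1)(c−1) df. The
no-correction choice was verified against the published association table:
the lymph-node 2×2 [[7,13],[13,7]] gives the printed p = 0.0578 uncorrected
but ≈ 0.11 with Yates' correction. Cases missing the covariate under test
are dropped for that comparison only, never imputed — which is why the
per-covariate case counts (41, 34, 30, 40, 35, 35) fall below the cohort
size. Expected counts below 5 raise a flag but do not switch the test,
matching the published analysis (the benign-versus-cancer table's smallest
expected count is ≈ 5.9).

`chi_square_permutation_p()` provides an independent Monte-Carlo oracle:
tables drawn from the fixed-margin independence null via
`stats::r2dtable()`. That null is discrete, and the tie mass at the
observed statistic is not negligible at cohort-scale N, so the oracle
reports both the conventional tie-inclusive p and the mid-p (half the tie
mass), the quantity a continuous approximation actually targets. Even so,
the chi-square tail approximation deviates from the exact conditional
mid-tail by up to ~0.01–0.1 for 2×2 tables with N ≤ 60 — users comparing
the analytic p against exact or Monte-Carlo conditional tests should
expect discrepancies of that order, which is a property of the chi-square
approximation, not an implementation artifact.

The bundled cohort `steap4_tma_cohort()` is a deterministic case-level
reconstruction from published per-covariate margins. Covariate columns are
assigned independently within the positive and negative groups, so every
2-way covariate-by-expression table is exact while the joint distribution
across covariates is synthetic — sufficient for everything the association
analysis computes, but not a real patient-level dataset.

## Dose-response pharmacology

Viability is the background-corrected absorbance (OD570 − OD650) divided
by the vehicle mean, floored at zero (negative corrected signal is noise),
not capped above one (growth stimulation is real signal). The
four-parameter logistic model

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}{1 + (x/\mathrm{IC50})^{h}}$$

is fitted by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) on
the log₁₀-dose scale, since study doses span 3.5 orders of magnitude
(0.01–30 µM). Numerical choices:

* **Initialization** — top and bottom at the extreme mean responses, IC50
  at the dose whose mean response is nearest the half-maximum, Hill
  slope 1.
* **Bounds** — log₁₀ IC50 within [min dose / 100, max dose × 100]; Hill
  slope in [0.1, 10]. IC50 estimates beyond the tested dose ceiling are
  flagged `ic50_extrapolated` (relevant for weakly cytotoxic agents such
  as iron chelators alone, whose reported IC50s can exceed the tested
  range).
* **Degenerate data** — a fitted span |top − bottom| < 0.05 flags the IC50
  unidentifiable; downstream comparisons then refuse to produce a p-value.

**Per-experiment IC50s and the combination test.** With several
independent experiments the default is a *global* fit sharing bottom, top
and Hill slope across experiments while letting log₁₀ IC50 vary per
experiment — the shared-parameter mode standard curve-fitting software
offers. The alternative, fitting each experiment completely independently
(`share_shape = FALSE`), roughly doubles the per-experiment IC50 spread in
the three-experiment designs this package targets, because each small fit
must re-estimate the curve shape and shape–IC50 compensation inflates the
IC50 variance. With only three experiments per arm the comparison t-test
has 4 degrees of freedom, where the two-sided critical value at
α = 0.001 is 8.61; an estimator that wastes per-experiment precision
makes even a 2.3-fold IC50 shift undetectable at that level. The t-test
itself is run on log₁₀ IC50s (equal-variance, two-sided): IC50 estimates
are log-normally distributed, so the log scale is where their spread is
symmetric and a location test is appropriate. Even with these choices the
detection probability of a 2.3 → 1.0 µM shift at α = 0.001 under the
simulated design (8 doses, 3 × 3 wells, noise SD 0.05) sits near the
theoretical ceiling of the design — a noncentral-t calculation with the
information-bound per-experiment log-IC50 SD (~0.033) gives ≈ 0.95 — so
single-digit shortfalls from 95% are expected and reflect the design, not
the fit.

## What the synthetic generators emulate

`sim_quant_experiment()` draws a shared universe of (by default) 2300
proteins, 26% membrane-annotated, echoing a typical membrane-enriched
identification depth of ~2300 proteins with ~600 membrane-associated. Raw
abundances are log-normal (meanlog 13, sdlog 1.5, arbitrary intensity
units); replicate noise is multiplicative log-normal at a 20% target CV,
loosely calibrated to the 10–40% CVs printed in published candidate
tables and user-overridable; dropout is logistic in log-abundance
(data-dependent acquisition misses low-abundance proteins preferentially)
with a uniform-rate shortcut for controlled experiments. Thirty
cancer-exclusive membrane proteins per cancer line are planted with
abundances drawn from the upper half of the distribution times a boost
factor (default 8) — planted candidates emulate the *abundant* exclusives
a top-30 table reports, and the draw guarantees they clear any sensible
detection floor. Control-side absence is true absence by default (the
protein contributes no rows); a trace mode instead plants sub-threshold
control signal to exercise the threshold-based exclusivity rule.

The generators do **not** emulate: peptide-level roll-up, shared peptides,
retention-time alignment artifacts, batch effects between replicates,
correlated dropout, or the identification/FDR layer. A passing recovery
test therefore demonstrates that the screening logic is sound, not that
the thresholds are optimal for any particular instrument or search engine.

`sim_tma_cohort()` draws benign and carcinoma cases (defaults 18/42) with
group positivity probabilities (defaults 0 and 0.49); carcinoma positivity
follows a logistic model so per-covariate odds ratios can be planted, and
positive cases receive scores 2–4 with configurable weights.
`sim_dose_response()` adds Gaussian noise (default SD 0.05) to exact 4PL
curves on an 8-point log-spaced 0.01–30 µM grid, three experiments in
triplicate, truncated at zero viability.

## Problem sizes used by the test suite

The suite runs full-scale screening worlds (2300 proteins × 4 replicates
× 3 lines) for the deterministic recovery check and for 20-seed dropout
recall; 100 seeds for IC50 recovery and 200 for shift detection; 100
randomized tables for normalization properties; and 100,000-draw
permutation nulls for the chi-square oracle. These sizes were chosen so
each stochastic assertion has comfortable Monte-Carlo margin while the
whole suite stays interactive.

## Known limitations

* The screen treats cell lines independently; there is no shared-variance
  or moderated-statistics machinery (this is a presence/threshold screen,
  not a differential-expression model).
* The chi-square analysis is the classical unconditional approximation;
  exact conditional inference is available only as the Monte-Carlo oracle.
* The 4PL machinery assumes homoscedastic additive noise on the viability
  fraction; weighting is not implemented.
* The bundled TMA cohort reproduces published margins, not patient-level
  data; cross-covariate structure in it is arbitrary.
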