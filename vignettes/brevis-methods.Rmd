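---
title: "Methods: scoring, demographic correction and regression-based norming for the BReViS test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, demographic correction and regression-based norming for the BReViS test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brevis)
```

## The test and its scoring model

The BReViS test is a four-card cancellation task: on every card the examinee
crosses out the 25 Landolt rings whose gap matches a target orientation,
among distractor rings. The cards cross two factors — layout (linear:
cards 1–2; random: cards 3–4) and crowding (low: cards 1 and 3; high:
cards 2 and 4) — so that contrasts between cards isolate components of
visual attention.

Accuracy and speed are folded into a single per-card **performance time**.
A participant who missed `om` of the 25 targets effectively searched
`25 - om` targets in the recorded execution time `t`, so

$$P = \frac{25\,t}{25 - om}.$$

`P` is undefined at `om = 25` (nothing was searched); the package raises a
scoring error naming the offending card, because no index can be computed
for that participant. From `P1..P4` the indexes are `SA = P1`,
`OA = (P3+P4)/2 - (P1+P2)/2`, `FA = (P2+P4)/2 - (P1+P3)/2`, and `Err`, the
error count. Two algebraic properties are worth noting (both are tested):
`OA` and `FA` are invariant under adding a constant to all four cards, and
`SA + OA + FA = P4` holds identically — the contrast terms telescope — so
the three time indexes always reconstruct card 4 exactly.

**What counts as an error.** The published materials record omissions,
substitutions and autocorrections but define `Err` only as "the sum of all
errors". This package counts `Err = omissions + substitutions` over the four
cards and excludes autocorrections: an autocorrected response was ultimately
correct, and under the test's "do not go back" instruction an autocorrection
is a procedure deviation rather than a search failure. Autocorrections are
still stored and reported separately, so users who prefer the inclusive
definition can add them back.

## Demographic correction and classification

Raw indexes are corrected by adding a regression-based correction score.
Each correction model is a sum of terms
`coefficient * (transform(predictor) - centering constant)`; the embedded
published models use a reflected natural log of age, `ln(86.9 - Age)`, and
inverse education for SA, cubic age for OA and FA, and inverse age, inverse
education and gender (0 = female, 1 = male) for Err. Corrections are 0 at
the normative sample's mean (transformed) demographics by construction.

Hard domain limits are enforced (age ≥ 86.9 makes the SA log term
undefined; education 0 the inverse), but demographics outside the normative
range (ages 20–79, education 1–21) are *allowed* with an explicit
extrapolation flag and warning: refusing an 82-year-old patient outright
would be clinically useless, but the user must know the correction is an
extrapolation.

Classification is a step-function lookup at one-decimal resolution.
Adjusted values are rounded **half away from zero** to one decimal before
lookup — the convention that reproduces every printed grid cell (e.g. an OA
correction of −0.4525 at age 52 prints as −0.5; banker's rounding would give
−0.4) — so the printed band boundaries are unambiguous. Three lookups are
provided per index:

* **Tolerance class**: at or below the inner tolerance limit → within
  limits; at or above the outer limit → pathological; between → borderline.
* **Equivalent score** (ES 0–4): ES 0 begins at the outer tolerance limit,
  the ES 3/4 cut is the normative median, and ES 1–3 partition the range in
  between. ES 0 and "pathological" coincide by construction.
* **Percentile band**: the bracketing printed percentile rank (no
  interpolation); values beyond the printed grid report ">99th"/"<1st".

One harmonization was applied to the embedded tables: the published ES row
for OA prints cuts of 98.9 and 46.3 where the tolerance-limit table's OA
OTL is 98.8 and the printed OA median is 46.2. For the other three indexes
the ES-0 cut equals the OTL and the ES-4 cut equals the 50th-percentile
entry exactly; the OA row deviates from that convention by exactly one
0.1 step in both cells. The embedded OA cuts use 98.8 and 46.2 so that
"ES 0 ⇔ pathological" and "ES-4 cut = median" hold uniformly — the
behaviour a clinician applying the tolerance table would expect.

The published constants ship both embedded in code and as a versioned,
human-readable JSON norm file (`inst/extdata/brevis_norms_published.json`);
`brevis_norms(path)` loads alternative norm sets of the same format, such as
those produced by `build_norms()`.

## The norming pipeline

`build_norms()` reruns the procedure that produced the published tables:

1. **Outlier filtering.** Per card, the threshold is Q3 + 3·IQR of the
   cohort's performance times; a participant at or above the threshold on
   any card is removed casewise. Quartiles use linear interpolation between
   order statistics (`quantile` type 7, the default of mainstream
   statistical software); the convention is recorded in the filter's output
   metadata because the original description does not state one. Thresholds
   are computed once on the input cohort (single pass); an iterated variant
   is available but off by default. A zero IQR on a card yields a warning
   and no removals on that card rather than removing most of the cohort.

2. **Transformation selection.** For each index and predictor, bivariate
   Gaussian regressions of the raw index on candidate transforms are ranked
   by AICc. Candidates are {identity, square, cube, inverse, natural log,
   reflected log `ln(c - x)`} for age and {identity, inverse, natural log}
   for education — the published winners plus standard neighbours. The
   reflected-log offset `c` is profiled over `max(x) + 0.1 … max(x) + 25`
   in 0.1 steps; the published offset 86.9 is embedded verbatim for the
   published model and never re-derived. AICc uses
   `-2LL + 2k + 2k(k+1)/(n-k-1)` with `k` counting intercept, slopes and
   the residual variance (so a one-predictor model has `k = 3`, matching
   the published model-comparison table).

3. **Model selection.** The seven non-empty subsets of {age, education,
   gender} are fitted (gender untransformed 0/1) and ranked by AICc, with
   Akaike weights reported. A parsimony rule mirrors the published FA
   decision: if a model nested in the AICc-best model lies within
   ΔAICc < 2 (the conventional "substantial support" band), the model with
   fewer predictors is chosen. The chosen model must pass the overall
   F-test at p < 0.05, otherwise no correction is applied for that index.

4. **Correction regression.** The chosen model is refitted on mean-centered
   transformed predictors and the mean-centered index; the correction
   equation reverses the slopes' signs, and the centering constants are the
   cohort means of the transformed predictors. R², adjusted R² and the
   residual standard error are kept as metadata.

5. **Tolerance limits.** A Shapiro–Wilk test at α = 0.05 gates the branch.
   The nonparametric branch (the norm for right-skewed time scores) returns
   order statistics at ranks defined through the binomial CDF: the outer
   rank is the smallest `m` with `P(Bin(n, content) ≤ m-1) ≥ confidence`,
   the inner rank the smallest `m` with that CDF ≥ `1 - confidence`. This
   is the unique simple rule consistent with the published rank pair
   (515, 532) at n = 550, content 0.95, confidence 0.95 — a symmetric
   95%-confidence rule for both bounds would give 514, not 515. When the
   outer rank would exceed `n` the limit is reported as not computable
   rather than raising an error. The parametric branch uses the
   normal-theory one-sided factor `k = t'⁻¹(confidence; n-1,
   ncp = z(content)·√n)/√n`.

6. **Equivalent scores and percentiles.** The ES 0 cut is the outer
   tolerance limit and the ES 3/4 cut the sample median; the two
   intermediate cuts are the order statistics at cumulative proportions
   0.80 and 0.65, giving three equal 15%-probability bands between the 5%
   worse tail and the median. This reconstruction reproduces the agreement
   between the published ES table and the published 35th and 50th
   percentile entries, but the exact historical rank convention is not
   fully documented, so the proportions are a parameter. Percentile values
   are type-7 empirical quantiles at cumulative proportion `1 - p/100`
   (`p` = fraction of the sample performing worse); whether the original
   grid interpolated is unknown, and the interpolating convention was
   chosen for smoothness and consistency with the median-based ES 4 cut.

## The synthetic cohort generator

`generate_cohort()` emulates the normative study's structure so every
pipeline stage is testable without study data:

* **Demographics** are drawn from the published gender × age-decade ×
  education-band cell counts (n = 550), with age uniform within decade and
  education mapped into years by fixed rules (band 0–5 → 5 years; 6–8 → 8;
  9–13 → uniform 9–13; >13 → uniform 14–21). The study recorded years but
  reports bands, so this mapping is declared, not inferred.
* **Indexes** invert the correction models:
  `raw = baseline - correction(demographics) + noise`, so applying the
  published correction to generated data removes the demographic gradient
  by construction (a property the tests exploit). Baselines default to the
  published per-decade index means weighted by decade size; noise scales
  default to the published residual standard errors.
* **Noise** is a shifted gamma (shape 4, skewness 1) by default, so that
  adjusted scores are right-skewed and the pipeline's nonparametric
  tolerance branch — the branch used for the published norms — is exercised;
  a normal option exercises the parametric branch. `Err` is an
  overdispersed count (negative binomial with variance matched to the Err
  residual scale, Poisson when the scale is at or below the mean), then
  floored at 0 — an emulation, not a claim about the study's error process.
* **Cards** invert the index definitions (`P1 = SA`, `P2 = SA + FA`,
  `P3 = SA + OA`, `P4 = SA + OA + FA + I`): omissions are drawn with their
  expected total kept below `Err`, execution time is back-computed as
  `P(25 - om)/25`, and substitutions absorb the remaining errors, so
  scoring the generated cards returns the generated indexes exactly when
  the layout × crowding interaction `I` is 0 (nonzero `I` shifts recomputed
  OA and FA by `I/2` each).
* **Outlier injection** supports filter tests: clean members are redrawn if
  they would exceed their own cohort's 3×IQR thresholds and the requested
  outliers are placed at twice the threshold on one card, so a 563-record
  cohort with 13 injected exceedances deterministically filters to 550.
  This is a structural emulation of the study's casewise exclusion, not a
  behavioural model of why real participants overshoot.

What the generator does *not* emulate: response processes (scan paths, eye
movements), within-participant correlation beyond the card decomposition,
the layout × crowding interaction's dependence on demographics, or patient
populations. Passing pipeline tests on synthetic cohorts therefore
demonstrates the *procedure's* correctness (unbiased recovery, correct rank
arithmetic, correct classification plumbing), not that the published norm
values themselves could be re-derived — those depend on the original raw
data, which are not public.

## Numerical choices and test problem sizes

* Rounding for grid reproduction and classification: half away from zero to
  one decimal, with a machine-epsilon guard for binary representations of
  exact halves.
* Performance times and corrections are carried at full double precision
  internally; rounding happens only at presentation and classification.
* Transform selection at low signal: the convex age families (reflected
  log, cube, square) are nearly collinear over ages 20–79, so at the
  published effect sizes (age R² around 0.2 for SA, 0.04 for OA) the
  generating family wins the AICc comparison often but not reliably. The
  selection-consistency tests therefore use the conditions under which
  consistency is expected: a strong effect for SA (age-only model, residual
  scale 4 s, age R² ≈ 0.85) and, for OA at its published effect size, the
  comparison against the non-convex competitors (identity, log, inverse).
  This is a real limitation of AICc-based transform selection on samples of
  this size, inherited from the procedure itself.
* Coefficient recovery is tested at the study's own conditions (n = 550,
  published residual scales, 50 replicate cohorts), asserting 95% CI
  coverage of the generating coefficients at the nominal rate.
* The pipeline round-trip test uses residual scale 2 s at n = 550 and
  checks the rebuilt correction grids cell by cell: within ±0.5 s for OA
  and FA, ±1.0 s for SA (the profiled reflected-log offset is weakly
  identified, which lets extreme-age cells drift) and Err (its count noise
  cannot shrink below the Poisson floor). At the published residual scales
  the cell-level sampling error is several times larger — plain OLS
  sampling behaviour, covered by the coverage test instead.
* Simulation sizes (50 replicate cohorts of 550; single cohorts of 5 000
  for cancellation checks) keep the full suite to tens of seconds while
  leaving binomial assertion bands (e.g. coverage ≥ 42/50, the 0.001 lower
  band for a 0.95 rate) meaningful.

## Known limitations

* The published norm values (tolerance limits, ES cuts, percentile grids)
  are embedded verbatim; they cannot be re-derived without the original
  raw data, and the pipeline validates against them only structurally.
* `Err`'s composition (exclusion of autocorrections) is a documented
  interpretation; published summary tables cannot disambiguate it.
* The exact historical conventions for the intermediate ES cuts and the
  percentile quantile rule are reconstructions (parameterized, and
  consistent with the published tables at the checkable points); one
  published ES boundary (SA ES1/ES2 at 74.8 vs the printed 20th percentile
  74.0) hints at a rank-convention nuance the reconstruction does not
  capture.
* Corrections for demographics outside the normative ranges are
  extrapolations and flagged as such; norms for children or for neglect
  patients are out of scope.
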