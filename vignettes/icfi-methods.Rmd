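---
title: "Methods: the CS-ICFI pipeline, its assumptions and its synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CS-ICFI pipeline, its assumptions and its synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icfikit)
```

## The index and its scoring model

The cross-sectional infant and child feeding index (CS-ICFI) summarizes
nine feeding practices of a child aged 6–17 months into one score in 0–13.
Age enters through three half-open bands — [6, 9), [9, 12) and [12, 18)
months — because the same raw behaviour carries different meaning at
different ages: two food groups is good diversity at 7 months and poor
diversity at 14. Each band's component cutoffs are encoded as ascending
thresholds, a score being the number of thresholds reached; counts beyond
the highest threshold saturate at the top score, so seven feeds in the
youngest band still score 2. The defaults can be replaced wholesale by a
YAML/JSON scoring table (`read_scoring_table()`), which is validated so
that each band's maxima sum to 13 unless the caller explicitly allows a
custom total.

Two scoring details deserve emphasis:

* **Half-open bands.** A child of exactly 9.0 months belongs to the 9–11
  band. Band definitions must partition the age range; half-open intervals
  are the only unambiguous reading of band labels that touch at 9 and 12
  months.
* **The 12–17-month breastfeeding constant.** In the oldest band continued
  breastfeeding scores 1 whether present or absent. We reproduce this
  faithfully: it reflects the weaker breastfeeding recommendation at that
  age for this population (HIV-exposed infants, for whom guidance balances
  transmission risk against nutrition). A consequence is that the
  achievable minimum total in that band is 1, not 0, even though the
  index's nominal floor is 0; the test suite asserts exactly this.

Tertiles use the fixed cutpoints low 0–7, medium 8–10, high 11–13 by
default. The alternative `empirical` policy derives cutpoints from the
observed totals at the 33⅓ and 66⅔ percentiles — per age band, reflecting
the age-specific score distributions — using the linear-interpolation
quantile definition (`stats::quantile`, type 7), with a total lying exactly
on a cutpoint assigned to the lower category. Both conventions are stated
here and in the function documentation because tertile shares are sensitive
to them; the fixed table is the default because it is concrete and
portable, while the empirical rule describes how such tables are derived in
the first place.

## Survey records and missing data

Records are validated row by row; every input row is either accepted or
listed in a rejects table with its row number and reason — validation is
total, and the end-to-end report asserts the conservation identity
`read = accepted + rejected`. Index computation is complete-case: a missing
feeding item routes the record to the rejects table rather than being
imputed, since no defensible single imputation exists for behavioural
recall items. Anthropometric sanity bounds (weight 1–30 kg, length
40–120 cm) only warn: an implausible measurement is a data-quality signal,
not grounds for silent deletion.

## Internal consistency

Cronbach's α is computed on the raw covariance form,
α = k/(k−1) · (1 − Σsᵢ²/s_T²), with n−1 variances. The raw form is the
default because the nine items have deliberately unequal ranges (0–1
binaries next to 0–3 counts), so standardizing would reweight the scale
away from the published index; the standardized form is available behind a
flag. Confidence intervals use Feldt's closed-form F interval with (n−1)
and (n−1)(k−1) degrees of freedom — the standard analytic choice when no
resampling scheme is specified. Item–total correlations default to the
uncorrected form (item included in its own total); the corrected variant is
a flag. Negative α values, which the formula permits when items are
negatively related on average, are reported as computed with a warning
rather than truncated. Within the oldest band the breastfeeding item is
constant by construction; its item–total correlation is then undefined and
reported as `NA`, never silently zero.

## Anthropometry

z-scores use the LMS transform z = ((x/M)^L − 1)/(L·S), with the L = 0
logarithmic limit handled explicitly, against a pluggable reference of
(sex, index, L, M, S) rows; parameters are linearly interpolated between
grid rows and requests outside the grid span are errors naming the span
(records affected get `NA` and are listed, not dropped). No official
growth-standard tables are bundled — they are license-encumbered downloads
and bundling a partial copy invites silent misuse; any reference in the
documented CSV layout can be plugged in. For tests and simulation,
`generate_lms_fixture()` builds a *synthetic* reference: smooth monotone
median curves with constant L and small S, and a weight-for-length median
derived by inverting the length-for-age median curve, so that a child on
the weight and length medians is also on the weight-for-length median.
Magnitudes are plausible for infants but it is not, and does not claim to
be, any official standard.

Malnutrition flags are strict: stunted/underweight/wasted iff z < −2
exactly, so a child at precisely −2.0 is not flagged. Ages are used in
months as recorded; no day-level conversion is attempted because the survey
instrument records months.

## The statistical battery

Group comparisons use the classical one-way ANOVA F test and pooled
(optionally Welch) t-tests; variance homogeneity uses Levene's test with
deviations about group means; contingency tables use Pearson's chi-square
without continuity correction, with the proportion of expected counts
below 5 reported and Fisher's exact p attached for sparse 2×2 tables.
Regression coefficients are standardized betas — OLS after z-scoring
outcome and predictors — because that is the natural reading of
dimensionless coefficients of similar magnitude across predictors measured
on wildly different scales; unstandardized output is a flag. The
interaction screen fits, per moderator, outcome ~ index + moderator +
index×moderator on z-scored terms and reports the product-term coefficient.
Tests are two-sided at 0.05 and no multiple-testing correction is applied,
matching common practice in this literature; when screening many
moderators this inflates the family-wise error rate, which is documented as
a caveat rather than silently corrected.

## The synthetic cohort generator

The generator exists so that every stage has inputs with known ground
truth. Its design:

* **A single latent feeding-quality factor** q ~ Normal(μ, 1) per child
  drives all inter-item correlation: each item's base rate is tilted on the
  logit scale by λ·q (binomial day counts and a log-linked Poisson feed
  count analogously). One factor is the simplest mechanism consistent with
  summarizing the items by Cronbach's α, which presumes a dominant common
  dimension.
* **Marginals are preserved under tilting.** The tilt intercept is solved
  (by `uniroot`, or in closed form for the Poisson) so that the average
  success probability over the realized factor values equals the target
  marginal. Loadings therefore change dependence, not base rates — at
  n = 10 000 every binary item's empirical rate sits within Monte-Carlo
  noise of its target, which the suite checks at 3 standard errors.
* **Structure in μ.** The factor mean carries an urban shift (default 0.40)
  and a standardized age trend (default 0.7), so urban children and older
  children have better feeding quality. Breastfeeding has its own per-band
  marginal curve (0.95/0.85/0.70) and a small negative loading, and bottle
  feeding loads weakly — mirroring the empirical pattern that these two
  items sit apart from the complementary-feeding items and depress the
  scale's consistency.
* **Outcomes.** LAZ = mean + 0.183·z(index) + 0.199·z(log income)
  − 0.162·z(pre-lacteal) − 0.062·z(age at complementary feeding)
  + 0.054·z(married) + Normal(0, 0.94²); WAZ analogously with effect 0.168
  and a diarrhoea term; WLZ with a null index effect. The residual SD 0.94
  makes the outcome variance close to 1, so the generating coefficients are
  recovered as standardized betas. Anthropometric measurements are emitted
  by inverting the LMS fixture at the child's age, so `compute_zscores()`
  recovers the drawn WAZ and LAZ exactly. Two measurements cannot pin three
  indices, so WLZ is implied by the emitted weight and length; the drawn
  WLZ target is recorded in the truth object but not enforced.
* **Calibration.** Defaults were tuned once, against the implied-α
  evaluator and large-n summaries, to the conditions the index was studied
  under: implied α ≈ 0.68 for the nine scored items (band 0.65–0.72), mean
  total ≈ 9.0 with SD ≈ 3, band means rising with age, an urban–rural mean
  gap ≈ 0.9 points, 72.8% urban, 57.6% male, and the standardized effects
  above. They are fixed constants of the package, not fitting dials.
* **Determinism.** All randomness flows from one seed through a single
  stream in a documented draw order (demographics, covariates, factor,
  items, outcomes); regeneration with the same parameters is bit-identical.

`implied_alpha()` reports the α a parameter set implies for the *scored*
items. The scoring nonlinearity (thresholding, band cutoffs) has no
convenient closed form, so the implied value is evaluated by large-sample
simulation (default n = 40 000) of the item-generation step under a
dedicated internal seed, leaving the caller's random state untouched. One
subtlety the test suite documents: with all loadings at zero the scored
items are independent only *within* an age band — across bands the
band-specific cutoffs couple the scored items through age — so the
zero-loading α limit is checked within a single band.

## What the generator does and does not emulate

It reproduces the survey's structure (item layout, age bands, marginal
rates), a plausible single-factor dependence among items, and specified
index–outcome effects. It does not emulate cluster sampling by health
facility (by design: the downstream models are ordinary, not
survey-weighted), recall error or interviewer effects, seasonal diet
variation, item missingness, or multi-factor item structure. Passing tests
on synthetic cohorts therefore demonstrate that the estimators recover
known truth under the stated model, not that the model captures every
feature of field data.

## Numerical choices and problem sizes

Empirical tertile ties go to the lower category; degenerate (constant)
totals collapse to a single low category with a warning. Zero-variance
items make item–total correlations `NA` with a warning. The Feldt interval
requires n > k; smaller strata are flagged and skipped while the rest of
the report proceeds. Rank-deficient regression designs are refused naming
the collinear columns.

Test and calibration problem sizes are chosen to make Monte-Carlo noise
small relative to the tolerances: exhaustive scoring enumeration over
~124 000 response combinations per band; α recovery at n = 2000–5000
against an implied value evaluated at n = 20 000–40 000; effect recovery at
n = 2000 (±0.05 on standardized betas); type-I error of the regression and
interaction screen over 200 replicates of n = 300 (±0.03 around 0.05).

## Known limitations

The scoring table is faithful to its source including its quirks (the
oldest band's breastfeeding constant and resulting floor of 1). Equal
weighting of heterogeneous practices is a recognized limitation of summary
feeding indices generally. The α confidence interval is the analytic Feldt
form, which assumes the parallel-test model; bootstrap intervals are out of
scope. The z-score engine interpolates whatever reference it is given and
applies no implausibility exclusions beyond warnings — fidelity to an
official standard is the responsibility of the supplied table.
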