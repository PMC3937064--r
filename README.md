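# icfikit

Scoring, reliability and nutritional-association analysis for the
cross-sectional infant and child feeding index (CS-ICFI).

## The problem

Infant and young child feeding between 6 and 18 months is multidimensional —
breastfeeding, bottle use, dietary diversity, meal frequency, week-scale
food-group frequency, hygiene and psychosocial feeding behaviour all matter,
and each alone is a poor summary. A feeding *index* combines them into a
single age-appropriate score so that feeding practice can be described,
compared across groups, and related to nutritional status. `icfikit`
implements one such composite, the cross-sectional infant and child feeding
index for children aged 6–17 months, together with everything an analyst
needs around it: survey-record validation and I/O, internal-consistency
(item) analysis, LMS growth-reference z-scoring, the standard statistical
battery, and a synthetic-cohort generator with known ground truth for
testing every stage.

It is written for epidemiologists and nutrition researchers working with
per-child survey data (24-hour and 7-day feeding recall plus anthropometry).

## The index

Nine components are scored with age-band-specific cutoffs (bands
[6,9), [9,12), [12,18) months) and summed to a total in 0–13:

| component | range | notes |
|---|---|---|
| current breastfeeding | 0–2 | yes = 2 in the two younger bands; constant 1 at 12–17 months |
| bottle feeding (24 h) | 0–1 | bottle use scores 0 |
| dietary diversity (24 h) | 0–2 | count of 8 food groups, band cutoffs |
| solid/semi-solid meal frequency (24 h) | 0–2 (0–3 at 12–17 m) | band cutoffs, saturating |
| 7-day food-group frequency | 0–2 | per-group 0/1/2 by days (0, 1–3, 4+), summed over 7 groups to 0–14, rescored by band |
| hand washing before cooking | 0–1 | |
| hand washing before feeding | 0–1 | |
| child helped to eat | 0–1 | |
| active response to food refusal | 0–1 | leaving the child alone scores 0 |

Totals are classified into tertiles: low 0–7, medium 8–10, high 11–13
(fixed cutpoints), or empirically at the 33⅓/66⅔ percentiles per band.
Internal consistency is summarized by Cronbach's
α = k/(k−1)·(1 − Σsᵢ²/s_T²) with Feldt F-based confidence intervals,
α-if-item-deleted and item–total correlations. Anthropometric status uses
the LMS transform z = ((x/M)^L − 1)/(L·S) against a pluggable growth
reference; stunting/underweight/wasting are flagged at z < −2 on
LAZ/WAZ/WLZ. Associations use one-way ANOVA, t-tests, Levene's test,
chi-square tests and OLS with standardized coefficients.

## Worked example

```r
library(icfikit)

g      <- generate_cohort(sim_params(n = 184, seed = 42))
scored <- score_cohort(g$cohort)
scored
#> CS-ICFI cohort scores: 184 children
#> Tertile basis: fixed
#>     stratum   n  mean    sd ci_lower ci_upper
#>    band_6_8  46 8.152 2.708    7.348    8.956
#>   band_9_11  43 8.930 3.089    7.980    9.881
#>  band_12_17  95 9.916 3.038    9.297   10.535
#>     overall 184 9.245 3.048    8.801    9.688
#> Tertiles: low 53 | medium 52 | high 79

reliability_report(scored, by_band = TRUE)
#> CS-ICFI internal consistency
#>   overall     n = 184  alpha = 0.687  (95% CI 0.614-0.750)
#>   band_6_8    n = 46  alpha = 0.698  (95% CI 0.547-0.813)
#>   band_9_11   n = 43  alpha = 0.743  (95% CI 0.610-0.844)
#>   band_12_17  n = 95  alpha = 0.715  (95% CI 0.620-0.793)

z <- compute_zscores(g$cohort$anthro, g$reference)
prevalence_summary(z)
#>               index   n      mean_z n_below prevalence_pct
#> 1    stunting (LAZ) 184 -0.97604479      36      19.565217
#> 2 underweight (WAZ) 184 -0.68624009      25      13.586957
#> 3     wasting (WLZ) 184  0.07413305      18       9.782609

dat <- merge(merge(scored$scores[, c("child_id", "total")], z, by = "child_id"),
             g$cohort$covariates, by = "child_id")
standardized_ols(dat$laz, data.frame(
  cs_icfi = dat$total, income = dat$monthly_income,
  pre_lacteal = dat$pre_lacteal_feeding, age_cf = dat$age_at_cf_months,
  married = dat$marital_status_married))
#> Standardized linear regression (n = 184, R2 = 0.078)
#>    predictor     beta      se       t p_value
#>      cs_icfi  0.17954 0.07236  2.4811 0.01403
#>       income  0.13495 0.07235  1.8653 0.06379
#>  pre_lacteal -0.17293 0.07220 -2.3951 0.01765
#>       age_cf -0.03528 0.07208 -0.4895 0.62509
#>      married  0.01859 0.07210  0.2579 0.79680
```

Reading: the mean index is 9.25 (95% CI 8.80–9.69) and rises across the age
bands; internal consistency is acceptable (α ≈ 0.69 overall); about a fifth
of the synthetic cohort is stunted; and a one-SD increase in the index is
associated with a 0.18-SD higher length-for-age z-score after adjustment —
the effect size the generator was parameterized with. Real survey data
enter through `read_cohort()` (CSV; foreign column names map via
`schema_config`) and a real growth reference through
`read_lms_reference()`; `run_full_analysis()` executes the whole pipeline
and writes a combined report.

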