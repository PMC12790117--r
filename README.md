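# respaudit

Auditing respiratory-care resource availability in resource-constrained
hospitals and analysing cohorts of hypoxemic children.

Hypoxemia (low blood oxygen saturation) is common in children presenting to
hospitals in resource-constrained settings and is a strong predictor of
death, yet the equipment needed to detect and treat it — pulse oximetry,
oxygen delivery, non-invasive and invasive ventilation — is unevenly
available. Pediatric acute respiratory distress syndrome (PARDS) is even
harder to pin down: its consensus diagnostic criteria (PALICC-2) require
oxygenation metrics and chest imaging that many sites cannot obtain.
`respaudit` packages the full analytic machinery for studying these
questions on multicentre point-prevalence data:

* **Resource bundle scoring.** Facility surveys answer, on a 5-point Likert
  scale, how often each resource item is available. A tiered bundle
  (none < basic < intermediate < advanced < expert) is *available* when at
  least 80% of its items are "often" or "always" available (inclusive,
  compared in integer arithmetic), and a site's tier is the highest bundle
  whose chain of lower bundles all pass. Composite items follow explicit
  rules (pulse oximetry = portable OR continuous; intubation supplies =
  laryngoscopes AND endotracheal tubes; sedation = any of four agents).
* **Cohort construction.** A child is hypoxemic when any day-1..7 minimum
  SpO₂ < 88%, or any supplemental oxygen/respiratory support is received,
  or death occurs in the emergency department with SpO₂ < 88% or on oxygen;
  children with cyanotic heart disease are excluded first.
* **Clinical scores.** LODS (0–3: prostration/feeding, coma, deep
  breathing), malnutrition (MUAC < 12.5 cm, weight-for-age Z < −2, or
  reported), and PARDS-trigger grouping
  (LRTI > sepsis > trauma > other precedence).
* **PALICC-2 classifier.** Saturation-based oxygenation metrics — S/F =
  SpO₂/FiO₂ and OSI = FiO₂ × MAP × 100 / SpO₂, both undefined above an SpO₂
  of 97% — feed a data-sufficiency screen and the exclusive cascade PARDS →
  Possible PARDS → At-risk, with every missing field recorded per category.
* **Statistics.** 2×2 odds ratios with Wald intervals
  (CI = exp(ln OR ± z·√(1/a+1/b+1/c+1/d))), Pearson chi-square, Wilcoxon
  rank-sum (exact enumeration up to combined n = 14, tie-corrected normal
  approximation with continuity correction above), and logistic regression
  by iteratively reweighted least squares with separation and collinearity
  diagnostics — all implemented in the package and cross-checked against
  independent oracles in the test suite.
* **Synthetic data.** A stochastic cohort generator with configurable
  prevalences, logit effect sizes and SDI-dependent missingness, plus a
  deterministic reference fixture that reproduces the published marginal
  counts of the source study through the pipeline's own classifiers.

## Worked example

```r
library(respaudit)

fx  <- build_paper_fixture()   # deterministic reference dataset
run <- run_all(fx)             # classify -> screen -> score -> PARDS -> stats
run
```

```
Hypoxemia cohort analysis
  enrolled 7538; hypoxemic included 763 (10.1%); deaths 52 (6.8%)
  site tiers: NONE=3 BASIC=11 INTERMEDIATE=13 ADVANCED=16 EXPERT=3
  mortality by tier:
         tier patients deaths pct_mortality
         NONE       81     10    12.3456790
        BASIC      273     19     6.9597070
 INTERMEDIATE      177     21    11.8644068
     ADVANCED      189      1     0.5291005
       EXPERT       43      1     2.3255814
  low- vs high-resource OR 11.95 (95% CI 2.88-49.56)
  PALICC-2 cascade: n_trigger=430 any_eligible=25 not_classifiable=405
    full_evaluable=12 pards=5 possible_evaluable=8 possible=3
    at_risk_evaluable=14 at_risk=6
```

Reading this: of 7538 enrolled children, 763 (10.1%) met the hypoxemia
definition; 52 died (6.8%). Mortality falls steeply once the advanced
bundle is available (0.5–2.3% vs 7–12%), and the dichotomized
low-vs-high-resource odds ratio on this dataset is 11.95. Among the 430
hypoxemic children with a PARDS trigger, only 25 (5.8%) carry enough data
to evaluate any PALICC-2 category; 5 of the 12 fully evaluable children
meet PARDS criteria.

The trigger–mortality model:

```r
run$fit_trigger
```

```
Mortality model; exposure: trigger
              or ci_low ci_high
unadjusted 0.760  0.433   1.335
adjusted   0.709  0.393   1.279
```

The unadjusted odds ratio of 0.76 (95% CI 0.43–1.3) reproduces the
contingency-table cross-product exactly (the single-predictor logistic fit
and `odds_ratio()` agree to 1e-10); the adjusted fit controls for age ≤ 5,
malnutrition, LODS > 0 and site resource group.

## Vignette

`vignettes/respaudit-methods.Rmd` documents the operational definitions,
the PALICC-2 evaluability rules and their edge cases, every tunable
threshold with its default and rationale, what the synthetic generator does
and does not emulate, and known limitations of the approach.
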