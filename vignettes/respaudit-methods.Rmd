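---
title: "Methods: resource bundle scoring, hypoxemia cohorts, and the PALICC-2 cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resource bundle scoring, hypoxemia cohorts, and the PALICC-2 cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respaudit)
```

This vignette is the package's own account of its operational definitions:
what is computed, under which assumptions, with which thresholds, and where
genuine design freedom existed and how it was resolved.

## Tiered resource bundles

Facility surveys report, per resource item, a 5-point Likert availability
("never" = 1 .. "always" = 5). An item is *available* when its response is
in the configured available set (default: often, always). Three composite
items are resolved before counting: pulse oximetry is available if either
portable or continuous oximetry is (OR); intubation supplies require both
laryngoscopes and endotracheal tubes (AND); sedation requires any of IV
opioids, benzodiazepines, propofol, or ketamine (ANY).

A tier is available when at least 80% of its items are available. Three
choices deserve comment:

* **The threshold is inclusive and exact.** "At least 80%" is compared as
  `100 × available ≥ 80 × total` in integer arithmetic, so a 4-of-5 tier
  passes without floating-point tie ambiguity.
* **Missing responses count as unavailable.** Survey silence cannot
  evidence availability; no imputation is attempted.
* **The tier rule is cumulative.** A site's assigned tier is the highest
  tier such that it *and every lower tier* pass. Whether the original
  survey scoring enforced this chain or scored tiers independently is not
  documented; the cumulative rule makes classification well defined for
  non-monotone surveys and matches the reading that a site reporting the
  advanced bundle also has the basic and intermediate bundles. The default
  bundle definition (`extdata/bundle_definition.yaml`) lists 6/5/5/4 items
  per tier; the scoring engine is item-list agnostic, so a different
  transcription of the bundle figure slots in as configuration, not code.

For modelling, tiers are dichotomized into `INTERMEDIATE_OR_LESS`
(none/basic/intermediate) versus `ADVANCED_OR_EXPERT`.

## Hypoxemia cohort

A patient enters the hypoxemia cohort when any of three clauses holds, in
this order: (1) any day-1..7 minimum SpO₂ strictly below 88%; (2) any form
of respiratory support (simple oxygen through invasive ventilation) on any
of days 1..7; (3) death in the emergency department with SpO₂ < 88% or
while on oxygen. Patients with cyanotic congenital heart disease are
excluded *before* hypoxemia is evaluated, since their baseline saturations
are uninterpretable. The 88% cutoff is the At-risk saturation threshold of
the PALICC-2 consensus; the strictness of the inequality matters at the
boundary and is tested (SpO₂ of exactly 88 does not qualify). Clause (2)
is deliberately broad — oxygen receipt does not prove hypoxemia — which
mirrors the source study's stated over-inclusion and is one reason the
cohort's median admission saturation is high.

Scores: LODS adds one point each for prostration (or inability to feed
under 5 months; resolved upstream into a single boolean), coma, and deep
breathing; missing components score zero and are counted in a message for
audit. Malnutrition is MUAC < 12.5 cm (strict), weight-for-age Z < −2
(strict), or reported comorbid malnutrition. Trigger groups collapse
pneumonia/bronchiolitis/COVID-19 into LRTI and aspiration/drowning/other
shock into OTHER; multi-trigger patients take one primary group by the
configurable precedence LRTI > SEPSIS > TRAUMA > OTHER (the source
analysis treated groups as mutually exclusive without stating a tie-break;
precedence by cohort frequency is our choice and the raw trigger set is
always retained).

## PALICC-2 cascade and data sufficiency

Oxygenation rests on pulse oximetry alone (no blood gases are captured):
S/F = SpO₂/FiO₂ and OSI = FiO₂ × MAP × 100 / SpO₂, both undefined whenever
SpO₂ exceeds 97% — above that the oxyhemoglobin dissociation curve
flattens and saturation no longer tracks oxygen tension. The 97% ceiling
is inclusive: S/F(97, 1.0) = 97 is defined. Oxygenation fields are taken
from the first day attaining the patient's highest support level; mean
airway pressure is the capture 6 h after starting mechanical ventilation.

The cascade, evaluated in order with exactly one category per patient:

* **PARDS** — unattributed chest X-ray opacity, invasive mechanical
  ventilation, and OSI ≥ 5. Airway pressures are not captured for
  non-invasive ventilation, so NIV patients cannot satisfy the
  positive-pressure arm and are at best evaluable for lower categories.
* **Possible PARDS** — nasal respiratory support (NIV via nasal interface,
  or HFNC at ≥ 1.5 L/min/kg or ≥ 30 L/min), S/F ≤ 250, and *no chest X-ray
  obtained*. An X-ray that was obtained but whose result is missing blocks
  the category (and PARDS) and is recorded as a missing field — "not
  obtained" and "obtained, result unknown" are distinct states.
* **At-risk** — unattributed opacity plus flow-delivered oxygen meeting a
  weight-banded minimum flow (2/4/6/8 L/min up to 10/20/40/over-40 kg).

An opacity attributed to atelectasis, cardiac failure or fluid overload
negates the opacity clause; an unattributed opacity counts as acute
parenchymal disease. A category is *evaluable* only when every field its
rule reads is present (FiO₂, MAP, a usable SpO₂, interface, flow, CXR
result, weight as required); each absent or disqualifying field is
recorded as a `category:field` token, and a patient with no evaluable
category is `NOT_CLASSIFIABLE`. Severity sub-grading is out of scope: the
headline categories never depend on it.

Evaluability overlaps are real and intended. An invasively ventilated
patient with complete ventilation-day data is PARDS-evaluable; if an
earlier hospital day delivered flow-based oxygen with a known flow, the
patient is *also* At-risk-evaluable. Possible-evaluable patients, by
contrast, have no X-ray and can overlap neither set. In the reference
dataset this yields 12 fully evaluable, 8 Possible-evaluable and 14
At-risk-evaluable patients whose union is the 25 with sufficient data for
anything — the only reading we found under which all published cascade
counts hold simultaneously; the fixture manifest records it.

## Statistical machinery

All of it lives in the package, for auditability, and every routine is
cross-checked against an independent oracle in the test suite
(`chisq.test`, `wilcox.test`, `glm.fit`, direct likelihood maximization,
and brute-force enumeration).

* **Odds ratios**: OR = ad/bc with Wald interval
  exp(ln OR ± z·√(1/a+1/b+1/c+1/d)). Zero cells are an error by default;
  the Haldane–Anscombe +0.5 correction is strictly opt-in so corrections
  are never silent.
* **Chi-square**: plain Pearson Σ(O−E)²/E, no continuity correction,
  two-sided throughout; p < 0.05 is the significance convention and no
  multiplicity adjustment is applied (none in the source analysis).
* **Wilcoxon rank-sum**: midranks for ties; exact enumeration of all
  C(n, n_x) rank assignments when the combined sample is ≤ 14 without
  ties, otherwise a normal approximation with tie-corrected variance and
  0.5 continuity correction. The cutoff of 14 keeps enumeration below
  3 432 subsets. The approximation is only ever used above the cutoff;
  exhaustive comparison against enumeration at combined sizes 8–12 in the
  test suite measures a worst-case two-sided discrepancy near 0.10,
  concentrated at samples with an arm of fewer than five observations and
  at mid-range p-values (0.3–0.8), shrinking below 0.02 once both arms
  have at least five observations. That measured behaviour — rather than a
  smaller nominal bound — is the honest statement of approximation
  quality.
* **Logistic regression**: IRLS from a zero start, step-halving on any
  likelihood decrease, convergence at score norm ≤ 1e-8 within 50
  iterations; Wald covariance from the inverse Fisher information at the
  optimum. Rank-deficient designs error naming the dependent columns;
  quasi-separation (|coefficient| > 15 or non-convergence) is flagged,
  never silently reported as converged. Covariates without contrast are
  dropped with a warning so degenerate strata do not abort a fit. With a
  single binary predictor the fit reproduces the closed-form contingency
  OR and its Wald interval to 1e-10, which the tests assert.

The two study models are thin wrappers: mortality on the low-resource
exposure adjusted for census > 50, PICU and academic status (site-level
confounders), and mortality on trigger presence adjusted for age ≤ 5,
malnutrition, LODS > 0 and resource group. The published *adjusted* odds
ratios depend on joint covariate distributions only present in the
deposited individual-level data, so they are not desk-reproducible here;
what the package demonstrates instead is the model structure plus
parameter recovery — 100 simulated cohorts of n = 763 with a true exposure
log-odds of log 18 and site-covariate effects, whose adjusted Wald
intervals cover the truth at near the nominal 95% (at a baseline risk of
0.86%, roughly one replicate in eight has no unexposed deaths; such fits
are flagged quasi-separated and carry honestly enormous intervals).

## Synthetic data

Two modes. The **stochastic generator** draws sites (tier mix, SDI
correlated with tier), surveys guaranteed to classify back to their drawn
tier, and patients with Bernoulli hypoxemia and trigger indicators, a
configurable mortality logit (defaults: intercept −4.75, low-resource
log 18, trigger log 0.56, with modest age/malnutrition/LODS effects),
log-normal ages/weights/stays matched to the cohort's medians (age 1.9 y,
weight 10 kg, stay 3.25 d), and field-level missingness rising as SDI
falls. It emulates marginal structure and the logit link, *not* real joint
clinical correlations (e.g. support escalation over days, site-level
outcome clustering), so passing property tests speaks to the pipeline's
logic, not to clinical validity on real data.

The **deterministic reference fixture** encodes the published marginal
counts of the source study purely in raw fields — Likert responses, daily
SpO₂/support/FiO₂/MAP/flow series, diagnosis codes, outcomes — so that
fixture tests genuinely exercise classification rather than round-tripping
labels. Joint cells the publication does not pin are filled by
proportional interleaving with largest-remainder rounding (documented in
the manifest); the build consumes no randomness and is bit-stable.
Unpinned screening arms are completed with 41 cyanotic exclusions and 4848
non-admitted non-hypoxemic patients to partition the 7538 enrolled.

## Numerical and interface choices

* CSV interchange, UTF-8, one row per patient with day-indexed wide
  columns (day 1 = admission), missing values as empty fields — never
  sentinel numbers. Validation is total: each row is accepted as typed or
  rejected with a located diagnostic; the single documented coercion is
  FiO₂ entered as a percentage (> 1), divided by 100 with a message.
* FiO₂ is a fraction in [0.21, 1.0]; flows are L/min; MAP is cm H₂O;
  ages in years (29/365 to 14); the Likert interface label for invasive
  days is `INVASIVE`, and `NOT_APPLICABLE` exists so that a recorded
  non-answer is distinguishable from a missing one.
* Tie-breaks: largest-remainder allocations break ties by position;
  trigger precedence is configuration; the support order is fixed as
  IMV > CPAP/BiPAP > HFNC > simple O₂ > none.
* Test and simulation sizes were chosen to keep the default suite fast
  (about half a minute): 1000 survey round-trips, exhaustive Wilcoxon
  enumeration at combined n ≤ 12, 100 recovery replicates of n = 763,
  generator fidelity at n = 20 000 with a coefficient tolerance of 0.1.

## Limitations

* Bundle tier *membership* is configuration; a different transcription of
  the source study's bundle figure changes counts but not logic.
* The PALICC-2 evaluability rules encode one defensible reading of
  partially specified definitions (notably At-risk evaluability for
  ventilated patients with earlier flow-oxygen days); alternatives exist
  and would shift sufficiency counts.
* No imputation anywhere: missing anthropometrics, survey responses and
  oxygenation fields stay missing, matching the source study's fully
  descriptive stance but limiting power.
* The generator's independence assumptions make it unsuitable for
  estimating real-world operating characteristics (e.g. classifier
  sensitivity on real cohorts); it validates code paths and estimator
  calibration only.
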