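---
title: "Validating and updating a pediatric triage risk model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and updating a pediatric triage risk model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedtriage)
```

## The problem

Triage scores for children presenting to outpatient departments in
low-resource settings are usually derived at one site and then deployed at
others. Transporting a clinical prediction model this way fails in two
characteristic modes: the *baseline risk* differs (a site with a lower
admission rate makes the model overpredict everywhere), and the
*predictor–outcome associations* differ (a sign that was strongly prognostic
in the derivation cohort may carry little information in the new one, which
degrades discrimination, not just calibration). Both modes are amplified in
narrow age bands — neonates in particular — where the case mix is different
and the age predictor loses most of its range.

`pedtriage` implements the complete workflow around a nine-predictor logistic
triage model: scoring, external-validation metrics, a three-step updating
cascade, threshold selection, three-category stratification, and the
sample-size calculations used to plan validation cohorts.

## The model

The risk of the composite endpoint — admission of at least 24 hours,
readmission within 48 hours of enrollment, or death — is modelled as

$$\operatorname{logit}(p) = \beta_0 + \beta_1\sqrt{\text{age}} +
\beta_2\,\text{HR} + \beta_3\,\text{temp} + \beta_4\,\text{MUAC} +
\beta_5\,\text{VS}(\text{SpO}_2) + \beta_6\,\text{concern} +
\beta_7\,\text{diff.breathing} + \beta_8\,\text{oedema} +
\beta_9\,\text{pallor}.$$

Two transforms deserve comment.

* **Age** enters through its square root to linearize the steeply declining
  risk over the first months of life. Models refitted on narrow bands may
  prefer raw age; both modes are carried in the `coefficient_set` as
  `age_transform`, and the shipped updated neonatal equation uses
  $\sqrt{\text{age}}$, matching its published form (sources describing the
  refit procedure state that age was not square-rooted, but the printed
  equation itself contains the square root; the package follows the concrete
  equation and supports both modes).
* **Oxygen saturation** enters as a *virtual shunt*: the equivalent pulmonary
  shunt fraction implied by a given SpO₂, $\text{VS}(s) = a\log_{10}(b - s) +
  c$ with defaults $a = 68.864$, $b = 103.711$, $c = -52.109$. This maps the
  compressed 90–100% saturation range onto a physiologically linear severity
  scale and is monotone non-increasing in SpO₂. Saturations at or above the
  asymptote $b$ are clamped to $b - \varepsilon$ (default $\varepsilon =
  0.1$) to avoid the singularity; with the default constants no clamping
  occurs for SpO₂ ≤ 100. The constants are configuration
  (`spo2_transform_spec()`), since variants of the mapping circulate.

MUAC is taken in millimetres by default. The unit matters — the coefficient
is per-unit — so the `coefficient_set` records it and reports echo it.

The inverse logit is computed in a branch form that returns exactly 0 or 1
for extreme linear predictors instead of overflowing.

## Validation metrics

*Overall accuracy* is the Brier score, the mean squared distance between
predicted risk and outcome. *Discrimination* is the AUROC in its
Mann-Whitney rank form (ties counted ½), equal by construction to exhaustive
enumeration over case/non-case pairs — the test suite checks that equality on
inputs up to n = 200. The default interval is DeLong's, computed via the
midrank formulation and cross-checked in the tests against an independent
implementation; a seeded percentile bootstrap is the alternative.

*Calibration* is summarised four ways, all standard: the E:O ratio
(mean predicted over observed rate), calibration-in-the-large (intercept of a
logistic fit of the outcome on logit(score) with slope fixed at 1, i.e. an
offset model), the unconstrained calibration intercept and slope, and an
equal-count quantile reliability curve (10 bins by default; ties broken by a
stable sort on score then position). Scores of exactly 0 or 1 are clamped to
$[10^{-8}, 1-10^{-8}]$ before the logit-based fits. The slope fit is
undefined for constant scores or fewer than three observations; it is then
reported as `NA` with a warning rather than an error, since the E:O ratio and
CITL remain meaningful.

*Stratification*: two thresholds split risks into non-urgent
($p \le$ low), priority (low $< p \le$ high) and emergency ($p >$ high) —
boundaries inclusive on the left, matching the published table headers. For
classification metrics, "positive" means scoring above a boundary: at the
low boundary the positives are priority ∪ emergency, at the high boundary
emergency alone. Published three-category tables also print a middle
("priority") column whose values cannot be reconstructed unambiguously from
the category counts; the package reports the middle row under a documented
convention (identical 2×2 to the low boundary) and treats only the
non-urgent and emergency columns as arithmetically binding. Proportion
metrics carry Wilson score intervals, likelihood ratios Katz log-method
intervals; the methods are stated here because publications rarely name
theirs, and intervals computed by other methods will differ in the second
decimal. All metrics are computed from raw counts; rounding (half-even, 2
decimals for metrics, 1 for percentages) happens only in report rendering.
One documented consequence: the emergency-boundary likelihood ratios of a
published neonatal table equal the ratio of the *rounded* sensitivity and
specificity (0.58/0.10 = 5.8), while raw counts give 5.69; the package
outputs the raw-count value and the tests verify both arithmetics.

*Threshold selection* follows the deployment logic: the low threshold is the
largest candidate (observed score values plus 0/1 sentinels) whose
sensitivity is at least the target (default 90%, to avoid sending sick
children home), the high threshold the smallest candidate with specificity at
least its target (default 90%, to keep the emergency category specific).
When the two cross, specificity's monotonicity in the threshold is used to
raise the high threshold above the chosen low one if possible, otherwise the
low threshold is lowered below the high one; if neither repair is possible an
error describes the achievable frontier. Selected thresholds always satisfy
their targets on the selection data (a tested invariant).

## The updating cascade

Three nested updates, in increasing order of extensiveness:

1. **Recalibration-in-the-large** refits only the intercept, keeping the
   original linear predictor as an offset. By the maximum-likelihood score
   equation the updated mean prediction equals the observed rate, so E:O = 1
   and CITL = 0 on the fitting data — the tests assert this to $10^{-6}$.
2. **Logistic recalibration** refits intercept and a single slope on the
   linear predictor. Re-assessing the updated scores on the same data gives
   calibration intercept 0 and slope 1 exactly (the assessment refits the
   same model). With a positive slope the update is strictly monotone, so
   AUROC is bit-identical to baseline — both facts are tested invariants.
3. **Revision** re-estimates all nine coefficients (and intercept) on the
   validation cohort, keeping the predictor set and transforms.

Because each stage's score family nests the previous one *when the revision
template keeps the base model's transforms*, the in-sample log-likelihood is
non-decreasing across stages; `run_update_cascade()` therefore defaults the
revision template to the base model's transforms, and an identity-age
revision remains available by passing a modified template (at the price of
the nesting guarantee). The cascade reports AUROC, Brier, E:O, CITL,
calibration intercept/slope and the reliability curve at baseline and after
each stage — the standard four-panel calibration sequence
(`autoplot()` draws it).

The logistic fitter behind all of this is a compact IRLS with offset support:
tolerance $10^{-8}$ on the maximum coefficient change, at most 100
iterations, standard errors from the observed information. It is
cross-checked against `stats::glm` in the tests (coefficients, standard
errors, log-likelihood). Failures are classified rather than silenced:
fitted probabilities pulled to 0/1 across classes, a coefficient max-norm
above $10^3$ with non-vanishing steps, or a diverging predictor coefficient
(|slope| > 15 at the iteration cap, the signature of quasi-separation on a
rare binary sign such as oedema) are flagged `separation = TRUE` with a
warning; anything else at the iteration cap is flagged non-converged. A
singular system on the first iteration (truly collinear design, e.g. a
constant column) is an error.

Internal validation: `cross_validate()` assigns records to folds stratified
by outcome — shuffled within class, then dealt round-robin so every fold is
non-empty and events spread evenly — refits the revision on each training
set, and pools by concatenating out-of-fold predictions before computing
metrics once (per-fold AUROCs are also reported; a held-out fold with a
single class yields `NA` there, while a training fold with a single class is
an error suggesting smaller k). Thresholds for the pooled
sensitivity/specificity are selected once on the pooled out-of-fold
predictions by default — the alternative, per-fold selection, is a flag —
because pooling first is the only reading under which "a pooled estimate of
sensitivity and specificity" is well-defined. `bootstrap_validate()`
implements Harrell's optimism correction (refit on each resample; optimism =
resample-apparent AUROC minus resample-model-on-original AUROC; corrected =
apparent − mean optimism), skipping and counting degenerate resamples.

## Sample-size planning

Two calculators. The events rule $N = 10n/I$ (nine predictors at a 20% event
rate gives 450). And the four-criterion procedure for binary-outcome
prediction models given an anticipated Cox–Snell $R^2$: (1) global shrinkage
of at least 0.9, $n = P/((S-1)\ln(1 - R^2_{CS}/S))$; (2) apparent-vs-adjusted
$R^2$ difference at most $\delta$, via the shrinkage implied by
$S = R^2/(R^2 + \delta \max R^2_{CS})$ with
$\max R^2_{CS} = 1 - \exp\{2(\phi\ln\phi + (1-\phi)\ln(1-\phi))\}$;
(3) intercept precision, $n = (1.96/\text{margin})^2\phi(1-\phi)$;
(4) events per candidate predictor, $n = P\cdot\text{EPP}/\phi$. The overall
requirement is the maximum; each criterion is floored at 1 and rounded up.
With the published validation inputs (9 predictors, prevalence 0.05,
$R^2_{CS} = 0.0697$, differences/margins 0.05, EPP 7) the criteria give
1117 / 526 / 73 / 1260, so the events-per-predictor criterion binds at 1260.
A supplied C-statistic is recorded as provenance only; the package requires
$R^2_{CS}$ directly rather than approximating it from the C-statistic.

## The synthetic-cohort generator

Because the validation cohorts themselves are not public, every downstream
stage is exercised on synthetic cohorts whose statistical structure matches
what the analysis assumes:

* **Age** is drawn from a mixture over the exclusive bands <1 m, 1–2 m,
  >2–6 m, >6 m–<5 y with default weights (0.035, 0.042, 0.132, 0.791)
  following the age composition of a multi-site under-5 outpatient cohort,
  uniform within band.
* **Vitals** are age-dependent and loosely physiologic — heart rate with mean
  $150 - 0.6\,\text{age}$ (SD 18), temperature 37.2 (SD 0.9), MUAC
  $105 + 8\sqrt{\text{age}}$ mm (SD 12), SpO₂ as 100 minus a gamma-shaped
  deficit clamped into (50, 100] — and the four binary signs have default
  prevalences 0.25 / 0.20 / 0.01 / 0.10. These are configuration with no
  claim of clinical realism; what matters for the tests is that the outcome
  is generated from a known logistic model on the transformed predictors.
* **Outcome**: true risk is the inverse logit of the linear predictor under a
  configurable true coefficient set plus a site-level logit shift; the
  endpoint is Bernoulli in that risk. The default under-5 truth is a
  synthetic coefficient set (labelled as such) whose intercept (−20.5) was
  set so the default configuration yields roughly a 9% event rate, matching
  the under-5 prevalence scale of such cohorts; neonatal simulations use the
  shipped printed neonatal equation and reach event rates near 25%.
* **Back-filling**: endpoint-positive records are realised as a 48-hour
  admission (90%), a death (5%) or an early readmission (5%), and 5% of
  endpoint-negative records get a short (<24 h) admission — so
  `derive_composite_endpoint()` must actually apply the 24-hour rule to
  recover the drawn endpoint; tests verify the recovery is exact.
* **Reproducibility**: each record draws a fixed block of uniforms from a
  stream seeded deterministically from the master seed and the record index,
  so enlarging `n` never reshuffles earlier records. Missingness injection
  blanks predictor cells (never outcomes) independently at a configured rate
  under its own seed.

What passing tests on these cohorts shows — and does not show: parameter
recovery, the calibration identities, AUROC invariances and threshold
self-consistency are properties of the *procedures*, demonstrated under a
correctly-specified logistic truth with independent records. Real cohorts
have clustered sites, informative missingness, measurement error and model
misspecification; performance numbers on synthetic data therefore
characterise the software, not the clinical model.

## Numerical and design choices

* Ages are months internally; CSV input may declare days (divided by
  30.4375, so a 30-day child is a neonate) or years. Boundary conventions:
  "<1 m" is age < 1.0, "≤2 m" is ≤ 2.0, "<5 y" is < 60.0; exclusive bands
  are [0,1), [1,2], (2,6], (6,60).
* The composite endpoint requires length of stay ≥ 24 h, not mere admission.
  Records whose endpoint is undeterminable (missing outcome fields) are
  dropped with a warning; a record missing its stay length still counts as
  an endpoint if it has a qualifying death or readmission.
* Imputation is median (continuous) / mode (binary, ties toward 0) per
  analysis cohort, i.e. after age subsetting; impute before subsetting if a
  whole-dataset fill is wanted. Outcomes are never imputed.
* The two-sided Fisher exact test uses the probability-mass rule (sum of
  hypergeometric probabilities no larger than the observed table's), the
  convention of `stats::fisher.test`, verified against brute-force
  enumeration in the tests.
* Simulation-based test tolerances follow Monte-Carlo error at the chosen
  problem sizes: binomial rate checks use 3 standard errors; calibration
  recovery at n = 50,000 uses ±0.1 on the slope and ±0.05 on CITL and E:O.
  Coefficient recovery from the printed neonatal equation is checked as
  pooled 95%-CI coverage of at least 90% across 20 replicates of n = 50,000
  (200 coefficient-level checks) — a per-coefficient ≥18/20 rule would
  reject a correct implementation about half the time, since each
  coefficient independently clears 18/20 with probability ≈0.92 when true
  coverage is 95%.
* The cascade's per-stage problem sizes in the tests (15,000–20,000 records)
  keep Monte-Carlo noise well below the asserted effects while the full
  suite runs in well under a minute.

## Limitations

The package validates and updates a *given* nine-predictor model; it does not
re-select predictors, fit alternative learners, or handle clustered/limited
dependent outcomes. The middle triage category's published diagnostics are
reproduced only under a stated convention (see above). Likelihood-ratio and
proportion intervals use one defensible method each; publications using other
methods will differ slightly. The generator draws predictors independently
given age — real vitals are correlated — so synthetic AUROCs should not be
read as forecasts of field performance.
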