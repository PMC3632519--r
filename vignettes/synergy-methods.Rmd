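---
title: "Methods: classification, prevalence odds ratios and the synergy index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classification, prevalence odds ratios and the synergy index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortsynergy)
```

## Scope and model

`cohortsynergy` analyses biological (additive) interaction between two binary
risk factors on the prevalence odds of disease in a cross-sectional cohort,
with type 2 diabetes in 60-year-olds as the motivating application. The
pipeline is: classify the outcome, derive binary exposures, estimate
prevalence odds ratios by logistic regression, and summarise departure from
additivity with the synergy index

$$S = \frac{OR_{11} - 1}{(OR_{10} - 1) + (OR_{01} - 1)},$$

where the three odds ratios come from a single logistic fit of the case
indicator on three joint-exposure indicators (A only, B only, both) against
the doubly unexposed reference, optionally with adjustment covariates. The
companion measures RERI $= OR_{11} - OR_{10} - OR_{01} + 1$ and
AP $= \mathrm{RERI}/OR_{11}$ are computed from the same coefficients.

A prevalence odds ratio approximates the incidence rate ratio only under
stable prevalence and equal disease duration across exposure groups; the
package estimates the former and makes no attempt to correct it toward the
latter.

## Outcome classification

A participant is *diabetic* if any of: self-reported diabetes, fasting
glucose $\ge$ 7.0 mmol/l, or use of antidiabetic medication. Otherwise
*prediabetic* (impaired fasting glucose) when glucose lies in 6.1–6.9
mmol/l; otherwise *reference* when a glucose value exists. The band is
implemented as the half-open interval $[6.1, 7.0)$: with glucose reported
to one decimal the two are indistinguishable, and the half-open form keeps
classification total for unrounded inputs. Participants with no glucose
value who meet no diabetes criterion are *excluded* — this includes both a
blank self-report and an explicit "no", since neither can be placed in the
reference or impaired band without a measurement. Classification is a pure
function of the record; raising glucose can never demote a record to a
lower class.

The medication criterion is allowed to act alone (a blank self-report with
antidiabetic medication is classified diabetic): the three criteria are a
disjunction and there is no clinical reason to subordinate one to another.

## Exposure derivation

Parental history of diabetes (PHD) is diabetes in either parent; a
participant not reporting it is unexposed. Maternal-history analyses
exclude participants reporting a diabetic father (and symmetrically),
because a mixed signal would contaminate the single-parent contrast; these
exclusions are counted, never silent. Family history widens PHD with
siblings. Current smokers are contrasted with ex- and never-smokers
combined. Physical inactivity at leisure and at work is the most sedentary
of four ordinal questionnaire levels. BMI uses strict cut-offs (> 25
overweight, > 30 obesity), so a BMI of exactly 30 is overweight but not
obese. The 90th-percentile adiposity cut-offs (SAD, waist, WHR, BMI) are
computed per sex from the analysis cohort itself with the type-7 sample
quantile (linear interpolation between order statistics) — a deliberate
choice that must be documented because percentile conventions differ; a
record is "high" strictly above its sex's cut-off. Cut-off sets are
attached to the classified cohort and can be supplied externally for
reproducibility across cohorts.

## Logistic estimation

Each odds ratio contrasts cases of the target outcome against the
*reference* outcome class only: prediabetes models drop diabetics and vice
versa, so the comparison group is identical across exposures within an
outcome. Fitting is iteratively reweighted least squares (delegated to
`stats::glm.fit` with the deviance tolerance tightened to 1e-12, at most 50
iterations); the coefficient covariance is the inverse observed information
at the MLE. A crude single-binary-exposure fit coincides with the 2×2
cross-product ratio and Woolf standard error, which the test suite asserts
to 1e-9, and with a brute-force likelihood grid search to 1e-6 on small
fixtures. Complete or quasi-complete separation is detected as a diverging
coefficient (|β| > 15 on the log-odds scale) and raised as an error — a
synergy index computed from a divergent cell would be meaningless, and no
Firth-type correction is attempted. Zero cells in the 2×2 oracle are
likewise errors without continuity correction.

Adjusted models use indicator terms for current and ex-smoking (never the
reference), leisure and work inactivity, and BMI as a continuous term by
default. Treating BMI continuously is a design choice where dummy coding
(> 25 / > 30) would also be defensible; `bmi_coding = "categories"`
switches to the dummies. Both-sex models add a female indicator. All models
are complete-case, with dropped and ineligible record counts carried on
every result. Confidence intervals are Wald intervals with $z = 1.959964$;
rounding (one decimal, half away from zero) happens only in the
human-readable report layer, never upstream.

## Interaction confidence intervals

The delta method is applied on $\ln S$: writing $e_{ij} = e^{\beta_{ij}}$,
the gradient of $\ln S$ with respect to $(\beta_{10}, \beta_{01},
\beta_{11})$ is
$\left(-e_{10}/d,\; -e_{01}/d,\; e_{11}/(e_{11}-1)\right)$ with
$d = e_{10} + e_{01} - 2$, propagated through the fitted covariance and
exponentiated back. RERI and AP use their own gradients on their natural
scales. With few doubly exposed cases these intervals are wide; that is the
honest behaviour of the estimator, and a seeded percentile bootstrap
(`ci_method = "bootstrap"`) is provided as a cross-check rather than a
replacement. Degenerate cases carry explicit statuses: `no_result` when
$OR_{11} \le 1$ (no synergy index is reported), and
`undefined_antagonism_denominator` when the denominator is non-positive
while $OR_{11} > 1$. RERI and AP remain defined in both cases. Whenever S
and RERI are both defined, $\mathrm{RERI} > 0 \iff S > 1$.

## The synthetic-cohort generator

No individual-level data ship with the package; the generator produces
cohorts with the statistical structure the analysis assumes, so that every
estimator can be tested against a known truth.

**Outcome model.** The latent class (diabetes / prediabetes / reference) is
drawn from a baseline-category logit with the reference class as baseline:
cell weights $1$, $e^{\beta_0 + x\beta}$, $e^{\gamma_0 + x\gamma}$. This is
the one genuinely consequential design decision in the generator. A
sequential construction (Bernoulli diabetes, then Bernoulli prediabetes
among non-diabetics) was rejected because under it the case-vs-reference
logistic contrast no longer equals the configured log-odds ratio — the
prediabetes model's dependence on the same exposures leaks into the
denominator, biasing the "both exposed" coefficient by more than its
standard error at n = 50 000. With the baseline-category form, fitting
cases against the reference class recovers the configured coefficients
without bias, which the recovery tests confirm.

**Calibration.** The per-sex baselines $(\beta_0, \gamma_0)$ are solved by
Newton iteration over the enumerated joint exposure distribution so the
target prevalences (diabetes 10.1% men / 5.2% women; prediabetes 11.0% /
5.5%) hold in expectation. The default men's configuration additionally
solves the obesity prevalence among the PHD-exposed so that 20.4% of
exposed men are diabetic — this induces a positive obesity–PHD dependence
(odds ratio ≈ 2.3), the generator's expression of the fact that crude and
joint-coded odds ratios need not coincide. Overriding the odds structure
(`beta`, `gamma`) drops that conditional target unless re-stated, since it
encodes the default structure. Infeasible target combinations fail at
configuration time, not at draw time.

**Consistency by construction.** Glucose is drawn from log-normal
distributions parameterised by per-class median and IQR (matched before
truncation, a documented approximation) and truncated to the class band:
reference < 6.1, prediabetes [6.1, 6.9], glucose-identified diabetics
$\ge$ 7.0. Self-report (probability 0.546 men / 0.637 women given
diabetes), medication given self-report (0.78 / 0.71) and a small
never-validated fraction (3% / 13% of self-reporters, who receive normal
glucose and no medication) complete the outcome fields, so
`classify_outcome()` reproduces the latent class of every generated record
— an invariant tested at n = 100 000. BMI is drawn inside the band its
latent flags dictate, and waist, SAD and WHR load on the BMI z-score as a
single latent adiposity factor with loadings chosen so the sex-specific
90th percentiles land near 111 cm / 102 cm (waist), 25.0 cm / 23.5 cm
(SAD), 1.03 / 0.92 (WHR) and 31.7 kg/m² (BMI, men). The exposed-case
structure, not the marginal distributions, drives the estimators, so these
anthropometric choices are deliberately simple.

**What the generator does not emulate.** Records are independent — no
household or family clustering beyond the binary history flags, no
measurement error in glucose (one draw means one measurement), no
differential recall of parental history, and no behaviour change after
diagnosis (in real cohorts, diagnosed participants often alter their
smoking, activity and weight, attenuating cross-sectional exposure
contrasts). Passing tests therefore
demonstrate estimator correctness under the assumed structure, not
robustness to these real-data features.

## Problem sizes and numerical choices

The validation suite uses cohort sizes chosen to make Monte-Carlo noise
small relative to the tolerance being asserted: n = 50 000 × 100 seeds for
parameter recovery (each log-OR and ln S within 3 SE in ≥ 95% of seeds),
n = 5000 × 200 seeds for interval coverage (0.95 ± 0.03; the null-generator
Wald coverage sits near 0.947 when estimated over 600 seeds), n = 4232 ×
500 seeds for calibration of the diabetic fractions (within one percentage
point of 10.1% / 5.2%), and n = 100 000 for the classification-consistency
sweep. Ties in the likelihood-grid oracle are broken by taking the first
maximising grid point; the grid halves its span geometrically, so the
oracle's resolution (~1e-13) is far below the 1e-6 agreement asserted.

## Limitations

No multiple-testing adjustment is applied anywhere (each table reports
marginal 0.05-level tests), matching common practice in descriptive
epidemiology and documented here as a limitation. Separation is an error,
not an estimate: sparse double-exposure cells can make an entire pairing
unreportable, which the report tables flag row-wise rather than failing the
run. Type 1 and type 2 diabetes are not distinguished — at age 60 the
overwhelming majority of prevalent cases are type 2, but the classification
carries no onset-age information. The synergy index itself is only
interpretable for risk factors (both single-exposure odds ratios above 1);
the status flags make the undefined regions explicit instead of reporting a
number whose sign has no meaning.
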