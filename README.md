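# cohortsynergy

Additive interaction analysis of diabetes risk factors in cross-sectional
cohorts: outcome and exposure classification, prevalence odds ratios, and
Rothman's synergy index with delta-method confidence intervals — plus a
calibrated, seeded synthetic-cohort generator so that every stage of the
pipeline can be exercised, validated and power-checked without access to
individual-level data.

## The scientific problem

Family history of diabetes is a proxy for genetic susceptibility; overweight,
physical inactivity and smoking are modifiable risk factors. The
epidemiological question is not only whether each factor raises the
prevalence odds of type 2 diabetes, but whether the joint effect of a
genetic proxy and a lifestyle factor exceeds the *sum* of their separate
effects — biological interaction in Rothman's sense. For two binary
exposures, code the doubly unexposed as reference and estimate three
prevalence odds ratios from one logistic model:

- OR₁₀ — exposure A only,
- OR₀₁ — exposure B only,
- OR₁₁ — both exposures.

Departure from additivity is summarised by the **synergy index**

    S = (OR₁₁ − 1) / [(OR₁₀ − 1) + (OR₀₁ − 1)],

with S > 1 indicating synergy and S < 1 antagonism, together with the
relative excess risk due to interaction, RERI = OR₁₁ − OR₁₀ − OR₀₁ + 1, and
the attributable proportion AP = RERI / OR₁₁. When OR₁₁ ≤ 1 the numerator of
S is non-positive and no index is reported ("no result"); a non-positive
denominator with OR₁₁ > 1 is flagged as an undefined antagonism denominator.
Confidence intervals for S propagate the fitted coefficient covariance
through ln S by the delta method; RERI and AP get delta-method intervals on
their own scales, and a seeded percentile bootstrap is available as a
cross-check.

The package implements the full analysis pipeline around this statistic for
a cohort of 60-year-olds: classification of diabetes (self-report, fasting
glucose ≥ 7.0 mmol/l, or antidiabetic medication), prediabetes (impaired
fasting glucose 6.1–6.9 mmol/l), derived exposures (parental history of
diabetes, current smoking, leisure-time and at-work inactivity, BMI > 25 and
BMI > 30, and sex-specific 90th-percentile cut-offs of SAD, waist
circumference, WHR and BMI), crude and covariate-adjusted prevalence odds
ratios, and descriptive tables with chi-square, Student t and
Kruskal–Wallis tests.

## Worked example

```r
library(cohortsynergy)

coh <- generate_cohort(paper_default_config(), seed = 1)
cc  <- derive_exposures(coh)
table(sex = cc$sex, outcome = cc$outcome_class)
#>         outcome
#> sex      diabetes excluded prediabetes reference
#>   female      132        4         123      2000
#>   male        218        2         237      1516

estimate_or(cc, "phd", "diabetes", sex = "male")
#> OR 3.429 (95% CI 2.474-4.754), beta 1.2324, SE 0.1666, n = 1734

interaction_analysis(cc, "bmi_gt30", "phd", sex = "male")
#> Additive interaction: bmi_gt30 x phd on diabetes (n = 1734)
#>   OR10 3.43 (2.36-4.98)  OR01 2.87 (1.83-4.49)  OR11 8.27 (5.21-13.15)
#>   S 1.69 (95% CI 0.93-3.09)   RERI 2.98 (-0.82-6.78)   AP 0.36 (0.03-0.69)
#>   exposed cases: neither=99, a_only=51, b_only=30, both=38
```

The first call draws a 4232-participant synthetic cohort whose outcome
prevalences, exposure structure and joint odds ratios follow the calibrated
defaults (`cohort_config()` documents every knob; the generator truth for
the obesity-by-parental-history pair in men is OR₁₀ = 3.4, OR₀₁ = 2.0,
OR₁₁ = 9.1, i.e. S ≈ 2.4). The crude odds ratio of diabetes for a parental
history in men, the three joint-coding odds ratios and the synergy index
with its delta-method interval are then estimated from that cohort; at this
sample size the interval around S is wide because only 38 cases are doubly
exposed, which is exactly the behaviour the method is meant to expose.

Full report tables come from the pipeline layer:

```r
rep <- run_report(coh)            # descriptive + OR + interaction tables
write_table3_tsv(rep$table3, "table3.tsv")  # rounded, "No result" convention
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/cohortsynergy` (subcommands `simulate`, `classify`, `analyze`).

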