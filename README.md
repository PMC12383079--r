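# iptwcohort

Causal estimation of how threshold-defined biomarker status affects
genomic-instability outcomes in a population cohort, by inverse probability
of treatment weighting (IPTW), with Factor Analysis of Mixed Data (FAMD)
confounder reduction and random-common-cause refutation — plus a
structural-causal-model cohort simulator with known injected effects so
that every stage is verifiable by parameter recovery.

## Who this is for

Biostatisticians and epidemiologists who want a tested, reproducible
implementation of the octile-threshold IPTW workflow used to study the
impact of LDL oxidizability (LDLox) and nitric-oxide metabolites (NOx) on
three continuous genomic-instability markers — the percentage of telomeres
shorter than 3 kb (CST), initial DNA integrity, and DNA damage after
3.8 Gy — in an age- and sex-stratified cohort of 1326 adults (aged 35–75).

## The method in brief

For a binary exposure rule T (e.g. "LDLox at or above its 87.5% octile",
"HDL-C below 60 mg/dL") and a continuous outcome Y:

1. the mixed continuous/categorical confounder block (age, sex, BMI, WTHR,
   plasma vitamins and trace elements, lifestyle questionnaire items) is
   reduced with FAMD: standardized continuous columns and
   proportion-scaled categorical indicators `(I_j - p_j)/sqrt(p_j)` enter
   a joint SVD; components explaining ≥ 80% of inertia are retained;
2. a logistic propensity model `e(x) = P(T = 1 | components)` is fitted by
   maximum likelihood and clipped to [0.001, 0.999];
3. stabilized weights `w = P(T=1) T/e + P(T=0) (1-T)/(1-e)` feed the Hájek
   estimator — the difference of within-arm weight-renormalized outcome
   means, treated minus control, in outcome percentage points;
4. a percentile bootstrap over subjects (B = 499, propensity refit per
   replicate) gives a two-sided p-value, and the estimate is refuted by
   appending an independent standard-normal "random common cause" to the
   adjustment set: `Var(%) = (effect_initial - effect_RCC)/effect_initial x 100`
   should stay within ±2% for a robust estimate.

Exposure rules cover the seven octiles of LDLox and of NOx, seven
concomitant ("both above") indicators, and guideline thresholds for blood
pressure, HDL-C, LDL-C and HOMA-IR (insulin x glucose / 405) — 33 rules in
all, crossed with the three outcomes. Spearman rank correlations (whole
cohort and per age decade) accompany the causal surface.

Because the original cohort is not public, `generate_cohort()` simulates
one with the published structure: exact strata (635 men / 691 women;
age-decade counts 295, 350, 353, 328), non-Gaussian marginals
quantile-matched to published medians and IQRs (LDLox 17.565 (9.46)
nmol MDA/mL; NOx 25.808 (15.505) µmol/L, ...), a Gaussian-copula
confounding structure, and one injected causal effect with the truth
recorded for recovery testing.

## Worked example

```r
library(iptwcohort)

# a scenario whose injected truth is 3.214 percentage points of CST
# for the HDL-C < 60 mg/dL intervention
scen <- default_scenarios()[["HDL-C_60"]]
gen  <- generate_cohort(scen)

est <- run_iptw(gen$cohort, "HDL-C_60", "cst_pct",
                iptw_config(B = 499L, seed = 7L))
est
#> <causal_estimate> HDL-C_60 -> cst_pct
#>   effect +2.741 percentage points (treated 351 / control 975)
#>   bootstrap p = 0.002 (B = 499)
#>   ESS 297.1 / 951.8, max weight 4.04, 0 propensities clipped

refute_random_common_cause(gen$cohort, "HDL-C_60", "cst_pct",
                           iptw_config(compute_p = FALSE),
                           seed = 8L, initial = est)
#> <refutation_result> HDL-C_60 -> cst_pct
#>   initial +2.741, random-common-cause +2.717, Var 0.873% (robust)

gen$truth$injected_effect   # 3.214  (the injected truth)
gen$truth$naive_contrast    # 3.312  (unadjusted contrast, confounded)
```

Reading the numbers: subjects with HDL-C below 60 mg/dL have, after
weighting, 2.74 percentage points more critically short telomeres than the
rest (p = 0.002); the unadjusted contrast (3.31) overshoots the injected
truth (3.214) because low HDL-C co-occurs with the metabolic-risk
confounder axis, and a single cohort's weighted estimate scatters around
the truth (averaging estimates over many generated cohorts recovers it —
that is what the acceptance script measures). Adding a random common cause
moves the estimate by under 1%, so the estimate is robust in the
refutation sense.

The threshold report reproduces the published table layout:

```r
head(intervention_report(gen$cohort), 4)
#>   intervention sign threshold pct_subjects
#> 1    NOx_Q12.5   >=   16.0923        87.48
#> 2      NOx_Q25   >=   19.4868        74.96
#> 3    NOx_Q37.5   >=   22.5105        62.52
#> 4      NOx_Q50   >=   25.9257        50.00
```

`run_full_analysis(run_config(...))` writes the complete plain-text bundle
(cohort, truth sidecar, threshold report, effect surface, refutation and
correlation reports, recovery summary, run log); a thin command-line
wrapper lives at `inst/cli/iptw-pipeline.R`.

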