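Package: iptwcohort
Title: Causal Effects of Biomarker Threshold Status on Genomic Instability
    Markers via Inverse Probability of Treatment Weighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the effect of threshold-defined biomarker status
    (octile cut points for LDL oxidizability and nitric-oxide metabolites,
    plus guideline thresholds for lipids, blood pressure and insulin
    resistance) on continuous genomic-instability outcomes in an
    age- and sex-stratified cohort.  The pipeline reduces a mixed
    continuous/categorical confounder block with Factor Analysis of Mixed
    Data (FAMD), fits a logistic propensity model on the retained
    components, forms stabilized inverse-probability-of-treatment weights,
    estimates the average treatment effect with the Hajek estimator, and
    tests robustness by re-estimating after injecting a random common
    cause.  A structural-causal-model cohort simulator with known injected
    effects makes every stage verifiable by parameter recovery, and
    Spearman rank correlations provide the companion age-decade-stratified
    association analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
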