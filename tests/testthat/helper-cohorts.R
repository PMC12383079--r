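# Shared fixtures: small cohorts are generated in code, never stored.

small_cohort <- function(n = 400, seed = 101, strength = 1,
                         intervention = "HDL-C_60", tau = 3.214) {
  generate_cohort(scenario_config(
    n_total = n,
    injected_effect = list(intervention = intervention,
                           outcome = "cst_pct", tau = tau),
    strength = strength, seed = seed))
}

# mixed-type confounder table with known structure, for FAMD unit tests
toy_mixed <- function(n = 120, seed = 7) {
  set.seed(seed)
  data.frame(
    x1 = rnorm(n), x2 = rnorm(n, 5, 2), x3 = runif(n),
    f1 = sample(c("a", "b"), n, replace = TRUE),
    f2 = sample(c("u", "v", "w"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}
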