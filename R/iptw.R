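# Inverse probability of treatment weighting: logistic propensity model on
# FAMD components, stabilized weights, Hajek ATE, percentile-bootstrap p.

#' IPTW configuration
#'
#' @param B Bootstrap replicates for the p-value (>= 99; default 499).
#' @param clip Propensity clipping bounds (positivity protection).  The
#'   default `c(0.001, 0.999)` keeps the lower bound below the propensities
#'   that genuinely occur for the rarest interventions (prevalence down to
#'   about 2%); a higher lower bound flattens the weights of exactly those
#'   interventions toward the unadjusted contrast.
#' @param stabilized Multiply arm weights by marginal prevalences (default
#'   TRUE); unstabilized weights are 1/e and 1/(1-e).
#' @param variance_target FAMD inertia fraction retained for the propensity
#'   design (default 0.80).
#' @param n_components Optional fixed number of FAMD components.
#' @param compute_p Whether `run_iptw()` computes the bootstrap p-value.
#' @param seed Seed for the bootstrap resampling.
#' @return List of settings.
#' @export
iptw_config <- function(B = 499L, clip = c(0.001, 0.999), stabilized = TRUE,
                        variance_target = 0.8, n_components = NULL,
                        compute_p = TRUE, seed = 1L) {
  stopifnot(B >= 99L, length(clip) == 2L, clip[1] > 0, clip[2] < 1,
            clip[1] < clip[2])
  list(B = as.integer(B), clip = clip, stabilized = stabilized,
       variance_target = variance_target, n_components = n_components,
       compute_p = compute_p, seed = as.integer(seed))
}

#' Fit a logistic propensity model on component scores
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, gradient tolerance 1e-8, at most 100 iterations).  Fitted
#' probabilities are clipped to the configured bounds; non-convergence or
#' quasi-separation is flagged but clipped probabilities are still returned.
#'
#' @param scores Numeric matrix of covariates (FAMD component scores).
#' @param treatment Binary 0/1 vector; both arms must be non-empty.
#' @param clip Clipping bounds for the fitted probabilities.
#' @return Object of class `propensity_model` with `coefficients`,
#'   clipped `fitted`, `converged`, and the clipping count.
#' @export
fit_propensity <- function(scores, treatment, clip = c(0.001, 0.999)) {
  scores <- as.matrix(scores)
  treatment <- as.integer(treatment)
  stopifnot(length(treatment) == nrow(scores), all(treatment %in% 0:1))
  if (length(unique(treatment)) < 2L) {
    stop("both treatment arms must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, scores)
  fit <- suppressWarnings(stats::glm.fit(
    X, treatment, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  e <- fit$fitted.values
  separated <- any(e < 1e-8 | e > 1 - 1e-8)
  n_clipped <- sum(e < clip[1] | e > clip[2])
  e <- pmin(pmax(e, clip[1]), clip[2])
  structure(list(coefficients = fit$coefficients, fitted = e,
                 converged = fit$converged && !separated,
                 n_clipped = n_clipped, clip = clip),
            class = "propensity_model")
}

#' Inverse-probability-of-treatment weights
#'
#' Unstabilized: w = T/e + (1-T)/(1-e).  Stabilized weights multiply the
#' treated arm by the marginal prevalence P(T=1) and the control arm by
#' P(T=0), which leaves the Hajek estimate unchanged but tames the weight
#' distribution.
#'
#' @param model A `propensity_model`.
#' @param treatment Binary 0/1 vector.
#' @param stabilized Logical.
#' @return Positive weight vector.
#' @export
compute_weights <- function(model, treatment, stabilized = TRUE) {
  stopifnot(inherits(model, "propensity_model"))
  treatment <- as.integer(treatment)
  e <- model$fitted
  w <- treatment / e + (1 - treatment) / (1 - e)
  if (stabilized) {
    p1 <- mean(treatment)
    w <- w * ifelse(treatment == 1, p1, 1 - p1)
  }
  w
}

#' Hajek estimate of the average treatment effect
#'
#' Weighted mean of treated outcomes minus weighted mean of control
#' outcomes, with weights renormalized to sum to one within each arm
#' (treated-minus-control sign convention).
#'
#' @param outcome Continuous outcome vector.
#' @param treatment Binary 0/1 vector.
#' @param weights Positive weights.
#' @return Effect estimate (outcome units).
#' @export
estimate_ate <- function(outcome, treatment, weights) {
  treatment <- as.integer(treatment)
  t1 <- treatment == 1
  if (!any(t1) || all(t1)) stop("both arms must be non-empty", call. = FALSE)
  s1 <- sum(weights[t1]); s0 <- sum(weights[!t1])
  if (s1 <= 0 || s0 <= 0) stop("zero total weight in an arm", call. = FALSE)
  sum(weights[t1] * outcome[t1]) / s1 - sum(weights[!t1] * outcome[!t1]) / s0
}

# effective sample size of a weighted arm: (sum w)^2 / sum w^2
.ess <- function(w) sum(w)^2 / sum(w^2)

# run a block of code with a private RNG stream, restoring global state
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Two-sided percentile-bootstrap p-value for the IPTW effect
#'
#' Resamples subjects with replacement; each replicate refits the propensity
#' model on the resampled component scores, recomputes the weights, and
#' re-estimates the Hajek effect.  The two-sided p-value is
#' 2 min(P*(effect <= 0), P*(effect >= 0)) from the bootstrap proportions,
#' floored at 1/(B+1).  Replicates in which an arm is empty are redrawn (at
#' most 100 retries each).
#'
#' @param scores FAMD component scores (fixed design; not refit per
#'   replicate).
#' @param treatment Binary 0/1 vector.
#' @param outcome Continuous outcome vector.
#' @param B Number of replicates (>= 99).
#' @param seed Seed (deterministic given the same data and seed).
#' @param clip,stabilized Propensity/weight settings.
#' @return List with `p_value` and the bootstrap `effects`.
#' @export
bootstrap_pvalue <- function(scores, treatment, outcome, B = 499L, seed = 1L,
                             clip = c(0.001, 0.999), stabilized = TRUE) {
  stopifnot(B >= 99L)
  scores <- as.matrix(scores)
  n <- length(treatment)
  .with_seed(seed, {
    eff <- numeric(B)
    for (b in seq_len(B)) {
      for (try in seq_len(100L)) {
        idx <- sample.int(n, n, replace = TRUE)
        tb <- treatment[idx]
        if (any(tb == 1L) && any(tb == 0L)) break
        if (try == 100L) stop("could not draw a replicate with both arms",
                              call. = FALSE)
      }
      pm <- fit_propensity(scores[idx, , drop = FALSE], tb, clip = clip)
      wb <- compute_weights(pm, tb, stabilized = stabilized)
      eff[b] <- estimate_ate(outcome[idx], tb, wb)
    }
    p <- 2 * min(mean(eff <= 0), mean(eff >= 0))
    list(p_value = min(1, max(p, 1 / (B + 1))), effects = eff)
  })
}

#' End-to-end IPTW effect of one intervention on one outcome
#'
#' Composes the pipeline stages: build the binary indicator from the
#' intervention specification, reduce the confounder block with FAMD, fit
#' the logistic propensity model on the retained components, form
#' (stabilized) clipped weights, estimate the Hajek ATE and (optionally) the
#' percentile-bootstrap p-value.
#'
#' @param cohort A `cohort_table` with confounder, exposure and outcome
#'   columns.
#' @param spec An [intervention_spec()] or the name of one of the 33
#'   defaults.
#' @param outcome Outcome column name.
#' @param config An [iptw_config()].
#' @param extra_covariates Optional numeric matrix of additional adjustment
#'   columns appended to the retained FAMD component scores before the
#'   propensity fit (used by the random-common-cause refuter; the
#'   dimensionality reduction itself is a fixed preprocessing step and is
#'   not refit around the injected column).
#' @return Object of class `causal_estimate`: intervention and outcome
#'   names, `effect` (percentage points, treated minus control), `p_value`
#'   (NA when `compute_p = FALSE`), arm sizes, weight diagnostics (max
#'   weight, effective sample size per arm, clipping count), convergence
#'   flag and seed.
#' @export
run_iptw <- function(cohort, spec, outcome, config = iptw_config(),
                     extra_covariates = NULL) {
  if (is.character(spec)) {
    spec <- default_intervention_specs()[[spec]] %||%
      stop("unknown intervention name", call. = FALSE)
  }
  if (!outcome %in% names(cohort)) {
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  }
  col <- apply_intervention(spec, cohort)
  treat <- col$indicator
  if (length(unique(treat)) < 2L) {
    stop("intervention '", spec$name, "' is constant in this cohort",
         call. = FALSE)
  }
  conf <- cohort[, confounder_columns(cohort), drop = FALSE]
  class(conf) <- "data.frame"
  fam <- fit_famd(conf, n_components = config$n_components,
                  variance_target = config$variance_target)
  scores <- fam$scores
  if (!is.null(extra_covariates)) {
    scores <- cbind(scores, as.matrix(extra_covariates))
  }
  pm <- fit_propensity(scores, treat, clip = config$clip)
  w <- compute_weights(pm, treat, stabilized = config$stabilized)
  eff <- estimate_ate(cohort[[outcome]], treat, w)
  p <- NA_real_
  if (isTRUE(config$compute_p)) {
    p <- bootstrap_pvalue(scores, treat, cohort[[outcome]], B = config$B,
                          seed = config$seed, clip = config$clip,
                          stabilized = config$stabilized)$p_value
  }
  structure(list(
    intervention = spec$name, outcome = outcome, effect = eff, p_value = p,
    n_treated = sum(treat), n_control = sum(1 - treat),
    max_weight = max(w),
    ess_treated = .ess(w[treat == 1]), ess_control = .ess(w[treat == 0]),
    n_components = fam$n_components, propensity_converged = pm$converged,
    n_clipped = pm$n_clipped, B = if (isTRUE(config$compute_p)) config$B else NA_integer_,
    seed = config$seed), class = "causal_estimate")
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("<causal_estimate> %s -> %s\n", x$intervention, x$outcome))
  cat(sprintf("  effect %+.3f percentage points (treated %d / control %d)\n",
              x$effect, x$n_treated, x$n_control))
  if (!is.na(x$p_value)) {
    cat(sprintf("  bootstrap p = %.3f (B = %d)\n", x$p_value, x$B))
  }
  cat(sprintf("  ESS %0.1f / %0.1f, max weight %.2f, %d propensities clipped\n",
              x$ess_treated, x$ess_control, x$max_weight, x$n_clipped))
  invisible(x)
}
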