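# Synthetic cohort generator: an age- and sex-stratified population with
# non-Gaussian biomarker marginals, a mixed continuous/categorical confounder
# block that genuinely drives both exposures and outcomes, and a single
# injected causal effect whose recovery can be checked against ground truth.

#' Calibrate a log-normal law from a median and an interquartile range
#'
#' Positive biomarkers are simulated as log-normal, quantile-matched to a
#' published median and IQR.  For a log-normal with location \eqn{\mu} and
#' scale \eqn{\sigma}, the median is \eqn{e^\mu} and the IQR is
#' \eqn{2 e^\mu \sinh(z_{0.75}\sigma)}, so the closed-form calibration is
#' \eqn{\mu = \log(\mathrm{median})} and
#' \eqn{\sigma = \mathrm{asinh}(\mathrm{IQR}/(2\,\mathrm{median}))/z_{0.75}}
#' with \eqn{z_{0.75}} the 0.75 standard-normal quantile.
#'
#' @param median Target median (> 0).
#' @param iqr Target interquartile range (> 0; 0 is allowed and yields a
#'   degenerate point mass at the median).
#' @return Named numeric vector with elements `location` and `scale`.
#' @examples
#' calibrate_lognormal(17.565, 9.46)
#' @export
calibrate_lognormal <- function(median, iqr) {
  stopifnot(is.numeric(median), is.numeric(iqr), length(median) == 1L,
            length(iqr) == 1L, is.finite(median), is.finite(iqr))
  if (median <= 0 || iqr < 0) {
    stop("calibrate_lognormal() needs median > 0 and iqr >= 0", call. = FALSE)
  }
  c(location = log(median),
    scale = asinh(iqr / (2 * median)) / stats::qnorm(0.75))
}

# Inverse-CDF of a normal truncated to [lower, upper]; u is standard normal.
.qtruncnorm <- function(u, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::pnorm(u) * (pu - pl), mean, sd)
}

# Marginal specification helpers -------------------------------------------

.lnorm_spec <- function(median, iqr) {
  list(type = "lognormal", median = median, iqr = iqr)
}
.tnorm_spec <- function(median, iqr, lower, upper) {
  # symmetric truncation keeps the median at the target; sd from IQR
  list(type = "truncnorm", median = median, iqr = iqr,
       lower = lower, upper = upper)
}

.apply_marginal <- function(spec, u) {
  switch(spec$type,
    lognormal = {
      p <- calibrate_lognormal(spec$median, spec$iqr)
      exp(p[["location"]] + p[["scale"]] * u)
    },
    truncnorm = .qtruncnorm(u, spec$median, spec$iqr / (2 * stats::qnorm(0.75)),
                            spec$lower, spec$upper),
    stop("unknown marginal type: ", spec$type)
  )
}

#' Default marginal specifications for the generated cohort
#'
#' Continuous biomarkers use log-normal laws quantile-matched to published
#' medians and IQRs; anthropometric and blood-pressure variables use
#' truncated normals.  Vitamins, trace elements, insulin and glucose are not
#' published as median (IQR) in the source tables and use typical adult
#' European reference values; insulin and glucose are chosen so that the
#' derived HOMA-IR (insulin x glucose / 405) has median close to 1.121 and
#' IQR close to 0.953.
#'
#' @return Named list of marginal specifications.
#' @export
default_marginal_specs <- function() {
  list(
    # exposures
    ldlox    = .lnorm_spec(17.565, 9.46),
    nox      = .lnorm_spec(25.808, 15.505),
    hdl_c    = .lnorm_spec(70.49, 25.26),
    ldl_c    = .lnorm_spec(126.864, 41.151),
    insulin  = .lnorm_spec(5.044, 4.24),
    glucose  = .lnorm_spec(90, 15),
    sbp      = .tnorm_spec(130, 26, 80, 230),
    dbp      = .tnorm_spec(80, 15, 40, 140),
    # continuous confounders
    bmi              = .tnorm_spec(25.352, 5.371, 15, 50),
    wthr             = .tnorm_spec(0.906, 0.105, 0.60, 1.30),
    alpha_carotene   = .lnorm_spec(0.10, 0.10),
    beta_carotene    = .lnorm_spec(0.40, 0.38),
    gamma_tocopherol = .lnorm_spec(1.70, 1.30),
    alpha_tocopherol = .lnorm_spec(27.0, 10.5),
    lycopene         = .lnorm_spec(0.55, 0.45),
    retinol          = .lnorm_spec(1.90, 0.70),
    vitamin_d        = .lnorm_spec(52.0, 30.0),
    fe               = .lnorm_spec(18.0, 8.0),
    se               = .lnorm_spec(1.10, 0.30),
    cu_zn_ratio      = .lnorm_spec(1.05, 0.25),
    smoking_years_pos = .lnorm_spec(15, 15)
  )
}

# Loadings of each generated confounder column on the latent structure
# (z_age, z_sex [+1 = female], two correlated lifestyle/metabolic factors
# G_L and G_N).  These only shape realistic inter-confounder correlation;
# exposures and outcomes depend on the *observed* columns, not the latents.
.confounder_loadings <- function() {
  L <- rbind(
    bmi              = c(0.10,  0.00,  0.78,  0.00),
    wthr             = c(0.10, -0.30,  0.68,  0.00),
    alpha_carotene   = c(0.00,  0.10, -0.15,  0.70),
    beta_carotene    = c(0.00,  0.15, -0.10,  0.75),
    gamma_tocopherol = c(0.05,  0.00,  0.10,  0.55),
    alpha_tocopherol = c(0.15,  0.00, -0.60,  0.20),
    lycopene         = c(-0.20, 0.00, -0.60,  0.20),
    retinol          = c(0.10, -0.15,  0.35,  0.00),
    vitamin_d        = c(0.00,  0.00, -0.10,  0.75),
    fe               = c(-0.05, -0.25, 0.40,  0.00),
    se               = c(0.00,  0.00,  0.00,  0.70),
    cu_zn_ratio      = c(0.15,  0.20,  0.65,  0.00),
    smoking_latent   = c(-0.10, -0.15, 0.72,  0.00),
    consume_meat     = c(0.00, -0.25,  0.60,  0.00),
    consume_fish     = c(0.05,  0.00,  0.00,  0.60),
    consume_fruit    = c(0.10,  0.20, -0.20,  0.65),
    consume_vegetables = c(0.05, 0.25, -0.60, 0.30),
    consume_dairy_products = c(-0.05, 0.05, 0.00, 0.15),
    consume_fries_fried_potatos = c(-0.20, -0.15, 0.65, 0.00),
    day_activities_moderate = c(0.35, 0.05, 0.55, -0.15),
    feel_full_of_life = c(0.00, -0.05, -0.15, 0.55),
    drink_wine_never = c(-0.05, 0.15, -0.10, -0.20),
    drink_cola_soft_never = c(0.30, 0.10, -0.20, 0.10),
    lives_with_spouse = c(0.20, -0.10, 0.00, 0.05),
    housing_house    = c(0.15,  0.00,  0.00,  0.05),
    marital_status_married = c(0.25, -0.10, 0.00, 0.00),
    hypertension_treated = c(0.45, 0.00, 0.40, 0.00)
  )
  colnames(L) <- c("z_age", "z_sex", "G_L", "G_N")
  L
}

#' Default confounding strengths
#'
#' Coefficients of each exposure latent and each outcome log-baseline on the
#' four latent confounder axes of the Gaussian copula: standardized age
#' (`age`), standardized female indicator (`sex`), and the two correlated
#' lifestyle/metabolic factors `G_L` (metabolic-risk axis: drives BMI, WTHR,
#' smoking, LDL oxidizability up and antioxidant vitamins down) and `G_N`
#' (antioxidant/nitric-oxide axis: drives carotenoids, vitamin D, selenium
#' and NOx up).  The observed confounder columns are noisy indicators of the
#' same axes, so adjusting for the measured confounder block removes this
#' confounding.  Setting `strength = 0` in [scenario_config()] zeroes all
#' coefficients (unconfounded scenario).
#'
#' @return List with elements `exposures` and `outcomes`, each a named list
#'   of coefficient vectors over `c(age, sex, G_L, G_N)`, plus `shared`
#'   (extra correlation between the LDLox and NOx latents beyond what the
#'   shared axes induce, calibrated to the observed joint frequency of the
#'   concomitant median indicator).
#' @export
default_confounding_strengths <- function() {
  ax <- function(age = 0, sex = 0, G_L = 0, G_N = 0) {
    c(age = age, sex = sex, G_L = G_L, G_N = G_N)
  }
  list(
    exposures = list(
      ldlox   = ax(age = 0.15, G_L = 0.20, G_N = 0.06),
      nox     = ax(age = 0.08, G_L = 0.06, G_N = 0.22),
      hdl_c   = ax(age = -0.05, sex = 0.12, G_L = -0.24),
      ldl_c   = ax(age = 0.15, G_L = 0.22),
      sbp     = ax(age = 0.28, G_L = 0.18),
      dbp     = ax(age = 0.12, G_L = 0.20),
      insulin = ax(age = 0.05, G_L = 0.32),
      glucose = ax(age = 0.12, G_L = 0.18)
    ),
    outcomes = list(
      cst_pct = ax(age = 0.08, G_L = 0.03, G_N = 0.01),
      dna_integrity_pct = ax(age = 0.08, G_L = 0.02, G_N = -0.26),
      dna_damage_38gy_pct = ax(age = 0.06, G_N = -0.08)
    ),
    shared = 0.25
  )
}

#' Scenario configuration for the cohort generator
#'
#' Defines the population structure (stratum counts), the marginal laws, the
#' confounding coefficients, one injected causal effect, and the outcome
#' noise scales.  Defaults reproduce the study population: 1326 subjects
#' (635 men, 691 women), age-decade counts (295, 350, 353, 328) over
#' 35--44 / 45--54 / 55--64 / 65--74 years.  For other `n_total` the strata
#' are scaled proportionally (largest-remainder rounding).
#'
#' @param n_total Total number of subjects.
#' @param n_male,n_female Sex stratum counts (must sum to `n_total`).
#' @param decade_counts Integer vector of four age-decade counts.
#' @param marginal_specs See [default_marginal_specs()].
#' @param confounding_strengths See [default_confounding_strengths()].
#' @param strength Global multiplier applied to all confounding
#'   coefficients; `0` gives the unconfounded scenario.
#' @param injected_effect List with elements `intervention` (an
#'   [intervention_spec()] or the name of a default spec), `outcome`
#'   (outcome column name) and `tau` (effect in outcome percentage points).
#' @param noise_scales Named vector of total marginal log-scale spreads for
#'   the three outcomes (for DNA integrity, of the 100 - integrity deficit).
#'   Defaults are calibrated to the published medians and IQRs.
#' @param seed Master seed; all randomness derives from it.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(n_total = 1326L,
                            n_male = NULL,
                            n_female = NULL,
                            decade_counts = NULL,
                            marginal_specs = default_marginal_specs(),
                            confounding_strengths = default_confounding_strengths(),
                            strength = 1,
                            injected_effect = list(
                              intervention = "Risk_NOx+LDLox_Q87.5",
                              outcome = "cst_pct",
                              tau = 5.434),
                            noise_scales = NULL,
                            seed = 20260922L) {
  n_total <- as.integer(n_total)
  if (is.null(n_male) || is.null(n_female)) {
    if (n_total == 1326L) {
      n_male <- 635L; n_female <- 691L
    } else {
      n_male <- .largest_remainder(n_total, c(635, 691))[1L]
      n_female <- n_total - n_male
    }
  }
  if (is.null(decade_counts)) {
    decade_counts <- if (n_total == 1326L) c(295L, 350L, 353L, 328L) else
      .largest_remainder(n_total, c(295, 350, 353, 328))
  }
  decade_counts <- as.integer(decade_counts)
  if (is.null(noise_scales)) {
    noise_scales <- c(
      cst_pct = unname(calibrate_lognormal(19.733, 14.017)["scale"]),
      dna_integrity_pct = unname(calibrate_lognormal(100 - 75.874, 13.69)["scale"]),
      dna_damage_38gy_pct = unname(calibrate_lognormal(41.224, 12.551)["scale"])
    )
  }
  cfg <- list(n_total = n_total, n_male = as.integer(n_male),
              n_female = as.integer(n_female), decade_counts = decade_counts,
              marginal_specs = marginal_specs,
              confounding_strengths = confounding_strengths,
              strength = strength,
              injected_effect = injected_effect,
              noise_scales = noise_scales,
              seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

.largest_remainder <- function(n, weights) {
  q <- n * weights / sum(weights)
  out <- floor(q)
  rem <- n - sum(out)
  if (rem > 0) {
    idx <- order(q - out, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1
  }
  as.integer(out)
}

#' @rdname scenario_config
#' @param config Object to validate.
#' @export
validate_scenario_config <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  with(config, {
    if (n_male + n_female != n_total) {
      stop("n_male + n_female must equal n_total", call. = FALSE)
    }
    if (length(decade_counts) != 4L || sum(decade_counts) != n_total) {
      stop("decade_counts must be four counts summing to n_total", call. = FALSE)
    }
    if (any(c(n_male, n_female, decade_counts) < 0L)) {
      stop("stratum counts must be non-negative", call. = FALSE)
    }
    if (any(noise_scales <= 0)) {
      stop("noise_scales must be positive", call. = FALSE)
    }
    if (!is.numeric(injected_effect$tau) || !is.finite(injected_effect$tau)) {
      stop("injected effect must be a finite number", call. = FALSE)
    }
  })
  invisible(config)
}

#' Default confounded scenarios used throughout the package
#'
#' Three single-effect scenarios, one per headline intervention on the
#' percentage of critically short telomeres: the combined NOx+LDLox Q87.5
#' indicator (injected effect 5.434 percentage points), HDL-C < 60 mg/dL
#' (3.214) and NOx_Q12.5 (2.492).
#'
#' @param seed Master seed shared by the scenario configs.
#' @return Named list of `scenario_config` objects.
#' @export
default_scenarios <- function(seed = 20260922L) {
  list(
    "Risk_NOx+LDLox_Q87.5" = scenario_config(
      injected_effect = list(intervention = "Risk_NOx+LDLox_Q87.5",
                             outcome = "cst_pct", tau = 5.434),
      seed = seed),
    "HDL-C_60" = scenario_config(
      injected_effect = list(intervention = "HDL-C_60",
                             outcome = "cst_pct", tau = 3.214),
      seed = seed),
    "NOx_Q12.5" = scenario_config(
      injected_effect = list(intervention = "NOx_Q12.5",
                             outcome = "cst_pct", tau = 2.492),
      seed = seed)
  )
}

# ordinal cut from a latent standard normal with given level probabilities
.cut_latent <- function(u, probs, labels) {
  br <- stats::qnorm(cumsum(probs))
  br[length(br)] <- Inf
  labels[findInterval(u, c(-Inf, br[-length(br)]))]
}

#' Generate a synthetic cohort with known ground truth
#'
#' Builds an age- and sex-stratified cohort in which the mixed confounder
#' block drives both the continuous exposures (through a latent-normal score
#' pushed through each marginal quantile transform) and the outcomes
#' (through a linear log-scale baseline), then adds the configured injected
#' effect to the outcome of the treated subjects and clips outcomes to
#' [0, 100].
#'
#' @param config A [scenario_config()].
#' @return List with elements `cohort` (a `data.frame` of class
#'   `cohort_table`) and `truth` (a `truth_record` documenting the injected
#'   effect, the realized naive contrast and clipping counts).
#' @export
generate_cohort <- function(config = scenario_config()) {
  validate_scenario_config(config)
  set.seed(config$seed)
  n <- config$n_total
  if (n < 16L) stop("n_total too small to generate a meaningful cohort",
                    call. = FALSE)
  ms <- config$marginal_specs

  # exact strata: sex and age decade assigned by shuffling fixed labels
  sex <- sample(rep(c("M", "F"), times = c(config$n_male, config$n_female)))
  decade <- sample(rep(1:4, times = config$decade_counts))
  age <- stats::runif(n, 35 + 10 * (decade - 1), 45 + 10 * (decade - 1))
  # keep ages within [35, 75]; the top decade spans 65-75 per the study design
  z_age <- as.numeric(scale(age))
  z_sex <- as.numeric(scale(as.numeric(sex == "F")))

  rho_f <- 0.3
  G_L <- stats::rnorm(n)
  G_N <- rho_f * G_L + sqrt(1 - rho_f^2) * stats::rnorm(n)

  L <- .confounder_loadings()
  latent <- cbind(z_age = z_age, z_sex = z_sex, G_L = G_L, G_N = G_N)
  conf_u <- sapply(rownames(L), function(v) {
    a <- L[v, ]
    sys_var <- sum(a[1:2]^2) + a[3]^2 + a[4]^2 + 2 * a[3] * a[4] * rho_f
    if (sys_var >= 1) stop("confounder loading row '", v, "' exceeds unit variance")
    drop(latent %*% a) + sqrt(1 - sys_var) * stats::rnorm(n)
  })

  # observed confounder columns -------------------------------------------
  smoking_status <- .cut_latent(conf_u[, "smoking_latent"],
                                c(0.48, 0.30, 0.22),
                                c("never", "previous", "current"))
  smoking_years <- ifelse(
    smoking_status == "never", 0,
    .apply_marginal(ms$smoking_years_pos, stats::rnorm(n) * 0.8 +
                      0.2 * conf_u[, "smoking_latent"]))
  month_codes <- c(0, 2, 8, 20, 30)
  consume_probs <- list(
    consume_meat = c(0.04, 0.10, 0.38, 0.30, 0.18),
    consume_fish = c(0.08, 0.30, 0.42, 0.15, 0.05),
    consume_fruit = c(0.03, 0.07, 0.20, 0.30, 0.40),
    consume_vegetables = c(0.02, 0.06, 0.22, 0.32, 0.38),
    consume_dairy_products = c(0.04, 0.08, 0.18, 0.28, 0.42),
    consume_fries_fried_potatos = c(0.15, 0.35, 0.35, 0.10, 0.05)
  )
  consume <- sapply(names(consume_probs), function(v) {
    month_codes[as.integer(.cut_latent(conf_u[, v], consume_probs[[v]],
                                       as.character(1:5)))]
  })
  day_activities_moderate <- as.integer(.cut_latent(
    conf_u[, "day_activities_moderate"], c(0.72, 0.20, 0.08),
    as.character(1:3)))
  feel_full_of_life <- as.integer(.cut_latent(
    conf_u[, "feel_full_of_life"], c(0.03, 0.07, 0.15, 0.25, 0.30, 0.20),
    as.character(1:6)))
  yesno <- function(v, p) ifelse(conf_u[, v] > stats::qnorm(1 - p), "yes", "no")
  cat_cols <- data.frame(
    current_smoker = ifelse(smoking_status == "current", "yes", "no"),
    previous_smoker = ifelse(smoking_status == "previous", "yes", "no"),
    drink_wine_never = yesno("drink_wine_never", 0.30),
    drink_cola_soft_never = yesno("drink_cola_soft_never", 0.45),
    lives_with_spouse = yesno("lives_with_spouse", 0.70),
    housing_house = yesno("housing_house", 0.55),
    marital_status_married = yesno("marital_status_married", 0.68),
    hypertension_treated = yesno("hypertension_treated", 0.16),
    stringsAsFactors = FALSE)

  cont_conf_names <- c("bmi", "wthr", "alpha_carotene", "beta_carotene",
                       "gamma_tocopherol", "alpha_tocopherol", "lycopene",
                       "retinol", "vitamin_d", "fe", "se", "cu_zn_ratio")
  cont_conf <- sapply(cont_conf_names, function(v)
    .apply_marginal(ms[[v]], conf_u[, v]))

  # latent axes driving the exposure/outcome structural equations; the
  # observed confounder block consists of noisy indicators of the same axes
  axes <- cbind(age = z_age, sex = z_sex, G_L = G_L, G_N = G_N)
  cs <- config$confounding_strengths
  str_mult <- config$strength
  lin_score <- function(w) {
    if (str_mult == 0 || length(w) == 0) return(numeric(n))
    miss <- setdiff(names(w), colnames(axes))
    if (length(miss)) stop("unknown confounder axis in strengths: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    drop(axes[, names(w), drop = FALSE] %*% (w * str_mult))
  }

  shared_w <- if (str_mult == 0) 0 else cs$shared
  W <- stats::rnorm(n)
  exposures <- sapply(names(cs$exposures), function(v) {
    s <- lin_score(cs$exposures[[v]])
    sh <- if (v %in% c("ldlox", "nox")) shared_w else 0
    vs <- stats::var(s) + sh^2
    if (vs >= 0.9) stop("exposure confounding for '", v, "' leaves no room for noise",
                        call. = FALSE)
    u <- s + sh * W + sqrt(1 - vs) * stats::rnorm(n)
    .apply_marginal(ms[[v]], u)
  })
  exposures <- as.data.frame(exposures)
  exposures$homa_ir <- homa_ir(exposures$insulin, exposures$glucose)

  cohort <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    sex = sex, age = age,
    cont_conf, smoking_years = smoking_years, consume,
    day_activities_moderate = day_activities_moderate,
    feel_full_of_life = feel_full_of_life,
    cat_cols, exposures,
    stringsAsFactors = FALSE, check.names = FALSE)

  # intervention indicator for the injected effect
  eff <- config$injected_effect
  spec <- if (inherits(eff$intervention, "intervention_spec")) eff$intervention
          else default_intervention_specs()[[eff$intervention]]
  if (is.null(spec)) stop("unknown intervention: ", eff$intervention, call. = FALSE)
  treat <- apply_intervention(spec, cohort)$indicator

  # outcomes ---------------------------------------------------------------
  out_meta <- list(
    cst_pct = list(median = 19.733, flip = FALSE),
    dna_integrity_pct = list(median = 100 - 75.874, flip = TRUE),
    dna_damage_38gy_pct = list(median = 41.224, flip = FALSE))
  clipped <- 0L
  for (oc in names(out_meta)) {
    m <- out_meta[[oc]]
    total_sd <- config$noise_scales[[oc]]
    sys <- lin_score(cs$outcomes[[oc]])
    vs <- stats::var(sys)
    if (vs >= 0.9 * total_sd^2) {
      stop("outcome confounding for '", oc,
           "' exceeds the configured marginal spread", call. = FALSE)
    }
    lg <- log(m$median) + sys + sqrt(total_sd^2 - vs) * stats::rnorm(n)
    y <- if (m$flip) 100 - exp(lg) else exp(lg)
    if (oc == eff$outcome) y <- y + eff$tau * treat
    nclip <- sum(y < 0 | y > 100)
    clipped <- clipped + nclip
    cohort[[oc]] <- pmin(pmax(y, 0), 100)
  }
  if (clipped > 0.01 * 3 * n) {
    stop("configuration error: outcome clipping probability exceeds 1%",
         call. = FALSE)
  }

  naive <- mean(cohort[[eff$outcome]][treat == 1]) -
    mean(cohort[[eff$outcome]][treat == 0])
  truth <- structure(list(
    intervention = spec$name, outcome = eff$outcome,
    injected_effect = eff$tau, seed = config$seed,
    n_treated = sum(treat), naive_contrast = naive,
    clipped = clipped), class = "truth_record")
  class(cohort) <- c("cohort_table", "data.frame")
  attr(cohort, "clipped") <- clipped
  # ground-truth latent axes, kept as an attribute for recovery diagnostics
  attr(cohort, "latent_axes") <- axes
  list(cohort = cohort, truth = truth)
}

#' Names of the exposure, outcome and confounder columns of a cohort table
#'
#' The confounder block is every column except the subject id, the
#' continuous exposures (and derived HOMA-IR), the outcomes, and the
#' treated-hypertension flag (which defines an intervention row, not an
#' adjustment variable).
#'
#' @param cohort A `cohort_table`.
#' @return Character vector of confounder column names.
#' @export
confounder_columns <- function(cohort) {
  drop_cols <- c("subject_id", "ldlox", "nox", "hdl_c", "ldl_c", "insulin",
                 "glucose", "sbp", "dbp", "homa_ir", "hypertension_treated",
                 "cst_pct", "dna_integrity_pct", "dna_damage_38gy_pct")
  setdiff(names(cohort), drop_cols)
}

#' Median/IQR summary of a cohort table
#'
#' @param cohort A non-empty `cohort_table` (or any data.frame).
#' @return A `data.frame` with one row per continuous column (median, IQR)
#'   and one row per level of each categorical column (count).
#' @export
summarize_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop("summarize_cohort() needs a non-empty table", call. = FALSE)
  }
  rows <- list()
  for (v in setdiff(names(cohort), "subject_id")) {
    x <- cohort[[v]]
    if (is.numeric(x)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = NA_character_,
        median = stats::median(x), iqr = stats::IQR(x), count = NA_integer_,
        stringsAsFactors = FALSE)
    } else {
      tab <- table(x)
      for (lv in names(tab)) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lv, median = NA_real_, iqr = NA_real_,
          count = as.integer(tab[[lv]]), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Plain-text I/O ------------------------------------------------------------

#' Write / read a cohort table as comma-separated text
#'
#' @param cohort A `cohort_table`.
#' @param path File path.
#' @return `read_cohort()` returns a `cohort_table`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                       check.names = FALSE)
  class(x) <- c("cohort_table", "data.frame")
  x
}

#' Write / read a ground-truth record as key-value text
#'
#' @param truth A `truth_record`.
#' @param path File path.
#' @return `read_truth_record()` returns a `truth_record`.
#' @export
write_truth_record <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  lines <- vapply(names(truth), function(k) {
    v <- truth[[k]]
    paste0(k, "=", if (is.numeric(v)) format(v, digits = 17) else as.character(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_truth_record
#' @export
read_truth_record <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  out <- stats::setNames(
    lapply(kv, function(p) paste(p[-1], collapse = "=")),
    vapply(kv, `[[`, character(1), 1L))
  num <- c("injected_effect", "seed", "n_treated", "naive_contrast", "clipped")
  for (k in intersect(num, names(out))) out[[k]] <- as.numeric(out[[k]])
  out$seed <- as.integer(out$seed)
  out$n_treated <- as.integer(out$n_treated)
  out$clipped <- as.integer(out$clipped)
  structure(out, class = "truth_record")
}
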