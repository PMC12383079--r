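# Binary "intervention" indicators: octile thresholds for LDLox and NOx,
# combined concomitant indicators, and fixed guideline thresholds.

.OCTILE_LEVELS <- c(0.125, 0.25, 0.375, 0.5, 0.625, 0.75, 0.875)

#' Octile cut points of a continuous vector
#'
#' Seven thresholds at probability levels 12.5%, 25%, ..., 87.5% using the
#' linear-interpolation order-statistic convention h = (n - 1) p + 1
#' (quantile type 7).
#'
#' @param values Numeric vector with at least 8 finite values.
#' @return Named numeric vector of seven non-decreasing thresholds.
#' @examples
#' compute_octiles(1:8)
#' @export
compute_octiles <- function(values) {
  if (!is.numeric(values) || length(values) < 8L || any(!is.finite(values))) {
    stop("compute_octiles() needs >= 8 finite values", call. = FALSE)
  }
  stats::quantile(values, probs = .OCTILE_LEVELS, type = 7, names = TRUE)
}

#' Binarize a continuous variable at a threshold
#'
#' Indicator is 1 when the value is at or above the threshold
#' (`direction = "at_or_above"`, the default used by every intervention
#' except the HDL-C rows) or strictly below it (`direction = "below"`).
#'
#' @param values Finite numeric vector.
#' @param threshold Cut point.
#' @param direction `"at_or_above"` or `"below"`.
#' @param name Optional indicator name.
#' @return An `intervention_column`: list with `name`, binary `indicator`
#'   and `frequency` (percent of subjects with indicator 1).
#' @export
binarize <- function(values, threshold, direction = c("at_or_above", "below"),
                     name = NULL) {
  direction <- match.arg(direction)
  if (any(!is.finite(values))) {
    stop("binarize() needs finite values", call. = FALSE)
  }
  ind <- if (direction == "at_or_above") as.integer(values >= threshold)
         else as.integer(values < threshold)
  new_intervention_column(ind, name %||% paste0("ind_", direction, "_", threshold))
}

new_intervention_column <- function(indicator, name) {
  stopifnot(all(indicator %in% c(0L, 1L)))
  structure(list(name = name, indicator = as.integer(indicator),
                 frequency = 100 * mean(indicator)),
            class = "intervention_column")
}

#' @export
format.intervention_column <- function(x, ...) {
  sprintf("<intervention_column> %s: %d/%d subjects (%.2f%%)",
          x$name, sum(x$indicator), length(x$indicator), x$frequency)
}

#' @export
print.intervention_column <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Concomitant (logical AND) combination of two indicators
#'
#' @param a,b `intervention_column` objects of equal length.
#' @param name Name for the combined indicator.
#' @return An `intervention_column`.
#' @export
combine_indicators <- function(a, b, name) {
  stopifnot(inherits(a, "intervention_column"), inherits(b, "intervention_column"))
  if (length(a$indicator) != length(b$indicator)) {
    stop("combine_indicators(): length mismatch", call. = FALSE)
  }
  new_intervention_column(a$indicator * b$indicator, name)
}

#' Homeostasis Model Assessment of insulin resistance
#'
#' HOMA-IR = fasting insulin (mU/L) x fasting glucose (mg/dL) / 405.
#'
#' @param insulin Fasting insulin, mU/L (positive).
#' @param glucose Fasting glucose, mg/dL (positive).
#' @return Numeric vector of HOMA-IR values.
#' @examples
#' homa_ir(10, 100)  # 1000 / 405
#' @export
homa_ir <- function(insulin, glucose) {
  if (any(!is.finite(insulin)) || any(!is.finite(glucose)) ||
      any(insulin <= 0) || any(glucose <= 0)) {
    stop("homa_ir() needs positive finite inputs", call. = FALSE)
  }
  insulin * glucose / 405
}

#' Construct an intervention specification
#'
#' @param name Indicator name.
#' @param kind One of `"octile"`, `"fixed"`, `"combined"`,
#'   `"sex_specific_fixed"`, `"composite_bp"`.
#' @param variables Column name(s) the rule reads.
#' @param level Octile probability level (octile/combined kinds), one of
#'   0.125, 0.25, ..., 0.875.
#' @param threshold Numeric threshold(s) (fixed kinds).
#' @param direction `"at_or_above"` or `"below"` (below only for HDL-C).
#' @param include_treated For `composite_bp`: whether subjects flagged as
#'   diagnosed-and-treated hypertensive count as exposed even with
#'   controlled measured pressure.
#' @return Object of class `intervention_spec`.
#' @export
intervention_spec <- function(name, kind, variables, level = NULL,
                              threshold = NULL,
                              direction = "at_or_above",
                              include_treated = FALSE) {
  kind <- match.arg(kind, c("octile", "fixed", "combined",
                            "sex_specific_fixed", "composite_bp"))
  if (kind %in% c("octile", "combined")) {
    if (is.null(level) || !level %in% .OCTILE_LEVELS) {
      stop("octile level must be one of ", paste(.OCTILE_LEVELS, collapse = ", "),
           call. = FALSE)
    }
    if (kind == "combined" && length(variables) != 2L) {
      stop("combined kind references exactly two variables", call. = FALSE)
    }
  }
  if (direction == "below" && !grepl("^hdl", variables[1])) {
    stop("direction 'below' is reserved for HDL-C interventions", call. = FALSE)
  }
  structure(list(name = name, kind = kind, variables = variables,
                 level = level, threshold = threshold, direction = direction,
                 include_treated = include_treated),
            class = "intervention_spec")
}

#' Apply an intervention specification to a cohort
#'
#' Octile kinds compute their cut point in-sample from the named column;
#' fixed kinds use the stored threshold; the combined kind takes the
#' elementwise AND of the two member octile indicators; the sex-specific
#' HDL-C rule uses 40 mg/dL for men and 50 mg/dL for women; the composite
#' blood-pressure rules use measured SBP >= 140 or DBP >= 90, optionally
#' extended by the diagnosed-and-treated hypertension flag.
#'
#' @param spec An [intervention_spec()].
#' @param cohort A `cohort_table` (or data.frame) with the required columns.
#' @return An `intervention_column`.
#' @export
apply_intervention <- function(spec, cohort) {
  stopifnot(inherits(spec, "intervention_spec"))
  need <- switch(spec$kind,
                 sex_specific_fixed = c(spec$variables, "sex"),
                 composite_bp = c("sbp", "dbp",
                                  if (spec$include_treated) "hypertension_treated"),
                 spec$variables)
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  switch(spec$kind,
    octile = {
      thr <- compute_octiles(cohort[[spec$variables]])[[paste0(100 * spec$level, "%")]]
      binarize(cohort[[spec$variables]], thr, spec$direction, name = spec$name)
    },
    fixed = binarize(cohort[[spec$variables]], spec$threshold, spec$direction,
                     name = spec$name),
    combined = {
      a <- apply_intervention(
        intervention_spec(paste0(spec$variables[1], "_m"), "octile",
                          spec$variables[1], level = spec$level), cohort)
      b <- apply_intervention(
        intervention_spec(paste0(spec$variables[2], "_m"), "octile",
                          spec$variables[2], level = spec$level), cohort)
      combine_indicators(a, b, spec$name)
    },
    sex_specific_fixed = {
      v <- cohort[[spec$variables]]
      thr <- ifelse(cohort$sex == "M", spec$threshold[1], spec$threshold[2])
      new_intervention_column(as.integer(v < thr), spec$name)
    },
    composite_bp = {
      unc <- cohort$sbp >= 140 | cohort$dbp >= 90
      if (spec$include_treated) {
        unc <- unc | cohort$hypertension_treated == "yes"
      }
      new_intervention_column(as.integer(unc), spec$name)
    })
}

#' The default intervention specifications
#'
#' Seven NOx octiles, seven LDLox octiles, seven combined concomitant
#' indicators, four blood-pressure rules, two HDL-C rules (the only rows
#' thresholded from below), four LDL-C rules and two HOMA-IR rules.
#'
#' @return Named list of 33 `intervention_spec` objects.
#' @export
default_intervention_specs <- function() {
  specs <- list()
  qlab <- function(p) sub("\\.?0+$", "", sprintf("%.1f", 100 * p))
  for (p in .OCTILE_LEVELS) {
    specs[[paste0("NOx_Q", qlab(p))]] <-
      intervention_spec(paste0("NOx_Q", qlab(p)), "octile", "nox", level = p)
  }
  for (p in .OCTILE_LEVELS) {
    specs[[paste0("LDLox_Q", qlab(p))]] <-
      intervention_spec(paste0("LDLox_Q", qlab(p)), "octile", "ldlox", level = p)
  }
  for (p in .OCTILE_LEVELS) {
    nm <- paste0("Risk_NOx+LDLox_Q", qlab(p))
    specs[[nm]] <- intervention_spec(nm, "combined", c("nox", "ldlox"), level = p)
  }
  specs[["HBP_systolic_stage1"]] <-
    intervention_spec("HBP_systolic_stage1", "fixed", "sbp", threshold = 140)
  specs[["HBP_diastolic_stage1"]] <-
    intervention_spec("HBP_diastolic_stage1", "fixed", "dbp", threshold = 90)
  specs[["HBP_uncontrolled_stage1"]] <-
    intervention_spec("HBP_uncontrolled_stage1", "composite_bp", c("sbp", "dbp"))
  specs[["HBP_stage1"]] <-
    intervention_spec("HBP_stage1", "composite_bp", c("sbp", "dbp"),
                      include_treated = TRUE)
  specs[["HDL-C_40_50"]] <-
    intervention_spec("HDL-C_40_50", "sex_specific_fixed", "hdl_c",
                      threshold = c(40, 50), direction = "below")
  specs[["HDL-C_60"]] <-
    intervention_spec("HDL-C_60", "fixed", "hdl_c", threshold = 60,
                      direction = "below")
  for (thr in c(70, 100, 116, 190)) {
    nm <- paste0("LDL-C_", thr)
    specs[[nm]] <- intervention_spec(nm, "fixed", "ldl_c", threshold = thr)
  }
  for (thr in c(1.9, 2.9)) {
    nm <- paste0("HOMA_", thr)
    specs[[nm]] <- intervention_spec(nm, "fixed", "homa_ir", threshold = thr)
  }
  specs
}

#' Build every default intervention indicator for a cohort
#'
#' @param cohort A `cohort_table` with exposure columns, `sex` and the
#'   treated-hypertension flag.
#' @param specs Intervention specifications (default: all 33).
#' @return Named list of `intervention_column` objects.
#' @export
build_intervention_table <- function(cohort, specs = default_intervention_specs()) {
  lapply(specs, apply_intervention, cohort = cohort)
}

#' Threshold report (name, sign, threshold, percent of subjects)
#'
#' @param cohort A `cohort_table`.
#' @param specs Intervention specifications.
#' @return A `data.frame` with columns `intervention`, `sign`, `threshold`,
#'   `pct_subjects` (rounded to 2 decimals).
#' @export
intervention_report <- function(cohort, specs = default_intervention_specs()) {
  cols <- build_intervention_table(cohort, specs)
  thr_label <- function(sp) {
    switch(sp$kind,
      octile = sprintf("%.6g", compute_octiles(cohort[[sp$variables]])[[
        paste0(100 * sp$level, "%")]]),
      fixed = sprintf("%.6g", sp$threshold),
      combined = "-",
      sex_specific_fixed = paste(sp$threshold, collapse = "/"),
      composite_bp = "composite")
  }
  data.frame(
    intervention = vapply(specs, `[[`, character(1), "name"),
    sign = vapply(specs, function(sp)
      if (sp$direction == "below") "<" else ">=", character(1)),
    threshold = vapply(specs, thr_label, character(1)),
    pct_subjects = round(vapply(cols, `[[`, numeric(1), "frequency"), 2),
    row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
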