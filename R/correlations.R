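# Spearman rank correlations between the continuous exposures and the three
# genomic-instability outcomes, whole-cohort and per age decade.

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of midranked data; the two-sided p-value
#' uses t = rho sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value` and `n`.
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))  # rho = 0.8
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("spearman_cor() needs n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rho undefined for a constant vector", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

# decade membership by floored age: [35,44], [45,54], [55,64], [65,74]
.decade_label <- function(age) {
  fl <- floor(age)
  lab <- rep(NA_character_, length(age))
  lab[fl >= 35 & fl <= 44] <- "35-44"
  lab[fl >= 45 & fl <= 54] <- "45-54"
  lab[fl >= 55 & fl <= 64] <- "55-64"
  lab[fl >= 65 & fl <= 74] <- "65-74"
  lab
}

#' Whole-cohort and age-decade-stratified Spearman correlations
#'
#' For each exposure in `exposures` and each outcome in `outcomes`, computes
#' rho, p and n within each age decade (35--44, 45--54, 55--64, 65--74 on
#' floored age) and over the entire cohort (`stratum = "all"`).  An empty
#' stratum yields an undefined cell (NA rho/p, n = 0).
#'
#' @param cohort A `cohort_table` with an `age` column.
#' @param exposures Exposure column names (default LDLox and NOx).
#' @param outcomes Outcome column names (default the three genomic
#'   instability markers).
#' @return A `data.frame` with columns `stratum`, `exposure`, `outcome`,
#'   `rho`, `p_value`, `n`.
#' @export
stratified_correlations <- function(cohort,
                                    exposures = c("ldlox", "nox"),
                                    outcomes = c("cst_pct",
                                                 "dna_integrity_pct",
                                                 "dna_damage_38gy_pct")) {
  if (!"age" %in% names(cohort)) stop("cohort needs an 'age' column", call. = FALSE)
  lab <- .decade_label(cohort$age)
  strata <- c("35-44", "45-54", "55-64", "65-74", "all")
  rows <- list()
  for (st in strata) {
    idx <- if (st == "all") rep(TRUE, nrow(cohort)) else !is.na(lab) & lab == st
    for (ex in exposures) {
      for (oc in outcomes) {
        if (sum(idx) >= 3L) {
          cc <- spearman_cor(cohort[[ex]][idx], cohort[[oc]][idx])
          rows[[length(rows) + 1L]] <- data.frame(
            stratum = st, exposure = ex, outcome = oc, rho = cc$rho,
            p_value = cc$p_value, n = cc$n, stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            stratum = st, exposure = ex, outcome = oc, rho = NA_real_,
            p_value = NA_real_, n = sum(idx), stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}
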