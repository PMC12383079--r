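# Factor Analysis of Mixed Data: joint factorization of standardized
# continuous columns and proportion-scaled categorical indicator columns.
# With continuous-only input it reduces exactly to PCA of standardized data.

#' Fit a Factor Analysis of Mixed Data model
#'
#' Continuous columns are centered and scaled to unit (population) variance.
#' Each categorical column is expanded into level indicators; the indicator
#' for level j with proportion p_j is transformed to (I_j - p_j) / sqrt(p_j),
#' so that the column's contribution to total inertia is (number of levels
#' - 1).  The combined matrix is factorized by singular value decomposition;
#' components are ordered by singular value.  Total inertia equals
#' (number of continuous columns) + (number of levels - number of
#' categorical columns).
#'
#' @param data A data.frame of confounders with >= 2 columns and no missing
#'   values.  Numeric columns are treated as continuous (ordinal scores
#'   included); character/factor columns as categorical.
#' @param n_components Number of components to retain; overrides
#'   `variance_target` when given.  `Inf` retains the full rank.
#' @param variance_target Retain the smallest number of components whose
#'   explained-inertia ratios sum to at least this value (default 0.80).
#' @param on_degenerate `"fail"` (default) errors on a zero-variance
#'   continuous column or single-level categorical column; `"drop"` removes
#'   such columns with a warning.
#' @return Object of class `famd_model` with centering/scaling parameters,
#'   level proportions, orthonormal loadings, singular values,
#'   explained-variance ratios, retained scores and `n_components`.
#' @export
fit_famd <- function(data, n_components = NULL, variance_target = 0.8,
                     on_degenerate = c("fail", "drop")) {
  on_degenerate <- match.arg(on_degenerate)
  stopifnot(is.data.frame(data))
  if (ncol(data) < 2L) stop("fit_famd() needs >= 2 columns", call. = FALSE)
  if (anyNA(data)) stop("fit_famd() does not accept missing values", call. = FALSE)
  n <- nrow(data)
  is_cat <- vapply(data, function(x) is.character(x) || is.factor(x), logical(1))

  bad <- character(0)
  for (v in names(data)[!is_cat]) {
    if (stats::var(data[[v]]) == 0) bad <- c(bad, v)
  }
  for (v in names(data)[is_cat]) {
    if (length(unique(as.character(data[[v]]))) < 2L) bad <- c(bad, v)
  }
  if (length(bad)) {
    if (on_degenerate == "fail") {
      stop("degenerate column(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    warning("dropping degenerate column(s): ", paste(bad, collapse = ", "))
    data <- data[, setdiff(names(data), bad), drop = FALSE]
    is_cat <- is_cat[setdiff(names(is_cat), bad)]
  }

  blocks <- list(); centers <- list(); scales <- list(); props <- list()
  col_var <- character(0)
  for (v in names(data)) {
    if (!is_cat[[v]]) {
      x <- data[[v]]
      ctr <- mean(x)
      scl <- sqrt(sum((x - ctr)^2) / n)  # population sd => unit inertia
      blocks[[v]] <- matrix((x - ctr) / scl, ncol = 1,
                            dimnames = list(NULL, v))
      centers[[v]] <- ctr; scales[[v]] <- scl
      col_var <- c(col_var, v)
    } else {
      x <- as.character(data[[v]])
      lv <- sort(unique(x))
      p <- vapply(lv, function(l) mean(x == l), numeric(1))
      Z <- sapply(lv, function(l) ((x == l) - p[[l]]) / sqrt(p[[l]]))
      colnames(Z) <- paste(v, lv, sep = ".")
      blocks[[v]] <- Z
      props[[v]] <- p
      col_var <- c(col_var, rep(v, length(lv)))
    }
  }
  Z <- do.call(cbind, blocks)
  sv <- svd(Z)
  inertia <- sv$d^2 / n
  total <- sum(inertia)
  ratios <- inertia / total
  k <- if (!is.null(n_components)) {
    min(ncol(Z), if (is.infinite(n_components)) ncol(Z) else as.integer(n_components))
  } else {
    which(cumsum(ratios) >= variance_target - 1e-12)[1L]
  }
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  colnames(scores) <- paste0("comp", seq_len(k))
  structure(list(
    columns = names(data), is_cat = is_cat, centers = centers,
    scales = scales, props = props, loadings = sv$v,
    singular_values = sv$d, inertia = inertia, total_inertia = total,
    explained_variance_ratio = ratios, n_components = k,
    scores = scores, n = n), class = "famd_model")
}

#' Project (new) observations onto fitted FAMD components
#'
#' Uses the centering/scaling parameters and level proportions stored at fit
#' time; on the training table this reproduces the fitted scores.
#'
#' @param model A `famd_model`.
#' @param data A data.frame with the same columns (and, for categorical
#'   columns, no unseen levels) as the fitting table.
#' @return Matrix of component scores (n x `n_components`).
#' @export
famd_transform <- function(model, data) {
  stopifnot(inherits(model, "famd_model"))
  miss <- setdiff(model$columns, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  blocks <- list()
  for (v in model$columns) {
    if (!model$is_cat[[v]]) {
      blocks[[v]] <- matrix((data[[v]] - model$centers[[v]]) / model$scales[[v]],
                            ncol = 1)
    } else {
      x <- as.character(data[[v]])
      p <- model$props[[v]]
      unseen <- setdiff(unique(x), names(p))
      if (length(unseen)) {
        stop("unseen level(s) in '", v, "': ", paste(unseen, collapse = ", "),
             call. = FALSE)
      }
      blocks[[v]] <- sapply(names(p), function(l) ((x == l) - p[[l]]) / sqrt(p[[l]]))
      if (nrow(data) == 1L) blocks[[v]] <- matrix(blocks[[v]], nrow = 1)
    }
  }
  Z <- do.call(cbind, blocks)
  k <- model$n_components
  scores <- Z %*% model$loadings[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("comp", seq_len(k))
  scores
}

#' Explained-inertia ratios of a fitted FAMD model
#'
#' Squared singular values normalized by total inertia, in non-increasing
#' order (all components, not just the retained ones).
#'
#' @param model A `famd_model`.
#' @return Numeric vector of ratios summing to 1 over the full rank.
#' @export
explained_variance <- function(model) {
  stopifnot(inherits(model, "famd_model"))
  model$explained_variance_ratio
}

#' @export
print.famd_model <- function(x, ...) {
  cat(sprintf(
    "<famd_model> %d columns (%d categorical), total inertia %.3f\n",
    length(x$columns), sum(x$is_cat), x$total_inertia))
  cat(sprintf("  retained %d components explaining %.1f%% of inertia\n",
              x$n_components,
              100 * sum(x$explained_variance_ratio[seq_len(x$n_components)])))
  invisible(x)
}

#' Serialize / restore a fitted FAMD model as structured text
#'
#' @param model A `famd_model`.
#' @param path File path (plain text, dput format).
#' @return `read_famd_model()` returns a `famd_model`.
#' @export
write_famd_model <- function(model, path) {
  stopifnot(inherits(model, "famd_model"))
  dput(unclass(model), file = path)
  invisible(path)
}

#' @rdname write_famd_model
#' @export
read_famd_model <- function(path) {
  structure(dget(path), class = "famd_model")
}
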