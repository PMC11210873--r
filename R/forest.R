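#' Fit a Gini node-purity random forest
#'
#' Classification forest in which every tree is grown on a bootstrap resample
#' of the patients (size N, with replacement) restricted to a uniformly random
#' fraction of the columns, splitting to maximize the Gini impurity reduction
#' \eqn{\Delta I_A = p(A)I(A) - p(A_L)I(A_L) - p(A_R)I(A_R)}. Per-column
#' importance is the sum of \eqn{\Delta I} over all splits on the column,
#' standardized by the number of trees. All ties (equal-gain splits, vote ties)
#' are broken deterministically, and a fixed seed reproduces the ensemble
#' bit-for-bit.
#'
#' @param features Numeric matrix or data frame of predictors (patients in
#'   rows); no missing values.
#' @param outcomes Factor (or coercible) of per-patient outcome classes; at
#'   least two classes must be present.
#' @param n_trees Number of trees (default 500).
#' @param feature_fraction Fraction of columns drawn per tree (default 0.8).
#' @param bootstrap Draw a size-N bootstrap per tree (default `TRUE`; `FALSE`
#'   gives deterministic single-tree fits, used for oracle checks).
#' @param seed Integer seed for the forest's internal RNG.
#' @return A `k_forest` object.
#' @export
fit_forest <- function(features, outcomes, n_trees = 500,
                       feature_fraction = 0.8, bootstrap = TRUE, seed = 1) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("features contain missing values", call. = FALSE)
  if (ncol(X) < 1) stop("no feature columns", call. = FALSE)
  y <- as.factor(outcomes)
  if (length(y) != nrow(X)) stop("outcome length != number of rows", call. = FALSE)
  fit <- rf_fit_cpp(X, as.integer(y) - 1L, nlevels(y), as.integer(n_trees),
                    feature_fraction, isTRUE(bootstrap), as.numeric(seed))
  structure(list(fit = fit, classes = levels(y), columns = colnames(X),
                 config = list(n_trees = n_trees,
                               feature_fraction = feature_fraction,
                               bootstrap = bootstrap, seed = seed)),
            class = "k_forest")
}

#' @export
predict.k_forest <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (!is.null(object$columns) && !is.null(colnames(X)) &&
      !identical(colnames(X), object$columns)) {
    stop("prediction columns do not match training columns", call. = FALSE)
  }
  idx <- rf_predict_cpp(object$fit, X)
  factor(object$classes[idx + 1L], levels = object$classes)
}

#' Per-column impurity-reduction importance
#'
#' @param fit A `k_forest` from [fit_forest()].
#' @return Named numeric vector, one nonnegative value per column.
#' @export
column_importance <- function(fit) {
  setNames(as.numeric(fit$fit$importance), fit$columns)
}

#' Aggregate column importance into variable groups
#'
#' Spatial interactions are represented by d principal-component columns whose
#' importances are summed; meta-variables map one-to-one.
#'
#' @param col_importance Named numeric vector from [column_importance()].
#' @param groups Tibble with columns `column` (feature column name) and
#'   `variable` (group name); every feature column must appear exactly once.
#' @return Named numeric vector of per-variable importances, in the order
#'   groups first appear.
#' @export
group_importance <- function(col_importance, groups) {
  if (!all(names(col_importance) %in% groups$column)) {
    stop("group map does not cover all columns", call. = FALSE)
  }
  v <- tapply(col_importance[groups$column], groups$variable, sum)
  as.numeric(v)[match(unique(groups$variable), names(v))] |>
    setNames(unique(groups$variable))
}

#' @export
print.k_forest <- function(x, ...) {
  cat("Gini node-purity random forest:", x$fit$n_trees, "trees,",
      length(x$columns), "features,", length(x$classes), "classes\n")
  invisible(x)
}
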