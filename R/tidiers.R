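#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an importance result
#'
#' @param x An `importance_result`.
#' @param ... Unused.
#' @return The per-variable importance tibble (variable, kind, raw and
#'   adjusted importance, CV spread, rank, thresholds, significance calls),
#'   ordered by rank.
#' @export
tidy.importance_result <- function(x, ...) {
  x$importance
}

#' One-row summary of an importance result
#'
#' @param x An `importance_result`.
#' @param ... Unused.
#' @return Tibble with accuracy estimates, thresholds and counts of
#'   significant variables.
#' @export
glance.importance_result <- function(x, ...) {
  tibble::tibble(
    n_variables = nrow(x$importance),
    n_significant_vi_only = sum(x$importance$significant_vi_only),
    n_significant_vi_minus_sd = sum(x$importance$significant_vi_minus_sd),
    q_noise = x$thresholds$Q_noise,
    oob = x$accuracy$oob,
    guess = x$accuracy$guess,
    bias = x$accuracy$bias
  )
}
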