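# Visualisation: the variable-importance plot (dot-and-interval chart with
# noise and interpolation thresholds) and a K-function comparison plot.

#' Variable importance plot
#'
#' Horizontal dot plot of adjusted variable importances, standardized by the
#' largest value so the axis runs from 0 to 1, with one-adjusted-SD intervals,
#' the noise threshold (red dotted vertical line), the rank-wise interpolation
#' threshold (orange dashed curve), and an OOB/GUESS/BIAS footer.
#'
#' @param object An `importance_result`.
#' @param top_k Show only the `top_k` largest importances (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.importance_result <- function(object, top_k = NULL, ...) {
  imp <- dplyr::arrange(object$importance, .data$rank)
  if (!is.null(top_k)) imp <- head(imp, top_k)
  scale_max <- max(object$importance$vi_adj, 1e-12)
  imp <- imp |>
    dplyr::mutate(
      std_vi = .data$vi_adj / scale_max,
      std_lo = pmax(0, (.data$vi_adj - .data$sd_adj) / scale_max),
      std_hi = (.data$vi_adj + .data$sd_adj) / scale_max,
      std_int = .data$q_int_at_rank / scale_max,
      variable = factor(.data$variable, levels = rev(.data$variable)))
  footer <- sprintf("OOB = %.3f   GUESS = %.3f   BIAS = %.3f",
                    object$accuracy$oob, object$accuracy$guess,
                    object$accuracy$bias)
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$std_vi, y = .data$variable)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$std_lo,
                                         xmax = .data$std_hi),
                            height = 0.3, colour = "grey60") +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::geom_vline(xintercept = object$thresholds$Q_noise / scale_max,
                        colour = "red", linetype = "dotted") +
    ggplot2::geom_path(ggplot2::aes(x = .data$std_int, group = 1),
                       colour = "orange", linetype = "dashed") +
    ggplot2::labs(x = "standardized adjusted variable importance", y = NULL,
                  caption = footer) +
    ggplot2::coord_cartesian(xlim = c(0, max(1, imp$std_hi))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.importance_result
#' @param result An `importance_result`.
#' @export
plot_importance <- function(result, top_k = NULL) {
  autoplot.importance_result(result, top_k = top_k)
}

#' K-function comparison plot for one interaction
#'
#' Per-patient K curves coloured by outcome, bold pointwise class means, and
#' the \eqn{\pi r^2} complete-spatial-randomness reference (dashed).
#'
#' @param kset A `k_set` from [cohort_k()].
#' @param pair Pair label (`"<t>_<t'>"`).
#' @param outcomes Optional tibble (`patient_id`, `outcome`) for colouring.
#' @return A ggplot object.
#' @export
plot_k_functions <- function(kset, pair, outcomes = NULL) {
  sub <- dplyr::filter(tibble::as_tibble(kset), .data$pair == !!pair,
                       .data$defined)
  if (nrow(sub) == 0) stop("pair not present or never defined", call. = FALSE)
  if (!is.null(outcomes)) {
    sub <- dplyr::left_join(sub, outcomes, by = "patient_id")
  } else {
    sub$outcome <- "all"
  }
  means <- sub |>
    dplyr::group_by(.data$outcome, .data$r) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  csr <- tibble::tibble(r = sort(unique(sub$r)))
  csr$value <- pi * csr$r^2
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$r, y = .data$value,
                                    colour = .data$outcome)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient_id), alpha = 0.25) +
    ggplot2::geom_line(data = means, linewidth = 1.1,
                       ggplot2::aes(group = .data$outcome)) +
    ggplot2::geom_line(data = csr, colour = "black", linetype = "dashed",
                       ggplot2::aes(group = 1)) +
    ggplot2::labs(x = "r", y = bquote(K(r)), title = pair) +
    ggplot2::theme_minimal()
}
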