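# Predictive-accuracy estimates reported alongside variable importance.
# OOB is cross-validated held-out accuracy (not tree-level out-of-bag);
# GUESS and BIAS are the frequency-matched and modal-class baselines.

#' Held-out (OOB) classification accuracy
#'
#' Mean agreement between each patient's outcome and the prediction from the
#' model fit with that patient's fold removed.
#'
#' @param predictions Factor of held-out predictions, one per patient.
#' @param outcomes Factor of observed outcomes.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy_oob <- function(predictions, outcomes) {
  if (anyNA(predictions)) stop("missing held-out prediction(s)", call. = FALSE)
  if (length(predictions) != length(outcomes)) {
    stop("predictions and outcomes differ in length", call. = FALSE)
  }
  mean(as.character(predictions) == as.character(outcomes))
}

#' Frequency-matched guessing accuracy
#'
#' Probability of a correct guess when the outcome is drawn at random with the
#' observed class frequencies: \eqn{\sum_i p_i^2}.
#'
#' @param outcomes Factor (or vector) of observed outcomes.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy_guess <- function(outcomes) {
  p <- table(outcomes) / length(outcomes)
  sum(p^2)
}

#' Modal-class accuracy
#'
#' Accuracy of always predicting the most prevalent outcome (ties broken by
#' lowest class label); `max(p, 1 - p)` for binary outcomes.
#'
#' @inheritParams accuracy_guess
#' @return Fraction in `[0, 1]`.
#' @export
accuracy_bias <- function(outcomes) {
  p <- table(outcomes) / length(outcomes)
  max(p)
}
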