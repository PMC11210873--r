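#' Full analysis pipeline: cells to significant interactions
#'
#' Runs the complete workflow on a cohort: patient-level cross-type K
#' functions with isotropic edge correction, FPCA reduction to d scores per
#' interaction, and the synthetic-variable random-forest significance
#' analysis with accuracy estimates.
#'
#' @param cells A `cell_table` (see [read_cells()] / [as_cell_table()]).
#' @param outcomes Tibble (`patient_id`, `outcome`).
#' @param meta Optional tibble: `patient_id` plus numeric meta-variables.
#' @param pairs Optional restriction of the ordered phenotype pairs
#'   (two-column data frame `t`, `t_prime`); defaults to all \eqn{T^2}.
#' @param r_max Maximum K-function radius; default 25% of the shortest window
#'   side.
#' @param n_r Radius grid points (default 50).
#' @param correction Edge correction, `"isotropic"` (default) or `"none"`.
#' @param d Principal components per interaction (default 3).
#' @inheritParams vi_significance
#' @return An `importance_result` (see [vi_significance()]) with the K set and
#'   scores attached as `k_set` and `scores`.
#' @examples
#' \donttest{
#' sim <- simulate_cohort(sim_profile_4type(relation = TRUE), seed = 7)
#' res <- analyze_cohort(sim$cells, sim$outcomes, sim$meta,
#'                       B = 20, H = 20, n_trees = 100, seed = 7)
#' res$importance
#' }
#' @export
analyze_cohort <- function(cells, outcomes, meta = NULL, pairs = NULL,
                           r_max = NULL, n_r = 50,
                           correction = c("isotropic", "none"), d = 3,
                           B = 100, H = 100, alpha_q = 0.95, folds = 10,
                           n_trees = 500, feature_fraction = 0.8, seed = 1) {
  correction <- match.arg(correction)
  kset <- cohort_k(cells, pairs = pairs, r_max = r_max, n_r = n_r,
                   correction = correction)
  scores <- pc_scores(kset, d = d)
  res <- vi_significance(scores, outcomes, meta = meta, B = B, H = H,
                         alpha_q = alpha_q, folds = folds, n_trees = n_trees,
                         feature_fraction = feature_fraction, seed = seed)
  res$k_set <- kset
  res$scores <- scores
  res
}

#' Family-wise discovery flags for every rule/threshold combination
#'
#' Evaluates, for one analysis, whether any variable is called significant
#' under each decision rule (`vi_only`, `vi_minus_sd`, `largest_only`) against
#' each threshold (`noise`, `interpolation`, `both`) — the nine cells of the
#' false-discovery-rate experiment.
#'
#' @param result An `importance_result`.
#' @return Tibble (`mode`, `threshold`, `flagged`).
#' @export
significance_table <- function(result) {
  tidyr::crossing(mode = c("vi_only", "vi_minus_sd", "largest_only"),
                  threshold = c("noise", "interpolation", "both")) |>
    dplyr::rowwise() |>
    dplyr::mutate(flagged = any(call_significance(result, .data$mode,
                                                  .data$threshold))) |>
    dplyr::ungroup()
}

#' Export an importance result as CSV
#'
#' @param result An `importance_result`.
#' @param path Output path.
#' @export
write_importance <- function(result, path) {
  readr::write_csv(result$importance, path)
  invisible(path)
}
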