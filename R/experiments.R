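# Threshold-calibration experiments: empirical false-discovery rate under a
# null cohort generator, and power to detect a single outcome-linked
# interaction as its dispersal parameter moves away from the null value.

run_pipeline_rep <- function(config, seed, d, B, H, alpha_q, folds, n_trees,
                             feature_fraction, n_r) {
  sim <- simulate_cohort(config, seed = seed)
  analyze_cohort(sim$cells, sim$outcomes, sim$meta, n_r = n_r, d = d, B = B,
                 H = H, alpha_q = alpha_q, folds = folds, n_trees = n_trees,
                 feature_fraction = feature_fraction, seed = seed)
}

#' Empirical false-discovery-rate experiment
#'
#' Simulates `n_reps` independent null cohorts (every spatial interaction and
#' meta-variable independent of the outcome), runs the full pipeline on each,
#' and records — for each decision rule and threshold — the fraction of
#' replicates in which any variable was (falsely) called significant.
#'
#' @param config Null `sim_config` (default [sim_profile_4type()]).
#' @param n_reps Number of independent cohorts.
#' @param seed Master seed; each replicate derives its own child seed.
#' @inheritParams analyze_cohort
#' @return List with `rates` (tibble `mode`, `threshold`, `fdr`, `n_reps`) and
#'   `detail` (tibble `rep`, `mode`, `threshold`, `flagged`).
#' @export
run_fdr_experiment <- function(config = sim_profile_4type(), n_reps = 100,
                               seed = 1, d = 3, B = 100, H = 100,
                               alpha_q = 0.95, folds = 10, n_trees = 500,
                               feature_fraction = 0.8, n_r = 50) {
  seeds <- child_seeds(seed, n_reps)
  detail <- purrr::map_dfr(seq_len(n_reps), function(i) {
    res <- run_pipeline_rep(config, seeds[i], d, B, H, alpha_q, folds,
                            n_trees, feature_fraction, n_r)
    dplyr::mutate(significance_table(res), rep = i, .before = 1)
  })
  rates <- detail |>
    dplyr::group_by(.data$mode, .data$threshold) |>
    dplyr::summarise(fdr = mean(.data$flagged), n_reps = dplyr::n(),
                     .groups = "drop")
  list(rates = rates, detail = detail)
}

#' Power-curve experiment for one spatial interaction
#'
#' For each value of the positive-class dispersal parameter sigma of c2 around
#' c1, simulates `n_reps` relation cohorts and records how often the `c1_c2`
#' adjusted importance exceeds the noise threshold, the interpolation
#' threshold at its rank, and both. At the null sigma the "both" rate should
#' sit near the nominal level; away from it the rates climb towards 1.
#'
#' @param sigma_grid Positive-class sigma values for the c1-c2 interaction
#'   (the null dispersal is 0.025).
#' @param n_reps Replicates per sigma.
#' @param profile `"4type"` or `"16type"`.
#' @param target Interaction monitored (default `"c1_c2"`).
#' @inheritParams run_fdr_experiment
#' @return List with `rates` (tibble `sigma`, `threshold`, `rate`, `n_reps`)
#'   and `detail` (tibble `sigma`, `rep`, `threshold`, `detected`).
#' @export
run_power_experiment <- function(sigma_grid = c(0.01, 0.015, 0.02, 0.025,
                                                0.03, 0.04, 0.05),
                                 n_reps = 100, profile = c("4type", "16type"),
                                 target = "c1_c2", seed = 1, d = 3, B = 100,
                                 H = 100, alpha_q = 0.95, folds = 10,
                                 n_trees = 500, feature_fraction = 0.8,
                                 n_r = 50) {
  profile <- match.arg(profile)
  make_config <- function(sg) {
    cfg <- if (profile == "4type") sim_profile_4type(relation = TRUE,
                                                     sigma_c2_positive = sg)
    else sim_profile_16type(relation = TRUE, sigma_c2_positive = sg)
    # isolate the c1-c2 effect: no age shift, no c3 repulsion, no label noise
    cfg$age_mean_positive <- cfg$age_mean_negative
    cfg$n_noise_positive <- 0
    cfg$types$relation[cfg$types$name == "c3"] <- "none"
    cfg
  }
  detail <- purrr::map_dfr(sigma_grid, function(sg) {
    config <- make_config(sg)
    seeds <- child_seeds(seed + round(1e6 * sg), n_reps)
    purrr::map_dfr(seq_len(n_reps), function(i) {
      res <- run_pipeline_rep(config, seeds[i], d, B, H, alpha_q, folds,
                              n_trees, feature_fraction, n_r)
      imp <- res$importance[res$importance$variable == target, ]
      tibble::tibble(sigma = sg, rep = i,
                     threshold = c("noise", "interpolation", "both"),
                     detected = c(imp$vi_adj > imp$q_noise,
                                  imp$vi_adj > imp$q_int_at_rank,
                                  imp$vi_adj > imp$q_noise &
                                    imp$vi_adj > imp$q_int_at_rank))
    })
  })
  rates <- detail |>
    dplyr::group_by(.data$sigma, .data$threshold) |>
    dplyr::summarise(rate = mean(.data$detected), n_reps = dplyr::n(),
                     .groups = "drop")
  list(rates = rates, detail = detail)
}
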