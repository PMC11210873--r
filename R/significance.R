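# Synthetic-variable calibration of random-forest variable importance.
#
# Significance of a spatial interaction or meta-variable is judged against two
# permutation references fit with the same forest:
#  * Q_noise — the alpha_q quantile of the importances of "synthetic"
#    (patient-permuted, outcome-independent) copies of the variables, taken as
#    the max over the spatial quantile Q_C and the per-meta quantiles Q_{M,m};
#  * Q_int — the rank-wise alpha_q quantile of ordered adjusted importances
#    from H forests in which the true variables are permuted too, which
#    accounts for selection among many candidate variables.

# Empirical upper quantile as the inf{q : fraction <= q > alpha} order
# statistic: the floor(alpha * n) + 1 smallest value.
upper_quantile <- function(x, alpha = 0.95) {
  n <- length(x)
  if (n < 1 / (1 - alpha)) {
    warning("fewer than 1/(1 - alpha) values; quantile equals the maximum",
            call. = FALSE)
  }
  sort(x)[min(n, floor(alpha * n) + 1L)]
}

# Synthetic feature matrix: B patient-permuted copies of randomly chosen
# spatial d-blocks, then B permuted copies of each meta column. The RNG call
# sequence matches make_synthetics() exactly.
make_syn_matrix <- function(spatial, cols_of, meta, B, seed) {
  n <- nrow(spatial)
  S <- length(cols_of)
  d <- length(cols_of[[1]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_meta <- if (is.null(meta)) 0L else ncol(meta)
  X <- matrix(0, n, B * d + n_meta * B)
  srcs <- integer(B)
  for (b in seq_len(B)) {
    src <- sample.int(S, 1)
    srcs[b] <- src
    X[, (b - 1L) * d + seq_len(d)] <- spatial[sample.int(n), cols_of[[src]],
                                              drop = FALSE]
  }
  if (n_meta > 0) {
    for (mi in seq_len(n_meta)) {
      perms <- vapply(seq_len(B), function(b) sample.int(n), integer(n))
      X[, B * d + (mi - 1L) * B + seq_len(B)] <- meta[, mi][perms]
    }
  }
  attr(X, "sources") <- srcs
  X
}

#' Synthetic (knock-off) variables by patient permutation
#'
#' Builds B synthetic spatial variables — each a copy of a randomly chosen real
#' interaction's d-score block with its rows reassigned to patients by one
#' shared permutation, so the d components stay together — and B permuted
#' copies of every meta-variable. Synthetics share their source's marginal
#' distribution but are independent of the outcome by construction.
#'
#' @param spatial Numeric matrix of spatial PC scores (columns grouped per
#'   interaction).
#' @param spatial_groups Tibble (`column`, `variable`, `component`) mapping
#'   `spatial` columns to interactions.
#' @param meta Numeric matrix of meta-variables (or `NULL`).
#' @param B Number of synthetic copies (default 100).
#' @param seed Integer seed.
#' @return List with `features` (matrix) and `groups` (tibble `column`,
#'   `variable`, `kind`, `source`).
#' @export
make_synthetics <- function(spatial, spatial_groups, meta = NULL, B = 100,
                            seed = 1) {
  spatial <- as.matrix(spatial)
  vars <- unique(spatial_groups$variable)
  cols_of <- lapply(vars, function(v) {
    match(spatial_groups$column[spatial_groups$variable == v],
          colnames(spatial))
  })
  d <- lengths(cols_of)
  if (length(unique(d)) != 1) stop("spatial groups must share d", call. = FALSE)
  d <- d[[1]]
  X <- make_syn_matrix(spatial, cols_of, meta, B, seed)
  srcs <- vars[attr(X, "sources")]
  sp_var <- rep(paste0(".synC", seq_len(B)), each = d)
  cn <- paste0(sp_var, "_", rep(seq_len(d), B))
  groups <- tibble::tibble(column = cn, variable = sp_var,
                           kind = "synthetic-spatial",
                           source = rep(srcs, each = d))
  if (!is.null(meta) && ncol(meta) > 0) {
    for (m in colnames(meta)) {
      cnm <- paste0(".synM_", m, "_", seq_len(B))
      cn <- c(cn, cnm)
      groups <- dplyr::bind_rows(groups, tibble::tibble(
        column = cnm, variable = cnm, kind = "synthetic-meta", source = m))
    }
  }
  colnames(X) <- cn
  attr(X, "sources") <- NULL
  list(features = X, groups = groups)
}

#' Noise thresholds from synthetic importances
#'
#' @param syn_spatial_vi Numeric vector of the B synthetic spatial group
#'   importances.
#' @param syn_meta_vi Named list (per meta-variable) of B synthetic importance
#'   vectors; may be empty.
#' @param alpha_q Quantile level (default 0.95).
#' @return List with `Q_C`, `Q_M` (named vector), `Q_noise = max(Q_C, Q_M)`.
#' @export
noise_thresholds <- function(syn_spatial_vi, syn_meta_vi = list(),
                             alpha_q = 0.95) {
  Q_C <- upper_quantile(syn_spatial_vi, alpha_q)
  Q_M <- vapply(syn_meta_vi, upper_quantile, numeric(1), alpha = alpha_q)
  list(Q_C = Q_C, Q_M = Q_M, Q_noise = max(c(Q_C, Q_M)))
}

#' Calibrate importances across variable kinds
#'
#' Scales spatial importances by `Q_noise / Q_C` and each meta-variable by
#' `Q_noise / Q_{M,m}`, putting d-dimensional spatial interactions and scalar
#' meta-variables on a common scale. Standard deviations are scaled by the
#' same factor. A zero denominator (degenerate no-signal synthetics) yields
#' factor 1 with a warning.
#'
#' @param vi Named numeric vector of raw group importances.
#' @param kind Character vector (`"spatial"` or `"meta"`) aligned with `vi`.
#' @param thresholds List from [noise_thresholds()].
#' @return Numeric vector of adjusted values.
#' @export
adjust_importance <- function(vi, kind, thresholds) {
  factor <- numeric(length(vi))
  for (i in seq_along(vi)) {
    den <- if (kind[i] == "spatial") thresholds$Q_C else
      thresholds$Q_M[[names(vi)[i]]]
    if (is.null(den) || is.na(den) || den <= 0) {
      warning("zero synthetic quantile; adjustment factor set to 1", call. = FALSE)
      factor[i] <- 1
    } else {
      factor[i] <- thresholds$Q_noise / den
    }
  }
  vi * factor
}

# Stratified fold assignment at patient level (avoids single-class folds).
assign_folds <- function(y, folds, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  kappa <- integer(length(y))
  offset <- 0L
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    kappa[idx] <- ((seq_along(idx) - 1L + offset) %% folds) + 1L
    offset <- offset + length(idx)
  }
  kappa
}

# Forest fit + per-group importance through an integer group index (1..G);
# returns the raw C++ fit and the group importance vector.
fit_group_fast <- function(X, y_int, n_classes, gidx, n_trees, feature_fraction,
                           seed, rows = NULL) {
  if (!is.null(rows)) {
    fit <- rf_fit_cpp(X[rows, , drop = FALSE], y_int[rows], n_classes,
                      as.integer(n_trees), feature_fraction, TRUE,
                      as.numeric(seed))
  } else {
    fit <- rf_fit_cpp(X, y_int, n_classes, as.integer(n_trees),
                      feature_fraction, TRUE, as.numeric(seed))
  }
  vi <- numeric(max(gidx))
  agg <- rowsum(as.numeric(fit$importance), gidx, reorder = TRUE)
  vi[as.integer(rownames(agg))] <- agg[, 1]
  list(fit = fit, vi = vi)
}

#' Variable-importance significance analysis
#'
#' Runs the full calibration: a forest is fit to the true spatial PC scores and
#' meta-variables together with permutation synthetics; group importances are
#' averaged over F full-data refits, their spread estimated over F
#' cross-validation folds, calibrated by the synthetic quantiles, and compared
#' to the noise and interpolation thresholds. Held-out CV predictions give the
#' OOB accuracy alongside the GUESS and BIAS baselines.
#'
#' @param scores A `pc_scores` tibble from [pc_scores()] (or any tibble with a
#'   `patient_id` column, spatial score columns and a `spatial_groups`
#'   attribute/argument).
#' @param outcomes Tibble (`patient_id`, `outcome`) or a vector aligned with
#'   `scores$patient_id`.
#' @param meta Optional tibble: `patient_id` plus numeric meta-variable
#'   columns.
#' @param B Synthetic copies per kind (default 100).
#' @param H Permutation forests for the interpolation threshold (default 100).
#' @param alpha_q Quantile level of both thresholds (default 0.95; significance
#'   is at level 1 - alpha_q).
#' @param folds Cross-validation folds F (default 10), stratified by outcome.
#' @param n_trees,feature_fraction Forest configuration (defaults 500, 0.8).
#' @param seed Master seed; all child seeds derive from it deterministically.
#' @param spatial_groups Optional explicit group map when `scores` lacks the
#'   attribute.
#' @return An `importance_result` with elements `importance` (tibble),
#'   `thresholds`, `accuracy`, `predictions`, `config`.
#' @export
vi_significance <- function(scores, outcomes, meta = NULL, B = 100, H = 100,
                            alpha_q = 0.95, folds = 10, n_trees = 500,
                            feature_fraction = 0.8, seed = 1,
                            spatial_groups = NULL) {
  if (is.null(spatial_groups)) spatial_groups <- attr(scores, "spatial_groups")
  if (is.null(spatial_groups)) stop("spatial_groups must be supplied", call. = FALSE)
  patients <- scores$patient_id

  if (is.data.frame(outcomes)) {
    y <- outcomes$outcome[match(patients, outcomes$patient_id)]
  } else if (!is.null(names(outcomes))) {
    y <- outcomes[patients]
  } else y <- outcomes
  if (anyNA(y)) stop("missing outcome for some patients", call. = FALSE)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("outcome must have at least 2 classes", call. = FALSE)
  y_int <- as.integer(y) - 1L

  X_spatial <- as.matrix(scores[, spatial_groups$column, drop = FALSE])
  X_meta <- NULL
  if (!is.null(meta)) {
    meta_df <- meta[match(patients, meta$patient_id),
                    setdiff(names(meta), "patient_id"), drop = FALSE]
    if (ncol(meta_df) > 0) {
      X_meta <- as.matrix(meta_df)
      rownames(X_meta) <- NULL
    }
  }
  spatial_vars <- unique(spatial_groups$variable)
  meta_vars <- colnames(X_meta)
  S <- length(spatial_vars); M <- length(meta_vars)
  d <- nrow(spatial_groups) / S
  cols_of <- lapply(spatial_vars, function(v) {
    match(spatial_groups$column[spatial_groups$variable == v],
          colnames(X_spatial))
  })

  n_seed <- 2L + folds + folds + H
  seeds <- child_seeds(seed, n_seed)
  s_syn <- seeds[1]; s_fold <- seeds[2]
  s_cv <- seeds[2 + seq_len(folds)]
  s_refit <- seeds[2 + folds + seq_len(folds)]
  s_perm <- seeds[2 + 2 * folds + seq_len(H)]

  # column layout: true spatial | meta | B synthetic spatial | B per meta
  X_syn <- make_syn_matrix(X_spatial, cols_of, X_meta, B, s_syn)
  X_all <- cbind(X_spatial, X_meta, X_syn)
  # group ids: spatial 1..S, meta S+1..S+M, synC S+M+1..S+M+B, synM after
  gidx <- c(match(spatial_groups$variable, spatial_vars),
            if (M > 0) S + seq_len(M),
            rep(S + M + seq_len(B), each = d),
            if (M > 0) S + M + B + seq_len(M * B))
  G <- S + M + B + M * B
  id_true <- seq_len(S + M)
  id_synC <- S + M + seq_len(B)
  id_synM_of <- if (M > 0) lapply(seq_len(M), function(mi) {
    S + M + B + (mi - 1L) * B + seq_len(B)
  }) else list()
  true_vars <- c(spatial_vars, meta_vars)
  kinds <- c(rep("spatial", S), rep("meta", M))

  # --- cross-validation: fold-removed fits give SD(v) and held-out predictions
  kappa <- assign_folds(y, folds, s_fold)
  fold_vi <- matrix(NA_real_, G, folds)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (j in seq_len(folds)) {
    hold <- which(kappa == j)
    if (length(hold) == 0) next
    fg <- fit_group_fast(X_all, y_int, nlevels(y), gidx, n_trees,
                         feature_fraction, s_cv[j],
                         rows = setdiff(seq_along(y), hold))
    fold_vi[, j] <- fg$vi
    idx <- rf_predict_cpp(fg$fit, X_all[hold, , drop = FALSE])
    pred[hold] <- levels(y)[idx + 1L]
  }
  used <- !apply(is.na(fold_vi), 2, all)
  vi_cv <- rowMeans(fold_vi[, used, drop = FALSE])
  sd_cv <- apply(fold_vi[, used, drop = FALSE], 1, stats::sd)

  # --- point estimates: mean over F full-data refits (fresh forest seeds)
  refit_vi <- vapply(seq_len(folds), function(j) {
    fit_group_fast(X_all, y_int, nlevels(y), gidx, n_trees, feature_fraction,
                   s_refit[j])$vi
  }, numeric(G))
  vi_hat <- rowMeans(refit_vi)

  # --- noise thresholds from the synthetic groups
  syn_meta_vi <- if (M > 0) {
    setNames(lapply(seq_len(M), function(mi) vi_hat[id_synM_of[[mi]]]),
             meta_vars)
  } else list()
  thr <- noise_thresholds(vi_hat[id_synC], syn_meta_vi, alpha_q)

  # --- adjusted importances and SDs for the true variables
  vi_true <- setNames(vi_hat[id_true], true_vars)
  vi_adj <- adjust_importance(vi_true, kinds, thr)
  sd_true <- setNames(sd_cv[id_true], true_vars)
  sd_adj <- adjust_importance(sd_true, kinds, thr)

  # --- interpolation threshold
  Q_int <- interpolation_threshold(
    X_spatial, spatial_groups, X_meta, y, thr$Q_noise, B = B, H = H,
    alpha_q = alpha_q, n_trees = n_trees, feature_fraction = feature_fraction,
    seeds = s_perm)

  rk <- integer(length(vi_adj))
  rk[order(-vi_adj)] <- seq_along(vi_adj)
  q_int_at <- Q_int[rk]

  importance <- tibble::tibble(
    variable = true_vars,
    kind = kinds,
    vi = unname(vi_true),
    vi_cv = unname(vi_cv[id_true]),
    vi_adj = unname(vi_adj),
    sd = unname(sd_true),
    sd_adj = unname(sd_adj),
    rank = rk,
    q_noise = thr$Q_noise,
    q_int_at_rank = unname(q_int_at),
    significant_vi_only = vi_adj > thr$Q_noise & vi_adj > q_int_at,
    significant_vi_minus_sd = (vi_adj - sd_adj) > thr$Q_noise &
      (vi_adj - sd_adj) > q_int_at
  ) |> dplyr::arrange(.data$rank)

  acc <- tibble::tibble(
    oob = accuracy_oob(pred, y),
    guess = accuracy_guess(y),
    bias = accuracy_bias(y)
  )

  structure(list(
    importance = importance,
    thresholds = list(Q_C = thr$Q_C, Q_M = thr$Q_M, Q_noise = thr$Q_noise,
                      Q_int = Q_int, alpha_q = alpha_q, B = B, H = H),
    accuracy = acc,
    predictions = tibble::tibble(patient_id = patients, outcome = y,
                                 fold = kappa, predicted = pred),
    config = list(B = B, H = H, alpha_q = alpha_q, folds = folds,
                  n_trees = n_trees, feature_fraction = feature_fraction,
                  seed = seed)
  ), class = "importance_result")
}

#' Rank-wise interpolation threshold
#'
#' Fits H forests in which every true variable is patient-permuted (spatial
#' d-score blocks jointly, meta-variables singly) alongside fresh synthetics,
#' adjusts each forest's importances using the previously computed `Q_noise`
#' (with the forest's own synthetic quantiles in the denominator), orders
#' them, and returns the alpha_q quantile at every rank.
#'
#' @param spatial,spatial_groups,meta True features as in [make_synthetics()].
#' @param y Outcome factor.
#' @param Q_noise Noise threshold from the unpermuted analysis.
#' @param B,H,alpha_q,n_trees,feature_fraction As in [vi_significance()].
#' @param seeds Integer vector of H child seeds.
#' @return Numeric vector `Q_int` of length V (spatial variables + meta),
#'   non-increasing in rank.
#' @export
interpolation_threshold <- function(spatial, spatial_groups, meta, y, Q_noise,
                                    B = 100, H = 100, alpha_q = 0.95,
                                    n_trees = 500, feature_fraction = 0.8,
                                    seeds = NULL) {
  if (is.null(seeds)) seeds <- child_seeds(1, H)
  stopifnot(length(seeds) >= H)
  spatial <- as.matrix(spatial)
  y <- droplevels(as.factor(y))
  y_int <- as.integer(y) - 1L
  n <- nrow(spatial)
  spatial_vars <- unique(spatial_groups$variable)
  meta_vars <- colnames(meta)
  S <- length(spatial_vars); M <- length(meta_vars)
  cols_of <- lapply(spatial_vars, function(v) {
    match(spatial_groups$column[spatial_groups$variable == v],
          colnames(spatial))
  })
  col_var <- spatial_groups$variable[match(colnames(spatial),
                                           spatial_groups$column)]
  gidx <- c(match(col_var, spatial_vars),
            if (M > 0) S + seq_len(M),
            rep(S + M + seq_len(B), each = length(cols_of[[1]])),
            if (M > 0) S + M + B + seq_len(M * B))
  id_synC <- S + M + seq_len(B)
  id_synM_of <- if (M > 0) lapply(seq_len(M), function(mi) {
    S + M + B + (mi - 1L) * B + seq_len(B)
  }) else list()
  kinds <- c(rep("spatial", S), rep("meta", M))
  V <- S + M
  ord_mat <- matrix(NA_real_, H, V)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (h in seq_len(H)) {
    sh <- child_seeds(seeds[h], 3)
    set.seed(sh[1])
    Xs <- spatial
    for (ci in cols_of) Xs[, ci] <- spatial[sample.int(n), ci]
    Xm <- meta
    if (M > 0) for (mi in seq_len(M)) Xm[, mi] <- meta[sample.int(n), mi]

    X_syn <- make_syn_matrix(Xs, cols_of, Xm, B, sh[2])
    X_all <- cbind(Xs, Xm, X_syn)
    fg <- fit_group_fast(X_all, y_int, nlevels(y), gidx, n_trees,
                         feature_fraction, sh[3])
    vi <- fg$vi
    syn_meta_vi <- if (M > 0) {
      setNames(lapply(seq_len(M), function(mi) vi[id_synM_of[[mi]]]),
               meta_vars)
    } else list()
    thr_h <- noise_thresholds(vi[id_synC], syn_meta_vi, alpha_q)
    thr_h$Q_noise <- Q_noise   # align with the original noise scale
    vi_true <- setNames(vi[seq_len(V)], c(spatial_vars, meta_vars))
    ord_mat[h, ] <- sort(adjust_importance(vi_true, kinds, thr_h),
                         decreasing = TRUE)
  }
  apply(ord_mat, 2, upper_quantile, alpha = alpha_q)
}

#' Significance calls for an importance result
#'
#' A variable is significant when its statistic exceeds both the noise
#' threshold and the interpolation threshold at its rank. `mode` selects the
#' statistic: the adjusted importance (`"vi_only"`), the importance lowered by
#' one adjusted CV standard deviation (`"vi_minus_sd"`), or the adjusted
#' importance with only the top-ranked variable eligible (`"largest_only"`).
#'
#' @param result An `importance_result` from [vi_significance()].
#' @param mode One of `"vi_only"`, `"vi_minus_sd"`, `"largest_only"`.
#' @param threshold Which threshold(s) must be exceeded: `"both"` (default),
#'   `"noise"`, or `"interpolation"`.
#' @return Logical vector aligned with `result$importance$variable`.
#' @export
call_significance <- function(result,
                              mode = c("vi_only", "vi_minus_sd", "largest_only"),
                              threshold = c("both", "noise", "interpolation")) {
  mode <- match.arg(mode)
  threshold <- match.arg(threshold)
  imp <- result$importance
  stat <- if (mode == "vi_minus_sd") imp$vi_adj - imp$sd_adj else imp$vi_adj
  over_noise <- stat > imp$q_noise
  over_int <- stat > imp$q_int_at_rank
  flag <- switch(threshold,
                 noise = over_noise,
                 interpolation = over_int,
                 both = over_noise & over_int)
  if (mode == "largest_only") flag <- flag & imp$rank == 1L
  flag
}

#' @export
print.importance_result <- function(x, ...) {
  cat("Variable importance significance analysis\n")
  cat(sprintf("  %d variables, Q_noise = %.4g, alpha_q = %.2f\n",
              nrow(x$importance), x$thresholds$Q_noise, x$thresholds$alpha_q))
  cat(sprintf("  OOB = %.3f  GUESS = %.3f  BIAS = %.3f\n",
              x$accuracy$oob, x$accuracy$guess, x$accuracy$bias))
  sig <- x$importance$variable[x$importance$significant_vi_minus_sd]
  cat("  significant (VI - 1 SD > both thresholds): ",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n", sep = "")
  invisible(x)
}
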