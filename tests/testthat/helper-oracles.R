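# Independent reference implementations used as oracles, plus tiny fixtures.

# O(n^2) double-loop cross-K reference, mirroring the estimator definition
# directly: |i|/(n_t n_t') sum_c sum_c' w_cc' 1(d_cc' <= r).
brute_cross_k <- function(xt, yt, xp, yp, grid, window,
                          correction = "none", self = FALSE) {
  n_t <- length(xt); n_p <- length(xp)
  denom <- if (self) n_t * (n_t - 1) else n_t * n_p
  out <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    r <- grid[gi]
    acc <- 0
    for (a in seq_len(n_t)) {
      for (b in seq_len(n_p)) {
        if (self && a == b) next
        d <- sqrt((xt[a] - xp[b])^2 + (yt[a] - yp[b])^2)
        if (d <= r) {
          w <- 1
          if (correction == "isotropic" && d > 0) {
            # fraction of the circle of radius d centred at (xt[a], yt[a])
            # inside the window, by fine angular quadrature
            th <- seq(0, 2 * pi, length.out = 20001)[-1]
            px <- xt[a] + d * cos(th); py <- yt[a] + d * sin(th)
            inside <- mean(px >= window$x_min & px <= window$x_max &
                             py >= window$y_min & py <= window$y_max)
            w <- 1 / inside
          }
          acc <- acc + w
        }
      }
    }
    out[gi] <- window$area / denom * acc
  }
  out
}

# Exhaustive best Gini split over all (feature, midpoint-threshold) pairs.
# Returns the maximal impurity reduction dI (p(.) = count/n) and all
# argmax (feature, threshold) pairs.
brute_best_split <- function(X, y) {
  n <- nrow(X)
  y <- as.integer(as.factor(y))
  gini_part <- function(yy) {
    if (length(yy) == 0) return(0)
    p <- tabulate(yy, max(y)) / length(yy)
    (length(yy) / n) * sum(p * (1 - p))
  }
  base <- gini_part(y)
  best <- -Inf; arg <- list()
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2) next
    for (k in seq_len(length(v) - 1)) {
      thr <- (v[k] + v[k + 1]) / 2
      l <- X[, j] <= thr
      dI <- base - gini_part(y[l]) - gini_part(y[!l])
      if (dI > best + 1e-12) {
        best <- dI; arg <- list(c(j, thr))
      } else if (abs(dI - best) <= 1e-12) {
        arg <- c(arg, list(c(j, thr)))
      }
    }
  }
  list(gain = best, argmax = arg)
}

# Small deterministic cell table on the unit square: two phenotypes laid out
# on a grid, one patient, one image.
toy_cells <- function() {
  as_cell_table(tibble::tibble(
    patient_id = "p1", image_id = "i1",
    x = c(0.3, 0.7, 0.3, 0.7), y = c(0.5, 0.5, 0.6, 0.6),
    phenotype = c("A", "A", "B", "B")))
}

# Cohort of pure-noise PC-score-like data for forest/significance tests.
toy_scores <- function(n = 20, S = 4, d = 3, seed = 1) {
  set.seed(seed)
  vars <- paste0("v", seq_len(S))
  cols <- paste0(rep(vars, each = d), "_PC", rep(seq_len(d), S))
  X <- matrix(rnorm(n * S * d), n, S * d, dimnames = list(NULL, cols))
  sc <- tibble::as_tibble(X)
  sc$patient_id <- sprintf("P%02d", seq_len(n))
  sc <- sc[, c("patient_id", cols)]
  attr(sc, "spatial_groups") <- tibble::tibble(
    column = cols, variable = rep(vars, each = d),
    component = rep(seq_len(d), S))
  sc
}
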