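test_that("upper quantile matches direct order-statistic enumeration", {
  # B = 100 values 0.01..1.00 at level 0.95: the 96th order statistic, 0.96
  x <- seq(0.01, 1, by = 0.01)
  expect_equal(upper_quantile(sample(x), 0.95), 0.96)
  # enumeration oracle: smallest q with fraction <= q strictly above alpha
  enum <- function(x, a) {
    s <- sort(x)
    s[which(vapply(s, function(q) mean(x <= q) > a, logical(1)))[1]]
  }
  set.seed(1)
  for (B in c(7, 20, 100)) {
    z <- rnorm(B)
    for (a in c(0.8, 0.9, 0.95)) {
      expect_equal(suppressWarnings(upper_quantile(z, a)), enum(z, a))
    }
  }
  expect_equal(upper_quantile(rep(0, 50), 0.95), 0)
  expect_warning(upper_quantile(rnorm(10), 0.95), "maximum")
})

test_that("noise threshold is the max over spatial and meta quantiles", {
  thr <- noise_thresholds(c(rep(0, 95), rep(0.2, 5)),
                          list(m1 = rep(0.1, 100), m2 = rep(0.3, 100)))
  expect_equal(thr$Q_C, 0.2)
  expect_equal(unname(thr$Q_M), c(0.1, 0.3))
  expect_equal(thr$Q_noise, 0.3)
})

test_that("synthetic variables are joint permutations of real blocks", {
  sc <- toy_scores(n = 12, S = 3, d = 3, seed = 2)
  gr <- attr(sc, "spatial_groups")
  Xsp <- as.matrix(sc[, gr$column])
  meta <- cbind(age = rnorm(12))
  syn <- make_synthetics(Xsp, gr, meta, B = 8, seed = 5)
  expect_equal(ncol(syn$features), 8 * 3 + 8)
  for (b in 1:8) {
    blk <- syn$features[, (b - 1) * 3 + 1:3]
    src <- syn$groups$source[(b - 1) * 3 + 1]
    src_blk <- Xsp[, gr$column[gr$variable == src]]
    # same multiset of rows: each synthetic patient's d components come
    # jointly from a single source patient
    expect_equal(blk[order(blk[, 1]), ], src_blk[order(src_blk[, 1]), ],
                 ignore_attr = TRUE)
  }
  # each synthetic meta column is a permutation of the meta-variable
  for (j in 1:8) {
    expect_equal(sort(syn$features[, 24 + j]), sort(meta[, 1]),
                 ignore_attr = TRUE)
  }
  # B = 1 with 2 patients: identical to source or rows swapped
  sc2 <- toy_scores(n = 2, S = 2, d = 2, seed = 3)
  gr2 <- attr(sc2, "spatial_groups")
  X2 <- as.matrix(sc2[, gr2$column])
  s2 <- make_synthetics(X2, gr2, B = 1, seed = 1)
  src <- s2$groups$source[1]
  sb <- X2[, gr2$column[gr2$variable == src]]
  same <- isTRUE(all.equal(unname(s2$features), unname(sb)))
  swapped <- isTRUE(all.equal(unname(s2$features), unname(sb[2:1, ])))
  expect_true(same || swapped)
})

test_that("adjustment rescales by kind and preserves within-kind order", {
  thr <- list(Q_C = 0.2, Q_M = c(m = 0.4), Q_noise = 0.4)
  vi <- c(s1 = 0.5, s2 = 0.1, m = 0.3)
  adj <- adjust_importance(vi, c("spatial", "spatial", "meta"), thr)
  expect_equal(unname(adj), c(0.5 * 2, 0.1 * 2, 0.3))
  expect_equal(order(adj[1:2]), order(vi[1:2]))
  # Q_C = Q_noise: identity for spatial
  thr2 <- list(Q_C = 0.4, Q_M = c(m = 0.4), Q_noise = 0.4)
  expect_equal(unname(adjust_importance(vi, c("spatial", "spatial", "meta"),
                                        thr2)), unname(vi))
  # zero denominator: factor 1 with warning
  thr3 <- list(Q_C = 0, Q_M = c(m = 0.4), Q_noise = 0.4)
  expect_warning(a3 <- adjust_importance(vi[1], "spatial", thr3), "zero")
  expect_equal(unname(a3), 0.5)
})

test_that("significance analysis returns coherent structure on noise data", {
  sc <- toy_scores(n = 20, S = 4, d = 3, seed = 4)
  out <- tibble::tibble(patient_id = sc$patient_id,
                        outcome = factor(rep(c("neg", "pos"), 10)))
  meta <- tibble::tibble(patient_id = sc$patient_id, age = rnorm(20))
  res <- suppressWarnings(
    vi_significance(sc, out, meta, B = 25, H = 15, folds = 5,
                    n_trees = 60, seed = 42))
  imp <- res$importance
  expect_setequal(imp$variable, c(paste0("v", 1:4), "age"))
  expect_equal(sort(imp$rank), 1:5)
  # rank order matches adjusted importance order
  expect_equal(imp$rank[order(-imp$vi_adj)], 1:5)
  # interpolation threshold is rank-wise non-increasing
  expect_true(all(diff(res$thresholds$Q_int) <= 1e-12))
  expect_equal(res$thresholds$Q_noise,
               max(res$thresholds$Q_C, res$thresholds$Q_M))
  expect_true(all(imp$vi_adj >= 0) && all(imp$sd_adj >= 0))
  # every patient held out exactly once, in a stratified fold
  expect_equal(sort(unique(res$predictions$fold)), 1:5)
  expect_false(anyNA(res$predictions$predicted))
  per_fold <- table(res$predictions$fold, res$predictions$outcome)
  expect_true(all(per_fold >= 1))
  # master seed reproduces the analysis exactly
  res2 <- suppressWarnings(
    vi_significance(sc, out, meta, B = 25, H = 15, folds = 5,
                    n_trees = 60, seed = 42))
  expect_equal(res$importance, res2$importance)
  expect_equal(res$thresholds$Q_int, res2$thresholds$Q_int)
})

test_that("decision rules implement the threshold logic", {
  imp <- tibble::tibble(
    variable = c("a", "b", "c"),
    kind = "spatial",
    vi = c(0.5, 0.3, 0.1), vi_cv = vi, vi_adj = c(0.5, 0.3, 0.1),
    sd = c(0.05, 0.25, 0.01), sd_adj = c(0.05, 0.25, 0.01),
    rank = 1:3, q_noise = 0.2,
    q_int_at_rank = c(0.4, 0.35, 0.05),
    significant_vi_only = NA, significant_vi_minus_sd = NA)
  res <- structure(list(importance = imp), class = "importance_result")
  # vi_only: a exceeds both; b fails interpolation; c fails noise
  expect_equal(call_significance(res, "vi_only", "both"), c(TRUE, FALSE, FALSE))
  expect_equal(call_significance(res, "vi_only", "noise"), c(TRUE, TRUE, FALSE))
  expect_equal(call_significance(res, "vi_only", "interpolation"),
               c(TRUE, FALSE, TRUE))
  # lowering by one SD knocks out a variable with a wide interval
  expect_equal(call_significance(res, "vi_minus_sd", "both"),
               c(TRUE, FALSE, FALSE))
  expect_equal(call_significance(res, "vi_minus_sd", "noise"),
               c(TRUE, FALSE, FALSE))
  # only the top-ranked variable is eligible in largest_only
  imp2 <- imp; imp2$q_int_at_rank <- c(0.6, 0.25, 0.05)
  res2 <- structure(list(importance = imp2), class = "importance_result")
  expect_equal(call_significance(res2, "largest_only", "both"),
               c(FALSE, FALSE, FALSE))
  expect_equal(call_significance(res2, "largest_only", "noise"),
               c(TRUE, FALSE, FALSE))
})

test_that("interpolation threshold with H = 1 equals that run's ordered VIs", {
  sc <- toy_scores(n = 16, S = 3, d = 2, seed = 6)
  gr <- attr(sc, "spatial_groups")
  Xsp <- as.matrix(sc[, gr$column])
  y <- factor(rep(c("a", "b"), 8))
  qi <- suppressWarnings(interpolation_threshold(
    Xsp, gr, NULL, y, Q_noise = 0.1, B = 10, H = 1, n_trees = 40,
    seeds = 123))
  expect_equal(length(qi), 3)
  expect_true(all(diff(qi) <= 1e-12))
})
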