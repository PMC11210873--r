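test_that("a perfectly separating stump reproduces hand-computed Gini gain", {
  # 17/17 cohort split perfectly by one binary feature:
  # I(root) = 2 * 0.5 * 0.5 = 0.5, dI = 0.5 - 0 - 0 = 0.5
  X <- matrix(rep(c(0, 1), each = 17), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- factor(rep(c("a", "b"), each = 17))
  fit <- fit_forest(X, y, n_trees = 1, feature_fraction = 1,
                    bootstrap = FALSE, seed = 1)
  expect_equal(unname(column_importance(fit)), 0.5)
  expect_equal(as.character(predict(fit, X)), as.character(y))
})

test_that("constant columns never gain importance", {
  set.seed(2)
  X <- cbind(const = 1, sig = rnorm(20))
  y <- factor(rep(c("a", "b"), 10))
  fit <- fit_forest(X, y, n_trees = 50, seed = 2)
  expect_equal(unname(column_importance(fit)["const"]), 0)
})

test_that("single unrestricted tree matches exhaustive split search", {
  set.seed(3)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    y <- factor(sample(c("a", "b"), n, replace = TRUE))
    if (nlevels(droplevels(y)) < 2) y <- factor(rep(c("a", "b"), length.out = n))
    ref <- brute_best_split(X, y)
    fit <- fit_forest(X, y, n_trees = 1, feature_fraction = 1,
                      bootstrap = FALSE, seed = rep)
    root_f <- fit$fit$node_feature[1] + 1L
    root_t <- fit$fit$node_threshold[1]
    if (ref$gain <= 1e-12) {
      expect_equal(root_f, 0L)  # no split improves impurity
    } else {
      hit <- any(vapply(ref$argmax, function(a) {
        a[1] == root_f && abs(a[2] - root_t) < 1e-12
      }, logical(1)))
      expect_true(hit)
      # dI of the root split agrees with the exhaustive maximum
      l <- X[, root_f] <= root_t
      gini <- function(yy) {
        p <- table(yy) / length(yy); (length(yy) / n) * sum(p * (1 - p))
      }
      dI <- gini(y) - gini(y[l]) - gini(y[!l])
      expect_equal(dI, ref$gain, tolerance = 1e-12)
    }
  }
})

test_that("root split agrees with an independent CART implementation", {
  # rpart grows the same Gini tree; on data with a unique optimal split the
  # root (feature, threshold) must coincide
  set.seed(13)
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- factor(ifelse(X[, 2] + 0.2 * rnorm(40) > 0, "a", "b"))
  fit <- fit_forest(X, y, n_trees = 1, feature_fraction = 1,
                    bootstrap = FALSE, seed = 1)
  rp <- rpart::rpart(y ~ ., data = data.frame(X, y = y),
                     method = "class",
                     control = rpart::rpart.control(minsplit = 2, cp = 0,
                                                    maxdepth = 1, xval = 0))
  rp_var <- as.character(rp$frame$var[1])
  rp_thr <- rp$splits[1, "index"]
  expect_equal(colnames(X)[fit$fit$node_feature[1] + 1], rp_var)
  expect_equal(fit$fit$node_threshold[1], rp_thr, tolerance = 1e-10)
})

test_that("column importances sum to the audited total impurity reduction", {
  # audit on a bootstrap-free tree where the training multiset is known:
  # walk the tree, recompute every split's dI from the rows reaching it
  set.seed(4)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- factor(sample(c("a", "b"), 30, replace = TRUE))
  fit2 <- fit_forest(X, y, n_trees = 1, feature_fraction = 1,
                     bootstrap = FALSE, seed = 9)
  f2 <- fit2$fit
  gini <- function(idx) {
    p <- table(y[idx]) / length(idx)
    (length(idx) / 30) * sum(p * (1 - p))
  }
  audit <- 0
  walk <- function(node, idx) {
    if (f2$node_pred[node + 1] >= 0) return(invisible())
    j <- f2$node_feature[node + 1] + 1
    thr <- f2$node_threshold[node + 1]
    l <- idx[X[idx, j] <= thr]; r <- idx[X[idx, j] > thr]
    audit <<- audit + gini(idx) - gini(l) - gini(r)
    walk(f2$node_left[node + 1], l)
    walk(f2$node_right[node + 1], r)
  }
  walk(0, seq_len(30))
  expect_equal(sum(column_importance(fit2)), audit, tolerance = 1e-12)
})

test_that("identical seed and data give bit-identical forests", {
  set.seed(5)
  X <- matrix(rnorm(25 * 10), 25, 10)
  y <- factor(sample(c("a", "b"), 25, replace = TRUE))
  f1 <- fit_forest(X, y, n_trees = 30, seed = 77)
  f2 <- fit_forest(X, y, n_trees = 30, seed = 77)
  expect_identical(f1$fit$importance, f2$fit$importance)
  expect_identical(f1$fit$node_threshold, f2$fit$node_threshold)
  f3 <- fit_forest(X, y, n_trees = 30, seed = 78)
  expect_false(identical(f1$fit$importance, f3$fit$importance))
})

test_that("prediction ties break to the lowest class label", {
  # all-constant features: every tree is a leaf voting the majority class;
  # with a 10/10 cohort the leaf itself ties and must pick the lowest label
  X <- matrix(1, 20, 2)
  y <- factor(rep(c("b", "a"), each = 10), levels = c("a", "b"))
  fit <- fit_forest(X, y, n_trees = 11, seed = 6)
  expect_true(all(predict(fit, X) == "a"))
})

test_that("degenerate inputs raise contract errors", {
  X <- matrix(rnorm(10), 5, 2)
  expect_error(fit_forest(X, factor(rep("a", 5))), "single class")
  expect_error(fit_forest(cbind(X, NA), factor(rep(c("a", "b"), c(2, 3)))),
               "missing")
  fit <- fit_forest(X, factor(c("a", "a", "b", "b", "a")), n_trees = 5)
  expect_error(predict(fit, X[, 1, drop = FALSE]), "mismatch|columns")
})

test_that("group importance sums component columns and passes meta through", {
  ci <- c(a_PC1 = 0.2, a_PC2 = 0.1, a_PC3 = 0, meta1 = 0.4)
  groups <- tibble::tibble(column = names(ci),
                           variable = c("a", "a", "a", "meta1"))
  gi <- group_importance(ci, groups)
  expect_equal(gi, c(a = 0.3, meta1 = 0.4))
  expect_error(group_importance(c(ci, other = 1), groups), "cover")
})

test_that("null-data group importances are exchangeable with synthetics", {
  # rank-sum comparison pooled over seeds; features independent of outcome
  set.seed(11)
  pool_true <- c(); pool_syn <- c()
  for (s in 1:12) {
    sc <- toy_scores(n = 20, S = 3, d = 2, seed = s)
    gr <- attr(sc, "spatial_groups")
    Xsp <- as.matrix(sc[, gr$column])
    syn <- make_synthetics(Xsp, gr, B = 3, seed = s + 100)
    y <- factor(rep(c("a", "b"), 10))
    X <- cbind(Xsp, syn$features)
    fit <- fit_forest(X, y, n_trees = 60, seed = s)
    gi <- group_importance(column_importance(fit),
                           dplyr::bind_rows(gr[, c("column", "variable")],
                                            syn$groups[, c("column", "variable")]))
    pool_true <- c(pool_true, gi[unique(gr$variable)])
    pool_syn <- c(pool_syn, gi[unique(syn$groups$variable)])
  }
  expect_gt(wilcox.test(pool_true, pool_syn)$p.value, 0.01)
})
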