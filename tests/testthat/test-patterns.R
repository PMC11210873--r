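test_that("read_cells parses, maps columns, and validates windows", {
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    patient = c("p1", "p1", "p1"), image = "i1",
    xx = c(0.1, 0.5, 0.9), yy = c(0.2, 0.5, 0.8),
    type = c("A", "B", "A")), f)
  cells <- read_cells(f, column_map = c(patient_id = "patient",
                                        image_id = "image", x = "xx",
                                        y = "yy", phenotype = "type"))
  expect_s3_class(cells, "cell_table")
  expect_equal(nrow(cells), 3)
  expect_equal(length(unique(cells$patient_id)), 1)
  expect_equal(attr(cells, "phenotypes"), c("A", "B"))

  # missing column is a configuration error
  expect_error(read_cells(f), "lacks mapped column")

  # a cell outside the declared unit-square window is a validation error
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    patient_id = "p1", image_id = "i1", x = c(0.2, 1.2), y = 0.5,
    phenotype = "A"), f2)
  expect_error(read_cells(f2), "outside declared window")
})

test_that("cell table invariants: image-to-patient map and phenotype set", {
  bad <- tibble::tibble(patient_id = c("p1", "p2"), image_id = "i1",
                        x = 0.5, y = 0.5, phenotype = "A")
  expect_error(as_cell_table(bad), "more than one patient")
  expect_error(
    as_cell_table(tibble::tibble(patient_id = "p1", image_id = "i1",
                                 x = 0.5, y = 0.5, phenotype = "A"),
                  phenotypes = c("B", "C")),
    "outside declared set")
})

test_that("uncorrected cross K matches hand-computed pair counts", {
  cells <- toy_cells()
  grid <- c(0, 0.15)
  k <- estimate_cross_k(cells, "A", "B", grid, correction = "none")
  # only the two vertical pairs at distance 0.10 qualify: 1/(2*2) * 2 = 0.5
  expect_equal(k$value[k$r == 0.15], 0.5)
  # no pairs at zero distance for distinct types
  expect_equal(k$value[k$r == 0], 0)
})

test_that("cross K equals the O(n^2) double-loop reference", {
  set.seed(42)
  win <- spatial_window()
  grid <- radius_grid(0.25, n_r = 8)
  for (rep in 1:3) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    xt <- runif(n1); yt <- runif(n1); xp <- runif(n2); yp <- runif(n2)
    cells <- as_cell_table(tibble::tibble(
      patient_id = "p", image_id = "i",
      x = c(xt, xp), y = c(yt, yp),
      phenotype = rep(c("A", "B"), c(n1, n2))))
    for (corr in c("none", "isotropic")) {
      k <- estimate_cross_k(cells, "A", "B", grid, correction = corr)
      ref <- brute_cross_k(xt, yt, xp, yp, grid, win, correction = corr)
      tol <- if (corr == "none") 1e-12 else 5e-4  # oracle uses angular quadrature
      expect_equal(k$value, ref, tolerance = tol)
    }
    # self-interaction excludes the c = c' pair
    ks <- estimate_cross_k(cells, "A", "A", grid, correction = "none")
    refs <- brute_cross_k(xt, yt, xt, yt, grid, win, correction = "none",
                          self = TRUE)
    expect_equal(ks$value, refs, tolerance = 1e-12)
  }
})

test_that("uncorrected K is monotone and obeys the pair-count symmetry", {
  set.seed(7)
  cells <- as_cell_table(tibble::tibble(
    patient_id = "p", image_id = "i", x = runif(30), y = runif(30),
    phenotype = rep(c("A", "B"), c(10, 20))))
  grid <- radius_grid(0.25, 20)
  kab <- estimate_cross_k(cells, "A", "B", grid, correction = "none")
  kba <- estimate_cross_k(cells, "B", "A", grid, correction = "none")
  expect_true(all(diff(kab$value) >= 0))
  # pair counts are symmetric, so the standard estimator satisfies
  # K_AB = K_BA, and the literal one n_B K^lit_AB = n_A K^lit_BA = |i| C
  expect_equal(kab$value, kba$value, tolerance = 1e-12)
  lab <- estimate_cross_k(cells, "A", "B", grid, correction = "none",
                          normalization = "literal")
  lba <- estimate_cross_k(cells, "B", "A", grid, correction = "none",
                          normalization = "literal")
  expect_equal(20 * lab$value, 10 * lba$value, tolerance = 1e-12)
})

test_that("literal normalization scales the standard estimator by n_t", {
  cells <- toy_cells()
  grid <- c(0, 0.15)
  std <- estimate_cross_k(cells, "A", "B", grid, correction = "none")
  lit <- estimate_cross_k(cells, "A", "B", grid, correction = "none",
                          normalization = "literal")
  expect_equal(lit$value, 2 * std$value)
})

test_that("undefined interactions are flagged, not errors", {
  cells <- toy_cells()
  k <- estimate_cross_k(cells, "A", "C", c(0, 0.1))
  expect_false(k$defined[1])
  expect_true(all(is.na(k$value)))
})

test_that("image averaging follows the count-weighted mean", {
  grid <- c(0, 0.1)
  mk <- function(val, n_t, defined = TRUE) {
    tibble::tibble(r = grid, value = if (defined) c(0, val) else NA_real_,
                   defined = defined, n_t = n_t)
  }
  # single image: identity
  expect_equal(average_k_over_images(list(mk(4, 3)))$value, c(0, 4))
  # counts 3 and 1, values 4 and 8: 0.75*4 + 0.25*8 = 5
  avg <- average_k_over_images(list(mk(4, 3), mk(8, 1)))
  expect_equal(avg$value, c(0, 5))
  # an image where the pair is undefined contributes weight 0
  avg2 <- average_k_over_images(list(mk(4, 3), mk(8, 1, defined = FALSE)))
  expect_equal(avg2$value, c(0, 4))
  # no image defines the pair: flagged undefined
  expect_false(average_k_over_images(list(mk(4, 3, FALSE)))$defined[1])
})

test_that("cohort_k yields T^2 curves per patient and multi-image averages", {
  set.seed(3)
  two_img <- tibble::tibble(
    patient_id = "p1",
    image_id = rep(c("i1", "i2"), c(30, 20)),
    x = runif(50), y = runif(50),
    phenotype = sample(c("A", "B", "C", "D"), 50, replace = TRUE))
  cells <- as_cell_table(two_img)
  kset <- cohort_k(cells, r_max = 0.2, n_r = 5, correction = "none")
  expect_equal(length(unique(kset$pair)), 16)  # T = 4
  # patient curve equals the weighted average of per-image estimates
  grid <- attr(kset, "grid")
  for (pr in c("A_B", "B_A")) {
    per_img <- lapply(c("i1", "i2"), function(im) {
      estimate_cross_k(cells[cells$image_id == im, ],
                       strsplit(pr, "_")[[1]][1], strsplit(pr, "_")[[1]][2],
                       grid, window = spatial_window(), correction = "none")
    })
    expect_equal(kset$value[kset$pair == pr],
                 average_k_over_images(per_img)$value, tolerance = 1e-12)
  }
})

test_that("K set round-trips through long CSV", {
  cells <- toy_cells()
  kset <- cohort_k(cells, r_max = 0.2, n_r = 4, correction = "none")
  f <- withr::local_tempfile(fileext = ".csv")
  write_k_set(kset, f)
  back <- read_k_set(f)
  expect_equal(back$value, kset$value)
  expect_equal(attr(back, "grid"), attr(kset, "grid"))
})

test_that("mean isotropic-corrected K under CSR is close to pi r^2", {
  # moderate-size calibration here; the acceptance suite runs the full one
  set.seed(123)
  grid <- radius_grid(0.25, 6)[-1]
  ks <- replicate(60, {
    n1 <- rpois(1, 100); n2 <- rpois(1, 100)
    cells <- as_cell_table(tibble::tibble(
      patient_id = "p", image_id = "i",
      x = runif(n1 + n2), y = runif(n1 + n2),
      phenotype = rep(c("A", "B"), c(n1, n2))))
    estimate_cross_k(cells, "A", "B", c(0, grid))$value[-1]
  })
  mc_se <- apply(ks, 1, sd) / sqrt(ncol(ks))
  expect_true(all(abs(rowMeans(ks) - pi * grid^2) < 3.5 * mc_se))
})
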