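# Functional PCA of K-function cohorts.
#
# Integrals over the radius grid use trapezoidal quadrature throughout. The
# empirical covariance kernel is eigendecomposed through the symmetrized
# matrix D C D (D = diag(sqrt(w))), whose eigenvectors u give orthonormal
# eigenfunctions phi = u / sqrt(w) under the quadrature inner product.

trapezoid_weights <- function(grid) {
  m <- length(grid)
  h <- diff(grid)
  w <- numeric(m)
  w[1] <- h[1] / 2
  w[m] <- h[m - 1] / 2
  if (m > 2) w[2:(m - 1)] <- (h[-1] + h[-(m - 1)]) / 2
  w
}

#' Functional principal components of one interaction's K curves
#'
#' Computes the empirical covariance kernel of the cohort's K curves (divisor
#' N over contributing curves), its quadrature-weighted eigendecomposition, and
#' per-patient scores: projections \eqn{\int K^{(p)}(r) \phi_i(r) dr} of the
#' (by default uncentered) curves onto the leading eigenfunctions.
#'
#' @param curves Numeric matrix, one row per patient, columns on `grid`; or a
#'   `k_set` filtered to a single pair (undefined patients are excluded from
#'   the decomposition).
#' @param grid Radius grid (required when `curves` is a matrix).
#' @param d Number of components to retain.
#' @param center Project centered curves instead of raw curves. The default
#'   `FALSE` projects raw curves; the two differ per component by a constant
#'   shared across patients, so downstream forest splits are unchanged.
#' @return List with `eigenvalues` (clipped at 0, descending), `eigenfunctions`
#'   (matrix, columns discretized on `grid`), `mean_curve`, `weights`
#'   (quadrature), `scores` (patients x d), `d`.
#' @export
fit_fpca <- function(curves, grid = NULL, d = 3, center = FALSE) {
  if (inherits(curves, "k_set") || is.data.frame(curves)) {
    if (length(unique(curves$pair)) != 1) {
      stop("fit_fpca() expects curves from a single pair", call. = FALSE)
    }
    grid <- sort(unique(curves$r))
    def <- dplyr::filter(curves, .data$defined)
    def <- def[order(def$r), ]
    curves <- t(vapply(split(def$value, def$patient_id)[unique(def$patient_id)],
                       identity, numeric(length(grid))))
  }
  K <- as.matrix(curves)
  m <- ncol(K)
  if (is.null(grid) || length(grid) != m) stop("grid must match curve columns", call. = FALSE)
  if (nrow(K) < 2) stop("need at least 2 defined curves", call. = FALSE)
  if (d < 1 || d > m) stop("d must be between 1 and the number of grid points", call. = FALSE)
  w <- trapezoid_weights(grid)
  mean_curve <- colMeans(K)
  Kc <- sweep(K, 2, mean_curve)
  Chat <- crossprod(Kc) / nrow(K)
  sw <- sqrt(w)
  S <- Chat * tcrossprod(sw)          # D C D
  ee <- eigen(S, symmetric = TRUE)
  lambda <- pmax(ee$values, 0)
  phi <- sweep(ee$vectors, 1, sw, "/")
  # deterministic sign: positive quadrature integral (fallback: largest element)
  for (j in seq_len(m)) {
    s <- sum(w * phi[, j])
    if (abs(s) < 1e-12) s <- phi[which.max(abs(phi[, j])), j]
    if (s < 0) phi[, j] <- -phi[, j]
  }
  proj <- if (center) Kc else K
  scores <- proj %*% (w * phi[, seq_len(d), drop = FALSE])
  colnames(scores) <- paste0("PC", seq_len(d))
  list(eigenvalues = lambda, eigenfunctions = phi, mean_curve = mean_curve,
       weights = w, scores = scores, d = d)
}

#' Number of components explaining a variance fraction
#'
#' @param eigenvalues Nonnegative eigenvalues in descending order.
#' @param threshold Target cumulative variance fraction (default 0.95).
#' @return Smallest d whose cumulative eigenvalue share reaches `threshold`
#'   (1 when all eigenvalues are zero).
#' @export
choose_d <- function(eigenvalues, threshold = 0.95) {
  lambda <- pmax(eigenvalues, 0)
  tot <- sum(lambda)
  if (tot <= 0) return(1L)
  which(cumsum(lambda) / tot >= threshold - 1e-12)[1]
}

#' Principal component score matrix for a K function set
#'
#' Runs FPCA per interaction and assembles the patient-by-score matrix used by
#' the forest. Patients whose K is undefined for a pair (no image contained
#' both types) receive the mean score vector of the defined patients — an
#' outcome-blind imputation that cannot inflate importance. Pairs undefined for
#' every patient are dropped with a warning.
#'
#' @param kset A `k_set` from [cohort_k()].
#' @param d Components per interaction (default 3, fixed across interactions).
#' @param center Passed to [fit_fpca()].
#' @return A `pc_scores` tibble: `patient_id` plus `<pair>_PC<i>` columns, with
#'   attributes `spatial_groups` (tibble `column`, `variable`, `component`) and
#'   `imputed` (tibble `patient_id`, `variable`).
#' @export
pc_scores <- function(kset, d = 3, center = FALSE) {
  grid <- attr(kset, "grid")
  if (is.null(grid)) grid <- sort(unique(kset$r))
  patients <- unique(kset$patient_id)
  pairs <- unique(kset$pair)
  out <- tibble::tibble(patient_id = patients)
  groups <- list(); imputed <- list()
  for (pr in pairs) {
    sub <- kset[kset$pair == pr, ]
    sub <- sub[order(sub$r), ]
    def_flag <- vapply(split(sub$defined, sub$patient_id)[patients],
                       function(z) z[1], logical(1))
    if (!any(def_flag)) {
      warning("pair ", pr, " undefined for every patient; dropped", call. = FALSE)
      next
    }
    if (sum(def_flag) < 2) {
      warning("pair ", pr, " defined for fewer than 2 patients; dropped", call. = FALSE)
      next
    }
    curves <- t(vapply(split(sub$value, sub$patient_id)[patients[def_flag]],
                       identity, numeric(length(grid))))
    fp <- fit_fpca(curves, grid, d = d, center = center)
    scores <- matrix(NA_real_, length(patients), d)
    scores[def_flag, ] <- fp$scores
    if (any(!def_flag)) {
      scores[!def_flag, ] <- matrix(colMeans(fp$scores), sum(!def_flag), d,
                                    byrow = TRUE)
      imputed[[pr]] <- tibble::tibble(patient_id = patients[!def_flag],
                                      variable = pr)
    }
    cn <- paste0(pr, "_PC", seq_len(d))
    colnames(scores) <- cn
    out <- dplyr::bind_cols(out, tibble::as_tibble(scores))
    groups[[pr]] <- tibble::tibble(column = cn, variable = pr,
                                   component = seq_len(d))
  }
  if (length(groups) == 0) stop("no pair is defined for at least 2 patients", call. = FALSE)
  structure(out,
            spatial_groups = dplyr::bind_rows(groups),
            imputed = if (length(imputed)) dplyr::bind_rows(imputed) else
              tibble::tibble(patient_id = character(), variable = character()),
            d = d,
            class = c("pc_scores", class(out)))
}
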