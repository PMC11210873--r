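#' Rectangular observation window
#'
#' Defines the rectangle on which an image's cells were observed. All K-function
#' edge corrections and the simulator use this window; areas enter the estimator
#' as \eqn{|i|}.
#'
#' @param x_min,x_max,y_min,y_max Window bounds (same spatial units as the cell
#'   coordinates, e.g. micrometers or unit-square coordinates).
#' @return A tibble with one row and columns `x_min`, `x_max`, `y_min`, `y_max`,
#'   `area`.
#' @examples
#' spatial_window() # unit square
#' @export
spatial_window <- function(x_min = 0, x_max = 1, y_min = 0, y_max = 1) {
  if (!(x_max > x_min && y_max > y_min)) {
    stop("window must satisfy x_max > x_min and y_max > y_min", call. = FALSE)
  }
  tibble::tibble(
    x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
    area = (x_max - x_min) * (y_max - y_min)
  )
}

window_side <- function(window) {
  min(window$x_max - window$x_min, window$y_max - window$y_min)
}

#' Read a cell table from delimited text
#'
#' Reads long-format single-cell data (one row per cell) with patient and image
#' identifiers, coordinates, and a phenotype label, validating every cell
#' against its image's window.
#'
#' @param path Path to a CSV/TSV file.
#' @param column_map Named character vector mapping the canonical names
#'   `patient_id`, `image_id`, `x`, `y`, `phenotype` to the file's column names.
#'   Defaults to identity.
#' @param windows Either a single window from [spatial_window()] applied to all
#'   images, or a tibble with an `image_id` column plus window bounds. When
#'   `NULL` and `infer_window = FALSE` the unit square is assumed.
#' @param infer_window If `TRUE`, use the bounding box of each image's cells as
#'   its window (never done silently by default).
#' @param phenotypes Optional character vector declaring the full phenotype set;
#'   defaults to the sorted labels present in the file.
#' @param delim Field delimiter, default `","`.
#' @return A `cell_table`: tibble with columns `patient_id`, `image_id`, `x`,
#'   `y`, `phenotype`, carrying the window table as attribute `windows` and the
#'   phenotype set as attribute `phenotypes`.
#' @export
read_cells <- function(path, column_map = NULL, windows = NULL,
                       infer_window = FALSE, phenotypes = NULL, delim = ",") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  canonical <- c("patient_id", "image_id", "x", "y", "phenotype")
  map <- setNames(canonical, canonical)
  if (!is.null(column_map)) map[names(column_map)] <- unname(column_map)
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0) {
    stop("input file lacks mapped column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cells <- tibble::tibble(
    patient_id = as.character(raw[[map[["patient_id"]]]]),
    image_id = as.character(raw[[map[["image_id"]]]]),
    x = as.numeric(raw[[map[["x"]]]]),
    y = as.numeric(raw[[map[["y"]]]]),
    phenotype = as.character(raw[[map[["phenotype"]]]])
  )
  as_cell_table(cells, windows = windows, infer_window = infer_window,
                phenotypes = phenotypes)
}

#' Validate a cell table
#'
#' @param cells Tibble with columns `patient_id`, `image_id`, `x`, `y`,
#'   `phenotype`.
#' @inheritParams read_cells
#' @return A validated `cell_table` tibble (see [read_cells()]).
#' @export
as_cell_table <- function(cells, windows = NULL, infer_window = FALSE,
                          phenotypes = NULL) {
  cells <- tibble::as_tibble(cells)
  needed <- c("patient_id", "image_id", "x", "y", "phenotype")
  if (!all(needed %in% names(cells))) {
    stop("cell table needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  cells$patient_id <- as.character(cells$patient_id)
  cells$image_id <- as.character(cells$image_id)
  cells$phenotype <- as.character(cells$phenotype)

  # each image must belong to exactly one patient
  img_pat <- dplyr::distinct(cells, .data$image_id, .data$patient_id)
  dup <- img_pat$image_id[duplicated(img_pat$image_id)]
  if (length(dup) > 0) {
    stop("image(s) assigned to more than one patient: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }

  image_ids <- unique(cells$image_id)
  if (infer_window) {
    windows <- cells |>
      dplyr::group_by(.data$image_id) |>
      dplyr::summarise(x_min = min(.data$x), x_max = max(.data$x),
                       y_min = min(.data$y), y_max = max(.data$y),
                       .groups = "drop") |>
      dplyr::mutate(area = (.data$x_max - .data$x_min) * (.data$y_max - .data$y_min))
  } else if (is.null(windows)) {
    windows <- tidyr::crossing(image_id = image_ids, spatial_window())
  } else if (!"image_id" %in% names(windows)) {
    windows <- tidyr::crossing(image_id = image_ids, windows)
  }
  if (!"area" %in% names(windows)) {
    windows <- dplyr::mutate(windows,
      area = (.data$x_max - .data$x_min) * (.data$y_max - .data$y_min))
  }
  windows$image_id <- as.character(windows$image_id)
  if (!all(image_ids %in% windows$image_id)) {
    stop("window table lacks image(s): ",
         paste(setdiff(image_ids, windows$image_id), collapse = ", "), call. = FALSE)
  }

  chk <- dplyr::left_join(cells, windows, by = "image_id")
  bad <- which(chk$x < chk$x_min | chk$x > chk$x_max |
                 chk$y < chk$y_min | chk$y > chk$y_max)
  if (length(bad) > 0) {
    stop("cell(s) outside declared window at row(s): ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ...", call. = FALSE)
  }
  if (is.null(phenotypes)) phenotypes <- sort(unique(cells$phenotype))
  if (!all(cells$phenotype %in% phenotypes)) {
    stop("phenotype label(s) outside declared set: ",
         paste(setdiff(unique(cells$phenotype), phenotypes), collapse = ", "),
         call. = FALSE)
  }
  structure(cells, windows = windows, phenotypes = phenotypes,
            class = c("cell_table", class(cells)))
}

#' Evenly spaced radius grid
#'
#' @param r_max Maximum radius R of the K functions. Defaults downstream to 25%
#'   of the shortest window side.
#' @param n_r Number of grid points (including 0 and `r_max`).
#' @return Strictly increasing numeric vector from 0 to `r_max`.
#' @export
radius_grid <- function(r_max, n_r = 50) {
  stopifnot(r_max > 0, n_r >= 2)
  seq(0, r_max, length.out = n_r)
}

# Ripley isotropic correction weight for a rectangular window: reciprocal of
# the fraction of the circle of radius d centred at (x, y) lying inside the
# window. Exterior arcs per edge minus double-counted corner overlaps; exact
# for d < half the shorter side.
ripley_iso_weight <- function(x, y, d, window) {
  w <- rep(1, length(d))
  pos <- d > 0
  if (!any(pos)) return(w)
  dd <- d[pos]
  dL <- x[pos] - window$x_min; dR <- window$x_max - x[pos]
  dB <- y[pos] - window$y_min; dT <- window$y_max - y[pos]
  edge_arc <- function(a) {
    out <- numeric(length(dd))
    inside <- a < dd
    out[inside] <- 2 * acos(pmin(1, a[inside] / dd[inside]))
    out
  }
  corner_arc <- function(a, b) {
    out <- numeric(length(dd))
    hit <- a * a + b * b < dd * dd
    out[hit] <- pi / 2 - asin(pmin(1, a[hit] / dd[hit])) -
      asin(pmin(1, b[hit] / dd[hit]))
    out
  }
  exterior <- edge_arc(dL) + edge_arc(dR) + edge_arc(dB) + edge_arc(dT) -
    corner_arc(dL, dB) - corner_arc(dL, dT) -
    corner_arc(dR, dB) - corner_arc(dR, dT)
  exterior <- pmin(exterior, 2 * pi * (1 - 1e-9))
  w[pos] <- 2 * pi / (2 * pi - exterior)
  w
}

# K curve for one ordered pair on one image. Circles are centred at the
# type-t cells, so the isotropic weight uses the type-t coordinates.
pair_k_values <- function(xt, yt, xp, yp, grid, window,
                          correction = "isotropic", self = FALSE,
                          normalization = "standard") {
  n_t <- length(xt); n_p <- length(xp)
  denom_pairs <- if (self) n_t * (n_t - 1) else n_t * n_p
  if (denom_pairs <= 0) return(rep(NA_real_, length(grid)))
  d <- sqrt(outer(xt, xp, "-")^2 + outer(yt, yp, "-")^2)
  if (self) d[cbind(seq_len(n_t), seq_len(n_t))] <- Inf
  keep <- which(d <= max(grid))
  scale <- window$area / denom_pairs
  if (normalization == "literal") scale <- scale * n_t
  if (length(keep) == 0) return(rep(0, length(grid)))
  dk <- d[keep]
  if (correction == "isotropic") {
    cx <- rep(xt, times = n_p)[keep]
    cy <- rep(yt, times = n_p)[keep]
    wk <- ripley_iso_weight(cx, cy, dk, window)
  } else {
    wk <- rep(1, length(dk))
  }
  ord <- order(dk)
  cw <- cumsum(wk[ord])
  idx <- findInterval(grid, dk[ord])
  scale * c(0, cw)[idx + 1]
}

#' Cross-type K function for a single image
#'
#' Estimates the cross K function \eqn{K_{t,t'}(r)}: the expected number of
#' type-\eqn{t'} cells within distance r of a typical type-\eqn{t} cell,
#' normalized by the type-\eqn{t'} intensity so that complete spatial
#' randomness gives \eqn{\pi r^2}. The estimator is
#' \eqn{|i|/(n_t n_{t'}) \sum_c \sum_{c'} w_{cc'} 1(d_{cc'} \le r)}, with
#' \eqn{w_{cc'}} the Ripley isotropic edge-correction weight (or 1 when
#' `correction = "none"`). For self pairs (\eqn{t = t'}) the \eqn{c = c'} pair
#' is excluded and the denominator becomes \eqn{n_t(n_t - 1)}.
#'
#' @param cells A `cell_table` restricted to one image.
#' @param t,t_prime Phenotype labels of the ordered pair.
#' @param grid Radius grid from [radius_grid()].
#' @param window Window tibble for the image (defaults to the cell table's
#'   window attribute).
#' @param correction `"isotropic"` (default) or `"none"`.
#' @param normalization `"standard"` divides by \eqn{n_t n_{t'}};
#'   `"literal"` reproduces the per-type-\eqn{t'}-only normalization (scales by
#'   \eqn{n_t}).
#' @return Tibble with columns `r`, `value`, `defined`, `n_t`, `n_t_prime`.
#'   When either type is absent the K is flagged undefined (`value = NA`).
#' @export
estimate_cross_k <- function(cells, t, t_prime, grid, window = NULL,
                             correction = c("isotropic", "none"),
                             normalization = c("standard", "literal")) {
  correction <- match.arg(correction)
  normalization <- match.arg(normalization)
  if (length(unique(cells$image_id)) > 1) {
    stop("estimate_cross_k() expects cells from a single image", call. = FALSE)
  }
  if (is.null(window)) {
    wins <- attr(cells, "windows")
    window <- wins[wins$image_id == cells$image_id[1], ]
  }
  is_t <- cells$phenotype == t
  is_p <- cells$phenotype == t_prime
  self <- identical(t, t_prime)
  n_t <- sum(is_t); n_p <- sum(is_p)
  vals <- pair_k_values(cells$x[is_t], cells$y[is_t],
                        cells$x[is_p], cells$y[is_p],
                        grid, window, correction, self, normalization)
  tibble::tibble(r = grid, value = vals, defined = !anyNA(vals),
                 n_t = n_t, n_t_prime = n_p)
}

#' Weighted average of per-image K functions
#'
#' Combines one patient's per-image K curves into a patient-level curve using
#' weights \eqn{n_{p,i,t}/n_{p,\cdot,t}} (prevalence of the centre type t in
#' each image). Images where the pair is undefined get weight 0; if no image
#' defines the pair the result is flagged undefined.
#'
#' @param per_image_ks List of tibbles as returned by [estimate_cross_k()], all
#'   on the same radius grid and pair.
#' @return Tibble with columns `r`, `value`, `defined`.
#' @export
average_k_over_images <- function(per_image_ks) {
  grids <- lapply(per_image_ks, function(k) k$r)
  if (length(unique(vapply(grids, paste, collapse = ",", ""))) != 1) {
    stop("per-image K functions must share the radius grid", call. = FALSE)
  }
  grid <- grids[[1]]
  ok <- vapply(per_image_ks, function(k) k$defined[1], logical(1))
  if (!any(ok)) {
    return(tibble::tibble(r = grid, value = NA_real_, defined = FALSE))
  }
  counts <- vapply(per_image_ks[ok], function(k) k$n_t[1], numeric(1))
  wts <- counts / sum(counts)
  mat <- vapply(per_image_ks[ok], function(k) k$value, numeric(length(grid)))
  tibble::tibble(r = grid, value = as.vector(mat %*% wts), defined = TRUE)
}

#' Cohort-wide K function set
#'
#' Computes the patient-level cross K function for every requested ordered
#' phenotype pair, averaging over each patient's images.
#'
#' @param cells A `cell_table` (see [read_cells()]).
#' @param pairs Optional two-column data frame (`t`, `t_prime`) restricting the
#'   ordered pairs; defaults to all \eqn{T^2} pairs.
#' @param r_max Maximum radius; defaults to 25% of the shortest window side.
#' @param n_r Number of radius grid points.
#' @inheritParams estimate_cross_k
#' @return A `k_set`: long tibble (`patient_id`, `t`, `t_prime`, `pair`, `r`,
#'   `value`, `defined`) with the radius grid as attribute `grid`. Pair labels
#'   are `"<t>_<t'>"`.
#' @export
cohort_k <- function(cells, pairs = NULL, r_max = NULL, n_r = 50,
                     correction = c("isotropic", "none"),
                     normalization = c("standard", "literal")) {
  correction <- match.arg(correction)
  normalization <- match.arg(normalization)
  windows <- attr(cells, "windows")
  phenos <- attr(cells, "phenotypes")
  if (is.null(windows) || is.null(phenos)) {
    cells <- as_cell_table(cells)
    windows <- attr(cells, "windows")
    phenos <- attr(cells, "phenotypes")
  }
  if (is.null(r_max)) {
    r_max <- 0.25 * min(windows$x_max - windows$x_min,
                        windows$y_max - windows$y_min)
  }
  grid <- radius_grid(r_max, n_r)
  if (is.null(pairs)) {
    pairs <- tidyr::crossing(t = phenos, t_prime = phenos)
  }
  pairs <- tibble::as_tibble(pairs)

  by_image <- split(seq_len(nrow(cells)),
                    paste(cells$patient_id, cells$image_id, sep = "\r"))
  patients <- unique(cells$patient_id)
  T_n <- length(phenos)
  n_r_grid <- length(grid)

  # One pass per image: all pairwise distances within r_max, edge-correction
  # weights, and cumulative weight curves grouped by ordered type code.
  image_info <- lapply(by_image, function(idx) {
    img <- cells[idx, ]
    win <- windows[windows$image_id == img$image_id[1], ]
    tc <- match(img$phenotype, phenos)
    n <- nrow(img)
    counts <- tabulate(tc, T_n)
    curves <- list()
    if (n >= 2) {
      d2 <- outer(img$x, img$x, "-")^2 + outer(img$y, img$y, "-")^2
      diag(d2) <- Inf                      # exclude the c = c' pair
      keep <- which(d2 <= max(grid)^2)
      if (length(keep) > 0) {
        ci <- ((keep - 1L) %% n) + 1L      # centre cell (row index)
        cj <- ((keep - 1L) %/% n) + 1L
        dk <- sqrt(d2[keep])
        wk <- if (correction == "isotropic") {
          ripley_iso_weight(img$x[ci], img$y[ci], dk, win)
        } else rep(1, length(dk))
        ord <- order(dk)
        code <- (tc[ci] - 1L) * T_n + tc[cj]
        ids_by_code <- split(ord, code[ord])
        curves <- lapply(ids_by_code, function(ids) {
          cw <- cumsum(wk[ids])
          c(0, cw)[findInterval(grid, dk[ids]) + 1L]
        })
      }
    }
    list(patient = img$patient_id[1], area = win$area, counts = counts,
         curves = curves)
  })
  pat_of_image <- vapply(image_info, function(ii) ii$patient, "")

  # assemble patient-level curves into flat vectors (one block per pair)
  n_pat <- length(patients)
  imgs_of <- split(seq_along(image_info), pat_of_image)[patients]
  blocks <- vector("list", nrow(pairs))
  zero <- numeric(n_r_grid)
  for (j in seq_len(nrow(pairs))) {
    ti <- match(pairs$t[j], phenos); tpi <- match(pairs$t_prime[j], phenos)
    self <- ti == tpi
    code <- as.character((ti - 1L) * T_n + tpi)
    V <- matrix(NA_real_, n_r_grid, n_pat)
    def <- logical(n_pat)
    for (pi in seq_len(n_pat)) {
      vals <- NULL; wts <- NULL
      for (ii in image_info[imgs_of[[pi]]]) {
        n_t <- ii$counts[ti]; n_p <- ii$counts[tpi]
        denom <- if (self) n_t * (n_t - 1) else n_t * n_p
        if (denom <= 0) next
        cum <- ii$curves[[code]]
        if (is.null(cum)) cum <- zero
        scale <- ii$area / denom
        if (normalization == "literal") scale <- scale * n_t
        vals <- cbind(vals, scale * cum)
        wts <- c(wts, n_t)
      }
      if (!is.null(vals)) {
        V[, pi] <- vals %*% (wts / sum(wts))
        def[pi] <- TRUE
      }
    }
    blocks[[j]] <- list(V = V, def = def)
  }
  kset <- tibble::tibble(
    patient_id = rep(rep(patients, each = n_r_grid), nrow(pairs)),
    t = rep(pairs$t, each = n_r_grid * n_pat),
    t_prime = rep(pairs$t_prime, each = n_r_grid * n_pat),
    r = rep(grid, n_pat * nrow(pairs)),
    value = unlist(lapply(blocks, function(b) as.vector(b$V)),
                   use.names = FALSE),
    defined = rep(unlist(lapply(blocks, function(b) b$def),
                         use.names = FALSE), each = n_r_grid)
  )
  kset$pair <- paste(kset$t, kset$t_prime, sep = "_")
  kset <- kset[, c("patient_id", "t", "t_prime", "pair", "r", "value",
                   "defined")]
  structure(kset, grid = grid, phenotypes = phenos,
            class = c("k_set", class(kset)))
}

#' Write / read a K function set as long CSV
#'
#' @param kset A `k_set` from [cohort_k()].
#' @param path Output CSV path.
#' @export
write_k_set <- function(kset, path) {
  readr::write_csv(tibble::as_tibble(kset), path)
  invisible(path)
}

#' @rdname write_k_set
#' @export
read_k_set <- function(path) {
  kset <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  grid <- sort(unique(kset$r))
  structure(kset, grid = grid, phenotypes = sort(unique(c(kset$t, kset$t_prime))),
            class = c("k_set", class(kset)))
}
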