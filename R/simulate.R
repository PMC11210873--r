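# Nested modified-Thomas-process simulator.
#
# Cell types are laid down iteratively: "random" types are homogeneous Poisson
# in the window; "child_of" types place Poisson offspring displaced from
# realized parent cells by bivariate Normal N(0, sigma^2 I); "self_cluster"
# types place offspring around hidden Poisson parents that are then removed,
# so the type appears self-clustered. Offspring falling outside the window are
# redrawn, keeping per-parent counts exact. Outcome-linked types switch their
# dispersal in the positive class: tighter clustering (smaller sigma) or
# repulsion (radial displacement |N(delta, sigma^2)| in a uniform direction).

#' Declare one simulated cell type
#'
#' @param name Phenotype label.
#' @param placement `"random"`, `"self_cluster"`, or `"child_of"`.
#' @param parent Parent type name (required for `placement = "child_of"`).
#' @param parent_mean Poisson mean of the number of parent points ("random":
#'   the cells themselves; "self_cluster": hidden parents).
#' @param offspring_mean Poisson mean of offspring per parent point.
#' @param sigma Offspring dispersal scale (bivariate Normal SD), in window
#'   units.
#' @param relation `"none"`, `"cluster_with_outcome"` (positive class uses
#'   `sigma_positive`), or `"repel_with_outcome"` (positive class displaces
#'   offspring radially by `|N(repel_delta, sigma^2)|`).
#' @param sigma_positive,repel_delta Positive-class overrides (see `relation`).
#' @return One-row tibble; rows bind into the type table of [sim_config()].
#' @export
cell_type_spec <- function(name, placement = c("random", "self_cluster", "child_of"),
                           parent = NA_character_, parent_mean = NA_real_,
                           offspring_mean = NA_real_, sigma = NA_real_,
                           relation = c("none", "cluster_with_outcome",
                                        "repel_with_outcome"),
                           sigma_positive = NA_real_, repel_delta = NA_real_) {
  placement <- match.arg(placement)
  relation <- match.arg(relation)
  if (placement == "child_of" && is.na(parent)) {
    stop("child_of placement needs a parent type", call. = FALSE)
  }
  tibble::tibble(name = name, placement = placement, parent = parent,
                 parent_mean = parent_mean, offspring_mean = offspring_mean,
                 sigma = sigma, relation = relation,
                 sigma_positive = sigma_positive, repel_delta = repel_delta)
}

#' Simulation configuration
#'
#' @param types Tibble of [cell_type_spec()] rows, in placement order (parents
#'   before children).
#' @param n_positive,n_negative Patients per outcome class (defaults 17/17).
#' @param images_per_patient Images simulated per patient (default 1).
#' @param window Observation window (default unit square).
#' @param age_mean_negative,age_mean_positive Mean of the Normal(mean, 1) age
#'   meta-variable per class (equal means give a null meta-variable).
#' @param n_noise_positive Number of positive patients generated from the
#'   negative-class mechanism (label noise; default 0).
#' @return A `sim_config` list.
#' @export
sim_config <- function(types, n_positive = 17, n_negative = 17,
                       images_per_patient = 1, window = spatial_window(),
                       age_mean_negative = 25, age_mean_positive = 25,
                       n_noise_positive = 0) {
  parents <- types$parent[types$placement == "child_of"]
  if (!all(parents %in% types$name)) {
    stop("child_of references undeclared parent type(s)", call. = FALSE)
  }
  stopifnot(n_positive >= 1, n_negative >= 1, images_per_patient >= 1)
  structure(list(types = types, n_positive = n_positive,
                 n_negative = n_negative,
                 images_per_patient = images_per_patient, window = window,
                 age_mean_negative = age_mean_negative,
                 age_mean_positive = age_mean_positive,
                 n_noise_positive = n_noise_positive),
            class = "sim_config")
}

draw_offspring <- function(px, py, n_per_parent, sigma, window,
                           repel_delta = NA_real_) {
  total <- sum(n_per_parent)
  if (total == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  cx <- rep(px, n_per_parent)
  cy <- rep(py, n_per_parent)
  x <- numeric(total); y <- numeric(total)
  todo <- seq_len(total)
  while (length(todo) > 0) {
    m <- length(todo)
    if (is.na(repel_delta)) {
      nx <- cx[todo] + rnorm(m, 0, sigma)
      ny <- cy[todo] + rnorm(m, 0, sigma)
    } else {
      rad <- abs(rnorm(m, repel_delta, sigma))
      ang <- runif(m, 0, 2 * pi)
      nx <- cx[todo] + rad * cos(ang)
      ny <- cy[todo] + rad * sin(ang)
    }
    ok <- nx >= window$x_min & nx <= window$x_max &
      ny >= window$y_min & ny <= window$y_max
    x[todo[ok]] <- nx[ok]
    y[todo[ok]] <- ny[ok]
    todo <- todo[!ok]
  }
  data.frame(x = x, y = y)
}

#' Simulate one image
#'
#' Uses the current RNG state; seed via `set.seed()` or use
#' [simulate_cohort()].
#'
#' @param config A `sim_config`.
#' @param outcome `"negative"` or `"positive"`; selects outcome-linked
#'   dispersal for types with a relation.
#' @return Tibble (`x`, `y`, `phenotype`).
#' @export
simulate_image <- function(config, outcome = c("negative", "positive")) {
  outcome <- match.arg(outcome)
  win <- config$window
  placed <- list()
  for (k in seq_len(nrow(config$types))) {
    sp <- config$types[k, ]
    sigma <- sp$sigma
    delta <- NA_real_
    if (outcome == "positive") {
      if (sp$relation == "cluster_with_outcome") sigma <- sp$sigma_positive
      if (sp$relation == "repel_with_outcome") delta <- sp$repel_delta
    }
    if (sp$placement == "random") {
      n <- rpois(1, sp$parent_mean)
      pts <- data.frame(x = runif(n, win$x_min, win$x_max),
                        y = runif(n, win$y_min, win$y_max))
    } else if (sp$placement == "self_cluster") {
      np <- rpois(1, sp$parent_mean)
      px <- runif(np, win$x_min, win$x_max)
      py <- runif(np, win$y_min, win$y_max)
      pts <- draw_offspring(px, py, rpois(np, sp$offspring_mean), sigma, win)
    } else {
      par_pts <- placed[[sp$parent]]
      if (is.null(par_pts) || nrow(par_pts) == 0) {
        pts <- data.frame(x = numeric(0), y = numeric(0))
      } else {
        pts <- draw_offspring(par_pts$x, par_pts$y,
                              rpois(nrow(par_pts), sp$offspring_mean),
                              sigma, win, repel_delta = delta)
      }
    }
    pts$phenotype <- rep(sp$name, nrow(pts))
    placed[[sp$name]] <- pts
  }
  tibble::as_tibble(dplyr::bind_rows(placed))
}

#' Simulate a patient cohort
#'
#' Simulates every patient's image(s), ages, and outcomes. The first
#' `n_noise_positive` positive patients are generated from the negative-class
#' mechanism (including age), mimicking label noise.
#'
#' @param config A `sim_config`.
#' @param seed Integer seed (reproducible cohorts).
#' @return List with `cells` (a `cell_table`), `meta` (tibble `patient_id`,
#'   `age`), `outcomes` (tibble `patient_id`, `outcome` factor
#'   negative/positive).
#' @export
simulate_cohort <- function(config, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_tot <- config$n_positive + config$n_negative
  ids <- sprintf("P%02d", seq_len(n_tot))
  outcome <- c(rep("positive", config$n_positive),
               rep("negative", config$n_negative))
  mechanism <- outcome
  if (config$n_noise_positive > 0) {
    mechanism[seq_len(min(config$n_noise_positive, config$n_positive))] <- "negative"
  }
  cells <- vector("list", n_tot)
  ages <- numeric(n_tot)
  for (i in seq_len(n_tot)) {
    imgs <- lapply(seq_len(config$images_per_patient), function(j) {
      img <- simulate_image(config, mechanism[i])
      img$image_id <- sprintf("%s_I%d", ids[i], j)
      img
    })
    pat <- dplyr::bind_rows(imgs)
    pat$patient_id <- ids[i]
    cells[[i]] <- pat
    mu <- if (mechanism[i] == "positive") config$age_mean_positive else
      config$age_mean_negative
    ages[i] <- rnorm(1, mu, 1)
  }
  cell_tab <- as_cell_table(dplyr::bind_rows(cells), windows = config$window,
                            phenotypes = config$types$name)
  list(cells = cell_tab,
       meta = tibble::tibble(patient_id = ids, age = ages),
       outcomes = tibble::tibble(patient_id = ids,
                                 outcome = factor(outcome,
                                                  levels = c("negative", "positive"))))
}

#' Four-cell-type simulation profile
#'
#' Small cohort profile used in the threshold-calibration experiments: c1
#' random (the sparse parent type), c2 and c3 Thomas children of c1, c4
#' random. The parent intensity is deliberately low so the nested-cluster
#' component of the cross K function (whose height scales with the reciprocal
#' parent intensity) is a leading mode of between-patient curve variation and
#' is therefore captured by the first few principal components. In the
#' relation variant, positives show tighter c2 clustering around c1 (sigma
#' 0.025 to 0.012), c3 repulsion from c1, and an age shift (25 to 27).
#'
#' @param relation Link c2/c3 dispersal and age to the outcome (default
#'   `FALSE`: the null profile, every variable independent of outcome).
#' @param sigma_c2_positive Positive-class sigma for c2 around c1 (relation
#'   case; the power experiment sweeps this).
#' @return A `sim_config`.
#' @export
sim_profile_4type <- function(relation = FALSE, sigma_c2_positive = 0.012) {
  types <- dplyr::bind_rows(
    cell_type_spec("c1", "random", parent_mean = 8),
    cell_type_spec("c2", "child_of", parent = "c1", offspring_mean = 25,
                   sigma = 0.025,
                   relation = if (relation) "cluster_with_outcome" else "none",
                   sigma_positive = sigma_c2_positive),
    cell_type_spec("c3", "child_of", parent = "c1", offspring_mean = 8,
                   sigma = 0.03,
                   relation = if (relation) "repel_with_outcome" else "none",
                   repel_delta = 0.06),
    cell_type_spec("c4", "random", parent_mean = 150))
  sim_config(types,
             age_mean_positive = if (relation) 27 else 25,
             n_noise_positive = if (relation) 2 else 0)
}

#' Sixteen-cell-type TNBC-like simulation profile
#'
#' Mimics the qualitative structure of a TNBC MIBI cohort: 16 phenotypes with
#' common types appearing hundreds of times per image and rare types fewer
#' than ten; c2, c3, c16 cluster around the random parent type c1; c8-c12
#' self-cluster; the rest are completely random. The relation variant links
#' c2 (tighter clustering around c1), c3 (repulsion from c1) and age to the
#' outcome, with 2 noise-labelled positive patients.
#'
#' @inheritParams sim_profile_4type
#' @return A `sim_config`.
#' @export
sim_profile_16type <- function(relation = FALSE, sigma_c2_positive = 0.012) {
  types <- dplyr::bind_rows(
    cell_type_spec("c1", "random", parent_mean = 8),
    cell_type_spec("c2", "child_of", parent = "c1", offspring_mean = 25,
                   sigma = 0.025,
                   relation = if (relation) "cluster_with_outcome" else "none",
                   sigma_positive = sigma_c2_positive),
    cell_type_spec("c3", "child_of", parent = "c1", offspring_mean = 8,
                   sigma = 0.03,
                   relation = if (relation) "repel_with_outcome" else "none",
                   repel_delta = 0.06),
    cell_type_spec("c4", "random", parent_mean = 400),
    cell_type_spec("c5", "random", parent_mean = 80),
    cell_type_spec("c6", "random", parent_mean = 30),
    cell_type_spec("c7", "random", parent_mean = 8),
    cell_type_spec("c8", "self_cluster", parent_mean = 12, offspring_mean = 15,
                   sigma = 0.02),
    cell_type_spec("c9", "self_cluster", parent_mean = 8, offspring_mean = 10,
                   sigma = 0.03),
    cell_type_spec("c10", "self_cluster", parent_mean = 20, offspring_mean = 8,
                   sigma = 0.015),
    cell_type_spec("c11", "self_cluster", parent_mean = 5, offspring_mean = 6,
                   sigma = 0.02),
    cell_type_spec("c12", "self_cluster", parent_mean = 3, offspring_mean = 4,
                   sigma = 0.025),
    cell_type_spec("c13", "random", parent_mean = 250),
    cell_type_spec("c14", "random", parent_mean = 15),
    cell_type_spec("c15", "random", parent_mean = 5),
    cell_type_spec("c16", "child_of", parent = "c1", offspring_mean = 1,
                   sigma = 0.02))
  sim_config(types,
             age_mean_positive = if (relation) 27 else 25,
             n_noise_positive = if (relation) 2 else 0)
}
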