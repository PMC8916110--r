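#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a middle-aged to
#' older population cohort (ages 45-74, about 45% female) with cortical
#' thickness declining with age, white-matter damage (PSMD) increasing with
#' age, Trail Making Test scores worsening with age, and resting-state
#' connectomes whose global mean functional connectivity sits near 0.36,
#' with a planted connected subnetwork of edges whose connectivity declines
#' with age partly through a cortical-thickness pathway.
#'
#' Age-correlation targets are achieved analytically: for a fixed slope
#' `b` on age, the noise standard deviation is set to
#' `|b| * sd(age) * sqrt(1 / r^2 - 1)` so that the population correlation
#' equals the target exactly, keeping the generating model interpretable
#' for mediation recovery.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param n_rois Number of ROIs per connectome (>= 4).
#' @param seed Integer seed; identical seeds yield identical outputs.
#' @param n_timepoints BOLD series length (volumes) for time-series
#'   generation. Default 125.
#' @param tr_ms Repetition time in milliseconds. Default 2500.
#' @param age_min,age_max Age range in years (uniform integer ages).
#' @param female_fraction Proportion of female subjects.
#' @param target_r_age_thickness Population correlation between age and
#'   cortical thickness. Default -0.4.
#' @param target_r_age_psmd Population correlation between age and PSMD.
#'   Default +0.5.
#' @param target_r_age_tmtb Population correlation between age and the
#'   Trail Making Test scores. Default +0.3.
#' @param baseline_fc_mean Grand mean functional connectivity of the
#'   generated (absolute-mode) connectomes. Default 0.36.
#' @param edge_noise_sd Subject-level edge noise SD, in correlation units.
#' @param planted_edge_fraction Fraction of the designated network's edges
#'   given a true (negative) age slope, as a connected subgraph.
#' @param planted_slope Marginal age slope of each planted edge, in FC
#'   units per year (the slope a simple regression of the edge on age
#'   recovers; it decomposes as `mediation_c_direct + mediation_a *
#'   mediation_b`).
#' @param mediation_a Age slope of cortical thickness (thickness units per
#'   year); the a-path of the planted mediation structure.
#' @param mediation_b Thickness coefficient in the planted edge equation
#'   (FC units per thickness unit); the b-path.
#' @param mediation_c_direct Direct age slope of planted edges (FC units
#'   per year). Defaults to `planted_slope - mediation_a * mediation_b` so
#'   the marginal slope equals `planted_slope`.
#' @param outcome_b_fc Effect of planted-subnetwork mean FC on the TMTB
#'   completion time, in seconds per FC unit; the b-path of the
#'   age -> FC -> executive-function structure. Negative values mean
#'   higher connectivity predicts faster (better) performance.
#' @return A `generator_config` list with validated fields.
#' @export
generator_config <- function(n_subjects = 200,
                             n_rois = 100,
                             seed = 1,
                             n_timepoints = 125,
                             tr_ms = 2500,
                             age_min = 45,
                             age_max = 74,
                             female_fraction = 0.454,
                             target_r_age_thickness = -0.4,
                             target_r_age_psmd = 0.5,
                             target_r_age_tmtb = 0.3,
                             baseline_fc_mean = 0.36,
                             edge_noise_sd = 0.03,
                             planted_edge_fraction = 0.15,
                             planted_slope = -0.002,
                             mediation_a = -0.005,
                             mediation_b = 0.1,
                             mediation_c_direct = NULL,
                             outcome_b_fc = -40) {
  cfg <- list(
    n_subjects = n_subjects, n_rois = n_rois, seed = seed,
    n_timepoints = n_timepoints, tr_ms = tr_ms,
    age_min = age_min, age_max = age_max,
    female_fraction = female_fraction,
    target_r_age_thickness = target_r_age_thickness,
    target_r_age_psmd = target_r_age_psmd,
    target_r_age_tmtb = target_r_age_tmtb,
    baseline_fc_mean = baseline_fc_mean,
    edge_noise_sd = edge_noise_sd,
    planted_edge_fraction = planted_edge_fraction,
    planted_slope = planted_slope,
    mediation_a = mediation_a,
    mediation_b = mediation_b,
    mediation_c_direct = mediation_c_direct %||%
      (planted_slope - mediation_a * mediation_b),
    outcome_b_fc = outcome_b_fc
  )

  check_count <- function(field, min) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < min || v != round(v)) {
      stop(sprintf("invalid configuration: `%s` must be an integer >= %d", field, min),
           call. = FALSE)
    }
  }
  check_prop <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1) {
      stop(sprintf("invalid configuration: `%s` must be a proportion in [0, 1]", field),
           call. = FALSE)
    }
  }
  check_corr <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || abs(v) >= 1) {
      stop(sprintf("invalid configuration: `%s` must be a correlation in (-1, 1)", field),
           call. = FALSE)
    }
  }
  check_count("n_subjects", 3)
  check_count("n_rois", 4)
  check_count("n_timepoints", 1)
  check_count("seed", 0)
  check_prop("female_fraction")
  check_prop("planted_edge_fraction")
  check_corr("target_r_age_thickness")
  check_corr("target_r_age_psmd")
  check_corr("target_r_age_tmtb")
  if (!is.numeric(cfg$age_min) || !is.numeric(cfg$age_max) ||
      cfg$age_min >= cfg$age_max) {
    stop("invalid configuration: `age_min` must be less than `age_max`", call. = FALSE)
  }
  if (!is.numeric(cfg$baseline_fc_mean) || cfg$baseline_fc_mean <= 0 ||
      cfg$baseline_fc_mean >= 1) {
    stop("invalid configuration: `baseline_fc_mean` must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(cfg$edge_noise_sd) || cfg$edge_noise_sd <= 0) {
    stop("invalid configuration: `edge_noise_sd` must be positive", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Population SD of uniform integers on [lo, hi].
uniform_int_sd <- function(lo, hi) {
  k <- hi - lo + 1
  sqrt((k^2 - 1) / 12)
}

#' Generate a synthetic cohort covariate table
#'
#' Draws per-subject age, sex, education, cortical thickness, PSMD and
#' Trail Making Test A/B scores with the marginal scales and age
#' correlations set by the configuration. Ages are uniform integers on
#' `[age_min, age_max]`; sex is Bernoulli(`female_fraction`) coded 0 =
#' male, 1 = female; education is uniform integer years 8-18. TMT scores
#' are truncated below at 5 s to keep completion times positive.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `subject_id`, `age`, `sex`, `education`,
#'   `cortical_thickness`, `psmd`, `tmta`, `tmtb`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  age <- sample(seq(config$age_min, config$age_max), n, replace = TRUE)
  sex <- stats::rbinom(n, 1, config$female_fraction)
  education <- sample(8:18, n, replace = TRUE)
  sd_age <- uniform_int_sd(config$age_min, config$age_max)
  age_mid <- (config$age_min + config$age_max) / 2

  lin <- function(center, slope_mag, target_r) {
    if (target_r == 0) {
      return(center + stats::rnorm(n, 0, slope_mag * sd_age))
    }
    slope <- sign(target_r) * slope_mag
    sigma <- slope_mag * sd_age * sqrt(1 / target_r^2 - 1)
    center + slope * (age - age_mid) + stats::rnorm(n, 0, sigma)
  }

  # thickness slope magnitude is |mediation_a| so the generating a-path is
  # exactly the configured value when the sign of the target agrees
  thickness <- lin(2.32, abs(config$mediation_a), config$target_r_age_thickness)
  psmd <- lin(2.17e-4, 2e-6, config$target_r_age_psmd)
  tmtb <- pmax(5, lin(79, 1.0, config$target_r_age_tmtb))
  tmta <- pmax(5, lin(36, 0.5, config$target_r_age_tmtb))

  tibble::tibble(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    age = as.integer(age),
    sex = as.integer(sex),
    education = as.integer(education),
    cortical_thickness = thickness,
    psmd = psmd,
    tmta = tmta,
    tmtb = tmtb
  )
}

#' Default parcellation for synthetic connectomes
#'
#' Assigns ROIs to resting-state networks in contiguous blocks: the first
#' four blocks are the default, dorsal attention, salience and control
#' networks (each `floor(n_rois / 5)` ROIs); remaining ROIs are labelled
#' `other`. Every ROI belongs to exactly one network.
#'
#' @param n_rois Number of ROIs (>= 4).
#' @return A tibble with columns `roi_index` (1-based, contiguous),
#'   `roi_name`, `network`.
#' @export
make_parcellation <- function(n_rois) {
  stopifnot(n_rois >= 4)
  nets <- c("default", "dorsal_attention", "salience", "control")
  block <- max(1, floor(n_rois / 5))
  network <- rep("other", n_rois)
  for (k in seq_along(nets)) {
    lo <- (k - 1) * block + 1
    hi <- min(k * block, n_rois)
    if (lo <= hi) network[lo:hi] <- nets[k]
  }
  tibble::tibble(
    roi_index = seq_len(n_rois),
    roi_name = sprintf("ROI_%03d", seq_len(n_rois)),
    network = network
  )
}

# A connected random subgraph with k edges within `nodes`: random
# recursive tree on min(length(nodes), k + 1) shuffled nodes, then extra
# random edges among those nodes until k edges.
connected_random_subgraph <- function(nodes, k) {
  if (k <= 0) return(matrix(integer(0), ncol = 2))
  nodes <- sample(nodes)
  t_n <- min(length(nodes), k + 1)
  use <- nodes[seq_len(t_n)]
  edges <- matrix(integer(0), ncol = 2)
  for (v in seq(2, t_n)) {
    u <- use[sample.int(v - 1, 1)]
    edges <- rbind(edges, c(min(u, use[v]), max(u, use[v])))
  }
  all_pairs <- t(utils::combn(sort(use), 2))
  key <- function(m) paste(m[, 1], m[, 2])
  pool <- all_pairs[!(key(all_pairs) %in% key(edges)), , drop = FALSE]
  extra <- k - nrow(edges)
  if (extra > 0) {
    if (extra > nrow(pool)) {
      stop("planted_edge_fraction requests more edges than the network holds",
           call. = FALSE)
    }
    pick <- pool[sample.int(nrow(pool), extra), , drop = FALSE]
    edges <- rbind(edges, pick)
  }
  edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
}

#' Generate a stack of synthetic connectomes with planted age effects
#'
#' Builds one absolute-mode connectivity matrix per subject. Every edge
#' has value `baseline_fc_mean` plus a fixed per-edge offset (SD 0.02)
#' plus subject noise (SD `edge_noise_sd`), clipped to `[0.01, 0.99]`.
#' A connected random subgraph within the default network — covering
#' `planted_edge_fraction` of that network's edges — additionally carries
#' the age effect: a direct term `mediation_c_direct * (age - mean age)`
#' and a thickness-mediated term `mediation_b * (thickness - mean
#' thickness)`, so the marginal age slope of each planted edge is
#' `planted_slope`. When `outcome_b_fc` is nonzero the returned cohort's
#' TMTB score is augmented by `outcome_b_fc * (subnetwork FC - mean)`,
#' planting the age -> FC -> executive-function pathway.
#'
#' @param config A [generator_config()].
#' @param cohort The cohort generated from the same configuration.
#' @return A list with elements `matrices` (list of symmetric
#'   zero-diagonal matrices, one per subject, in cohort order),
#'   `ground_truth` (tibble `node_i`, `node_j`, `true_slope`, with
#'   attribute `true_paths`), `cohort` (the input cohort with a
#'   `planted_fc` column and the TMTB adjustment applied) and
#'   `parcellation`.
#' @export
generate_connectomes <- function(config, cohort) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.data.frame(cohort) || nrow(cohort) != config$n_subjects) {
    stop(sprintf("cohort has %d rows but the configuration expects %d subjects",
                 nrow(cohort), config$n_subjects), call. = FALSE)
  }
  need <- c("age", "cortical_thickness", "tmtb")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    stop("cohort is missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  set.seed(config$seed + 1L)

  n <- config$n_subjects
  p <- config$n_rois
  parc <- make_parcellation(p)
  edges <- edge_index_table(p)
  E <- nrow(edges)

  net_nodes <- parc$roi_index[parc$network == "default"]
  e_net <- length(net_nodes) * (length(net_nodes) - 1) / 2
  k <- floor(config$planted_edge_fraction * e_net + 0.5)
  planted_pairs <- connected_random_subgraph(net_nodes, k)
  planted_idx <- if (nrow(planted_pairs)) edge_positions(planted_pairs, p) else integer(0)

  edge_offset <- stats::rnorm(E, 0, 0.02)
  age_c <- cohort$age - mean(cohort$age)
  th_c <- cohort$cortical_thickness - mean(cohort$cortical_thickness)

  values <- matrix(stats::rnorm(n * E, 0, config$edge_noise_sd), n, E)
  values <- sweep(values, 2, config$baseline_fc_mean + edge_offset, "+")
  if (length(planted_idx)) {
    signal <- config$mediation_c_direct * age_c + config$mediation_b * th_c
    values[, planted_idx] <- values[, planted_idx] + signal
  }
  values <- pmin(pmax(values, 0.01), 0.99)

  matrices <- lapply(seq_len(n), function(s) {
    m <- edge_vector_to_matrix(values[s, ], p)
    attr(m, "mode") <- "absolute"
    attr(m, "retained_proportion") <- "unthresholded"
    m
  })
  names(matrices) <- cohort$subject_id

  true_slope <- config$mediation_c_direct + config$mediation_a * config$mediation_b
  ground_truth <- tibble::tibble(
    node_i = as.integer(planted_pairs[, 1]),
    node_j = as.integer(planted_pairs[, 2]),
    true_slope = rep(true_slope, nrow(planted_pairs))
  )
  attr(ground_truth, "true_paths") <- list(
    a = config$mediation_a, b = config$mediation_b,
    c_direct = config$mediation_c_direct,
    outcome_b_fc = config$outcome_b_fc
  )
  attr(ground_truth, "planted_edges") <- planted_idx

  out_cohort <- cohort
  if (length(planted_idx)) {
    planted_fc <- rowMeans(values[, planted_idx, drop = FALSE])
    out_cohort$planted_fc <- planted_fc
    if (config$outcome_b_fc != 0) {
      out_cohort$tmtb <- pmax(5, out_cohort$tmtb +
                                config$outcome_b_fc * (planted_fc - mean(planted_fc)))
    }
  }

  list(matrices = matrices, ground_truth = ground_truth,
       cohort = out_cohort, parcellation = parc)
}

#' Generate a multivariate time series with a target correlation matrix
#'
#' Draws `n_timepoints` samples from a zero-mean Gaussian whose population
#' correlation matrix is `target` (via the Cholesky factor), so the sample
#' correlation of the series converges to `target` as the series grows.
#'
#' @param target Symmetric positive-definite correlation matrix with unit
#'   diagonal.
#' @param n_timepoints Series length (>= 3, so correlations are defined).
#' @param seed Integer seed.
#' @return An ROI x time matrix (`nrow(target)` rows, `n_timepoints`
#'   columns).
#' @export
generate_timeseries <- function(target, n_timepoints = 125, seed = 1) {
  check_symmetric(target, what = "`target`")
  if (max(abs(diag(target) - 1)) > 1e-8) {
    stop("`target` must have unit diagonal", call. = FALSE)
  }
  if (!is.numeric(n_timepoints) || n_timepoints < 3) {
    stop("`n_timepoints` must be at least 3 to define correlations", call. = FALSE)
  }
  ev <- eigen(target, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("`target` is not positive-definite: smallest eigenvalue %.3g is %s",
                 min(ev), if (min(ev) < 0) "negative" else "zero"), call. = FALSE)
  }
  set.seed(seed)
  L <- chol(target)
  z <- matrix(stats::rnorm(n_timepoints * nrow(target)), n_timepoints, nrow(target))
  t(z %*% L)
}

#' Simulate a minimal single-mediator dataset
#'
#' Generates `x -> m -> y` data with known path coefficients for mediation
#' recovery and calibration experiments: `m = a x + e_m`,
#' `y = c_direct x + b m + e_y`, all noise standard normal by default.
#'
#' @param n Number of observations.
#' @param a,b,c_direct True path coefficients.
#' @param sd_m,sd_y Noise SDs of the mediator and outcome equations.
#' @param seed Integer seed.
#' @return A tibble with columns `x`, `m`, `y`.
#' @export
simulate_mediation_data <- function(n, a = 0.5, b = 0.3, c_direct = 0.2,
                                    sd_m = 1, sd_y = 1, seed = 1) {
  stopifnot(n >= 4)
  set.seed(seed)
  x <- stats::rnorm(n)
  m <- a * x + stats::rnorm(n, 0, sd_m)
  y <- c_direct * x + b * m + stats::rnorm(n, 0, sd_y)
  tibble::tibble(x = x, m = m, y = y)
}
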