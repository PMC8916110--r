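#' Configuration for the full analysis pipeline
#'
#' Collects the file paths and stage settings of the end-to-end analysis:
#' per-subject proportional thresholding (default 50% retained, absolute
#' mode), univariate and covariate-adjusted regressions with the
#' Bonferroni family threshold (0.05 / 7 by default), the network-based
#' statistic on the networks that survive the age gate, and mediation of
#' the surviving subnetworks. One master seed derives every stage seed.
#'
#' @param cohort_csv Path to the cohort CSV.
#' @param matrix_dir Directory of per-subject matrix files.
#' @param parcellation_tsv Path to the parcellation TSV.
#' @param out_dir Output directory for result tables.
#' @param retained_proportion Proportion of edges retained per subject
#'   (default 0.5).
#' @param matrix_mode `"absolute"` (default) or `"signed"`.
#' @param alpha_family Family-wise alpha for the regression gate
#'   (default 0.05).
#' @param m_tests Number of tests in the Bonferroni family (default 7:
#'   four networks and three global measurements).
#' @param nbs An [nbs_config()] (its seed is overridden by a stage seed
#'   derived from `seed`).
#' @param n_boot Bootstrap iterations for mediation (default 10000).
#' @param split_age Last age (years) of the young stratum (default 63).
#' @param fwe_alpha Component-level significance level for carrying NBS
#'   subnetworks into mediation (default 0.05).
#' @param seed Master seed.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(cohort_csv, matrix_dir, parcellation_tsv, out_dir,
                            retained_proportion = 0.5,
                            matrix_mode = c("absolute", "signed"),
                            alpha_family = 0.05, m_tests = 7,
                            nbs = nbs_config(), n_boot = 10000,
                            split_age = 63, fwe_alpha = 0.05, seed = 1) {
  matrix_mode <- match.arg(matrix_mode)
  stopifnot(inherits(nbs, "nbs_config"))
  if (retained_proportion <= 0 || retained_proportion > 1) {
    stop("`retained_proportion` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(
    cohort_csv = cohort_csv, matrix_dir = matrix_dir,
    parcellation_tsv = parcellation_tsv, out_dir = out_dir,
    retained_proportion = retained_proportion, matrix_mode = matrix_mode,
    alpha_family = alpha_family, m_tests = m_tests,
    nbs = nbs, n_boot = n_boot, split_age = split_age,
    fwe_alpha = fwe_alpha, seed = seed
  ), class = "analysis_config")
}

#' Load and align the pipeline inputs
#'
#' Reads the cohort CSV, parcellation TSV and per-subject matrices, and
#' aligns subjects across the table and the matrix stack by subject id.
#' Subjects without a readable matrix are excluded with a message; matrix
#' files without a cohort row are an error.
#'
#' @param config An [analysis_config()].
#' @return A list with `cohort` (tibble, restricted to subjects with
#'   matrices), `matrices` (named list in cohort order), `parcellation`.
#' @export
load_inputs <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- read_cohort(config$cohort_csv)
  parcellation <- read_parcellation(config$parcellation_tsv)
  matrices <- read_connectome_matrices(config$matrix_dir, cohort$subject_id)
  cohort <- cohort[cohort$subject_id %in% names(matrices), , drop = FALSE]
  matrices <- matrices[cohort$subject_id]
  n_roi <- nrow(matrices[[1]])
  if (n_roi != nrow(parcellation)) {
    stop(sprintf("matrices have %d ROIs but the parcellation lists %d",
                 n_roi, nrow(parcellation)), call. = FALSE)
  }
  list(cohort = cohort, matrices = matrices, parcellation = parcellation)
}

#' Cohort summary table (medians, IQRs, percentages)
#'
#' Median and interquartile range per numeric variable and count /
#' percentage for binary variables, overall and within the young
#' (`age <= split_age`) and old (`age > split_age`) strata. Quantiles use
#' linear interpolation ([stats::quantile()] type 7).
#'
#' @param cohort Cohort tibble.
#' @param split_age Last age of the young stratum (default 63).
#' @return A tibble with columns `variable`, `stratum`, `n`, `median`,
#'   `iqr`, `count`, `percent`.
#' @export
cohort_summary <- function(cohort, split_age = 63) {
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  vars <- setdiff(names(cohort), "subject_id")
  vars <- vars[vapply(cohort[vars], is.numeric, logical(1))]
  strata <- list(
    overall = rep(TRUE, nrow(cohort)),
    young = cohort$age <= split_age,
    old = cohort$age > split_age
  )
  # a variable is binary when it takes both values of {0, 1} cohort-wide
  binary_vars <- vars[vapply(cohort[vars], function(x) {
    x <- x[is.finite(x)]
    length(unique(x)) == 2 && all(x %in% c(0, 1))
  }, logical(1))]
  purrr::map_dfr(names(strata), function(st) {
    sub <- cohort[strata[[st]], , drop = FALSE]
    purrr::map_dfr(vars, function(v) {
      x <- sub[[v]]
      x <- x[is.finite(x)]
      binary <- v %in% binary_vars
      tibble::tibble(
        variable = v, stratum = st, n = length(x),
        median = if (!binary && length(x)) stats::median(x) else NA_real_,
        iqr = if (!binary && length(x)) stats::IQR(x, type = 7) else NA_real_,
        count = if (binary) sum(x == 1) else NA_integer_,
        percent = if (binary && length(x)) 100 * mean(x == 1) else NA_real_
      )
    })
  })
}

# Per-subject FC outcome columns from the thresholded stack.
fc_outcome_table <- function(matrices, parcellation, networks) {
  purrr::map_dfr(matrices, function(m) {
    nm <- network_means(m, parcellation)
    row <- c(
      fc_global = nm$mean_fc[nm$scope == "global"],
      fc_within = nm$mean_fc[nm$scope == "within"],
      fc_between = nm$mean_fc[nm$scope == "between"]
    )
    for (net in networks) {
      row[paste0("fc_", net)] <- nm$mean_fc[nm$scope == "network" & nm$network == net]
    }
    tibble::as_tibble(as.list(row))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: load and align inputs; per-subject
#' proportional thresholding; per-subject global / within / between /
#' per-network mean FC; univariate age fits on all imaging and cognitive
#' measures; multiple regressions of each FC measure on age, cortical
#' thickness and PSMD adjusted for sex and education; the Bonferroni gate
#' (networks whose age effect misses `alpha_family / m_tests` are dropped
#' before the NBS); the network-based statistic (negative direction) on
#' the whole brain and each surviving network, on unthresholded
#' matrices; extraction of significant subnetworks and their per-subject
#' mean FC; mediation model one (thickness and PSMD mediating age ->
#' subnetwork FC) and model two (subnetwork FCs in parallel mediating
#' age -> TMTB and age -> TMTA). All stage seeds derive from the master
#' seed, and rerunning with the same configuration reproduces every
#' output byte for byte.
#'
#' @param config An [analysis_config()].
#' @return A `ResultsBundle`-style list (class `agefc_results`) with the
#'   cohort summary, regression tables, gate table, NBS results,
#'   mediation tables and a provenance block; tables are also written as
#'   TSV files under `config$out_dir`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  set.seed(config$seed)
  stage_seeds <- sample.int(1e8, 20)
  t0 <- Sys.time()
  log_stage <- function(fmt, ...) {
    message(sprintf("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                    sprintf(fmt, ...)))
  }

  inputs <- load_inputs(config)
  cohort <- inputs$cohort
  parcellation <- inputs$parcellation
  matrices <- inputs$matrices
  log_stage("loaded %d subjects, %d ROIs", nrow(cohort), nrow(parcellation))

  networks <- intersect(c("default", "dorsal_attention", "salience", "control"),
                        unique(parcellation$network))
  thresholded <- lapply(matrices, proportional_threshold,
                        proportion = config$retained_proportion,
                        mode = config$matrix_mode)
  fc <- fc_outcome_table(thresholded, parcellation, networks)
  data <- dplyr::bind_cols(cohort, fc)
  data$tmt_ratio <- tmt_ratio(data$tmtb, data$tmta)
  log_stage("thresholded at %.0f%% and computed FC outcomes",
            100 * config$retained_proportion)

  fc_outcomes <- c("fc_global", "fc_within", "fc_between", paste0("fc_", networks))
  uni_outcomes <- c("cortical_thickness", "psmd", fc_outcomes,
                    "tmta", "tmtb", "tmt_ratio")
  univariate <- purrr::map_dfr(uni_outcomes, function(oc) {
    univariate_fit(data, oc, "age")
  })
  mlr <- purrr::map_dfr(fc_outcomes, function(oc) {
    multiple_regression(data, oc, c("age", "cortical_thickness", "psmd"),
                        covariates = c("sex", "education"))
  })
  threshold <- bonferroni_alpha(config$alpha_family, config$m_tests)
  age_p <- mlr[mlr$term == "age", c("outcome", "p")]
  gate <- tibble::tibble(
    outcome = age_p$outcome,
    p_age = age_p$p,
    threshold = round(threshold, 3),
    survived = age_p$p <= threshold
  )
  surviving <- intersect(networks,
                         sub("^fc_", "", gate$outcome[gate$survived]))
  log_stage("Bonferroni gate at p <= %.3f: %d of %d networks survive",
            threshold, length(surviving), length(networks))

  # NBS on the whole brain and each surviving network (unthresholded input)
  scopes <- c("whole_brain", surviving)
  nbs_results <- list()
  subnet_fc <- list()
  nbs_components <- tibble::tibble()
  for (si in seq_along(scopes)) {
    scope <- scopes[si]
    if (scope == "whole_brain") {
      stack <- matrices
      node_map <- seq_len(nrow(parcellation))
    } else {
      nodes <- parcellation$roi_index[parcellation$network == scope]
      stack <- lapply(matrices, function(m) m[nodes, nodes, drop = FALSE])
      node_map <- nodes
    }
    cfg <- config$nbs
    cfg$seed <- stage_seeds[si]
    res <- nbs_test(stack, data$age, cfg)
    nbs_results[[scope]] <- res
    td <- generics::tidy(res)
    if (nrow(td)) {
      td$scope <- scope
      nbs_components <- dplyr::bind_rows(nbs_components, td)
    }
    sig <- Filter(function(cc) cc$fwe_p <= config$fwe_alpha, res$components)
    log_stage("NBS (%s): %d component(s), %d significant at FWE p <= %.2f",
              scope, length(res$components), length(sig), config$fwe_alpha)
    if (length(sig)) {
      comp <- sig[[1]]   # largest significant component
      mask_local <- component_edge_mask(comp)
      mask_global <- cbind(node_map[mask_local[, 1]], node_map[mask_local[, 2]])
      subnet_fc[[paste0("subnet_fc_", scope)]] <-
        subnetwork_mean_fc(matrices, mask_global)
      attr(nbs_results[[scope]], "edge_mask_global") <- mask_global
    }
  }
  for (nm in names(subnet_fc)) data[[nm]] <- subnet_fc[[nm]]

  # mediation model one: structural mediators of age -> subnetwork FC;
  # model two: subnetwork FCs mediating age -> TMT scores
  mediation_tbl <- tibble::tibble()
  med_fits <- list()
  if (length(subnet_fc) == 0) {
    log_stage("no significant NBS subnetwork: mediation stage skipped")
  } else {
    mi <- 0L
    run_model <- function(model, label, outcome) {
      fit <- tryCatch(
        bootstrap_mediation(data, model, n_boot = config$n_boot,
                            seed = stage_seeds[10 + mi]),
        error = function(e) {
          log_stage("mediation %s for %s skipped: %s", label, outcome,
                    conditionMessage(e))
          NULL
        }
      )
      if (!is.null(fit)) {
        med_fits[[paste(label, outcome, sep = "_")]] <<- fit
        td <- generics::tidy(fit)
        td$model <- label
        td$outcome <- outcome
        mediation_tbl <<- dplyr::bind_rows(mediation_tbl, td)
      }
    }
    for (nm in names(subnet_fc)) {
      mi <- mi + 1L
      run_model(mediation_model("age", c("cortical_thickness", "psmd"), nm),
                "model_one", nm)
    }
    # subnetworks that are numerically identical (the whole-brain component
    # can coincide with a network's) enter model two only once
    meds <- names(subnet_fc)
    if (length(meds) > 1) {
      keep <- rep(TRUE, length(meds))
      for (i in seq_along(meds)[-1]) {
        for (j in seq_len(i - 1)) {
          if (keep[j] &&
              abs(stats::cor(data[[meds[i]]], data[[meds[j]]])) > 1 - 1e-10) {
            keep[i] <- FALSE
            log_stage("mediator %s duplicates %s; dropped from model two",
                      meds[i], meds[j])
            break
          }
        }
      }
      meds <- meds[keep]
    }
    for (oc in c("tmtb", "tmta")) {
      mi <- mi + 1L
      run_model(mediation_model("age", meds, oc), "model_two", oc)
    }
    log_stage("mediation: %d model(s) with %d bootstrap iterations",
              length(med_fits), config$n_boot)
  }

  summary_tbl <- cohort_summary(cohort, config$split_age)
  provenance <- tibble::tibble(
    key = c("package_version", "master_seed", "n_subjects", "n_rois",
            "retained_proportion", "matrix_mode", "bonferroni_threshold",
            "nbs_t_threshold", "nbs_n_permutations", "nbs_direction",
            "mediation_n_boot", "config_hash"),
    value = c(as.character(utils::packageVersion("agefc")),
              as.character(config$seed),
              as.character(nrow(cohort)), as.character(nrow(parcellation)),
              as.character(config$retained_proportion), config$matrix_mode,
              as.character(round(threshold, 3)),
              as.character(config$nbs$t_threshold),
              as.character(config$nbs$n_permutations),
              config$nbs$direction,
              as.character(config$n_boot),
              config_hash(config))
  )

  bundle <- structure(list(
    cohort_summary = summary_tbl,
    univariate = univariate,
    mlr = mlr,
    gate = gate,
    nbs = nbs_results,
    nbs_components = nbs_components,
    mediation = mediation_tbl,
    mediation_fits = med_fits,
    data = data,
    provenance = provenance
  ), class = "agefc_results")

  write_results_bundle(bundle, config$out_dir)
  log_stage("wrote result tables to %s", config$out_dir)
  invisible(bundle)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  # the output location is not part of the analysis
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

write_results_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) readr::write_tsv(x, file.path(out_dir, name))
  w(bundle$cohort_summary, "cohort_summary.tsv")
  w(bundle$univariate, "univariate.tsv")
  w(bundle$mlr, "mlr.tsv")
  w(bundle$gate, "gate.tsv")
  if (nrow(bundle$nbs_components)) w(bundle$nbs_components, "nbs_components.tsv")
  for (scope in names(bundle$nbs)) {
    res <- bundle$nbs[[scope]]
    writeLines(as.character(res$null_max_sizes),
               file.path(out_dir, paste0("nbs_", scope, "_null.txt")))
    if (length(res$components)) {
      comp <- res$components[[1]]
      w(comp$edges, paste0("nbs_", scope, "_edges.tsv"))
      w(node_degree_table(comp), paste0("nbs_", scope, "_degrees.tsv"))
    }
  }
  if (nrow(bundle$mediation)) {
    med <- bundle$mediation
    med <- med[, c("model", "outcome", "effect", "mediator", "estimate",
                   "se", "std_estimate", "p", "ci_low", "ci_high")]
    names(med)[names(med) == "std_estimate"] <- "std_beta"
    w(med, "mediation.tsv")
  }
  w(bundle$provenance, "provenance.tsv")
  invisible(out_dir)
}

#' @export
print.agefc_results <- function(x, ...) {
  cat("agefc results bundle\n")
  cat(sprintf("  subjects: %s, gate: %d/%d FC measures survive\n",
              x$provenance$value[x$provenance$key == "n_subjects"],
              sum(x$gate$survived), nrow(x$gate)))
  cat(sprintf("  NBS scopes: %s\n", paste(names(x$nbs), collapse = ", ")))
  cat(sprintf("  mediation rows: %d\n", nrow(x$mediation)))
  invisible(x)
}
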