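test_that("generator configuration rejects invalid fields by name", {
  expect_error(generator_config(n_subjects = 2), "n_subjects")
  expect_error(generator_config(n_rois = 3), "n_rois")
  expect_error(generator_config(female_fraction = 1.2), "female_fraction")
  expect_error(generator_config(age_min = 80, age_max = 70), "age_min")
  expect_error(generator_config(target_r_age_psmd = 1.5), "target_r_age_psmd")
  expect_error(generator_config(edge_noise_sd = -1), "edge_noise_sd")
})

test_that("cohort generation is deterministic and hits its marginals", {
  cfg <- generator_config(n_subjects = 976, n_rois = 20, seed = 42)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  expect_identical(co1, co2)

  expect_true(all(co1$age >= 45 & co1$age <= 74))
  expect_true(all(co1$age == round(co1$age)))
  expect_true(all(co1$sex %in% c(0, 1)))
  expect_true(all(co1$tmta >= 5 & co1$tmtb >= 5))

  # Fisher-z 3-sigma band: 3 / sqrt(n - 3) ~ 0.096 at n = 976
  band <- 3 / sqrt(976 - 3)
  expect_lt(abs(cor(co1$age, co1$cortical_thickness) - (-0.4)), band + 0.01)
  expect_lt(abs(cor(co1$age, co1$psmd) - 0.5), band + 0.01)
  expect_lt(abs(cor(co1$age, co1$tmtb) - 0.3), band + 0.01)
})

test_that("zero correlation targets give near-independent variables", {
  cfg <- generator_config(
    n_subjects = 976, n_rois = 20, seed = 7,
    target_r_age_thickness = 0, target_r_age_psmd = 0, target_r_age_tmtb = 0
  )
  co <- generate_cohort(cfg)
  for (v in c("cortical_thickness", "psmd", "tmta", "tmtb")) {
    expect_lt(abs(cor(co$age, co[[v]])), 0.1)
  }
})

test_that("connectome stacks are valid, calibrated and deterministic", {
  cfg <- generator_config(n_subjects = 200, n_rois = 40, seed = 3)
  co <- generate_cohort(cfg)
  gen1 <- generate_connectomes(cfg, co)
  gen2 <- generate_connectomes(cfg, co)
  expect_identical(gen1$matrices, gen2$matrices)
  expect_identical(gen1$ground_truth, gen2$ground_truth)

  m <- gen1$matrices[[1]]
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(0, 40))
  off <- m[upper.tri(m)]
  expect_true(all(off >= 0.01 & off <= 0.99))

  grand <- mean(vapply(gen1$matrices, function(x) mean(x[upper.tri(x)]),
                       numeric(1)))
  expect_lt(abs(grand - cfg$baseline_fc_mean), 0.02)

  expect_error(generate_connectomes(cfg, co[1:10, ]), "rows")
})

test_that("planted edges recover the configured marginal slope", {
  cfg <- generator_config(n_subjects = 600, n_rois = 40, seed = 9,
                          planted_edge_fraction = 0.3)
  co <- generate_cohort(cfg)
  gen <- generate_connectomes(cfg, co)
  gt <- gen$ground_truth
  expect_gt(nrow(gt), 0)
  # planted mask lives in the upper triangle of the default network
  expect_true(all(gt$node_i < gt$node_j))
  default_rois <- gen$parcellation$roi_index[gen$parcellation$network == "default"]
  expect_true(all(c(gt$node_i, gt$node_j) %in% default_rois))

  for (k in seq_len(min(3, nrow(gt)))) {
    edge <- vapply(gen$matrices, function(m) m[gt$node_i[k], gt$node_j[k]],
                   numeric(1))
    fit <- summary(lm(edge ~ gen$cohort$age))$coefficients
    expect_lt(abs(fit[2, "Estimate"] - gt$true_slope[k]),
              3 * fit[2, "Std. Error"])
  }
})

test_that("unplanted edge t statistics follow a central t distribution", {
  cfg <- generator_config(n_subjects = 120, n_rois = 20, seed = 21,
                          planted_edge_fraction = 0)
  co <- generate_cohort(cfg)
  gen <- generate_connectomes(cfg, co)
  expect_equal(nrow(gen$ground_truth), 0)
  tmap <- edge_statistics(gen$matrices, gen$cohort$age)
  tvals <- tmap[upper.tri(tmap)]
  ks <- ks.test(tvals, "pt", df = attr(tmap, "df"))
  expect_gt(ks$p.value, 0.01)
})

test_that("time-series generation converges to its target correlation", {
  target <- random_corr_matrix(6, seed = 2)
  ts1 <- generate_timeseries(target, 125, seed = 4)
  ts2 <- generate_timeseries(target, 125, seed = 4)
  expect_identical(ts1, ts2)
  expect_equal(dim(ts1), c(6, 125))

  # null target: off-diagonal sample correlations stay inside the T=125 band
  id_ts <- generate_timeseries(diag(8), 125, seed = 5)
  r <- cor(t(id_ts))
  expect_lt(max(abs(r[upper.tri(r)])), 0.35)

  # long series: correlations converge to the target
  long <- generate_timeseries(target, 10000, seed = 6)
  expect_lt(max(abs(cor(t(long)) - target)), 0.05)

  expect_error(generate_timeseries(target, 1), "n_timepoints")
  bad <- matrix(1, 3, 3)   # rank-1: zero eigenvalues
  expect_error(generate_timeseries(bad, 125), "eigenvalue")
})

test_that("cohort and matrix writers round-trip through disk", {
  cfg <- generator_config(n_subjects = 12, n_rois = 10, seed = 8)
  co <- generate_cohort(cfg)
  gen <- generate_connectomes(cfg, co)
  dir <- withr::local_tempdir()
  write_cohort(gen$cohort, file.path(dir, "cohort.csv"))
  back <- read_cohort(file.path(dir, "cohort.csv"))
  expect_equal(as.data.frame(back),
               as.data.frame(gen$cohort[names(back)]), tolerance = 1e-12)

  write_connectome_matrices(gen$matrices, file.path(dir, "mats"))
  mats <- read_connectome_matrices(file.path(dir, "mats"), co$subject_id)
  expect_equal(mats[[3]], unclass(gen$matrices[[3]]),
               ignore_attr = TRUE, tolerance = 1e-12)

  write_parcellation(gen$parcellation, file.path(dir, "parc.tsv"))
  expect_equal(read_parcellation(file.path(dir, "parc.tsv")),
               gen$parcellation)
})
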