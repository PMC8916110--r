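test_that("correlation_matrix matches the Pearson formula and handles signs", {
  set.seed(1)
  ts <- matrix(rnorm(15), 3, 5)   # 3 ROIs, 5 timepoints
  m <- correlation_matrix(ts, mode = "signed")
  for (i in 1:2) for (j in (i + 1):3) {
    xi <- ts[i, ] - mean(ts[i, ]); xj <- ts[j, ] - mean(ts[j, ])
    expect_equal(m[i, j], sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2)),
                 tolerance = 1e-12)
  }

  dup <- rbind(ts[1, ], ts[1, ], ts[2, ])
  expect_equal(correlation_matrix(dup)[1, 2], 1)
  anti <- rbind(ts[1, ], -ts[1, ])
  expect_equal(correlation_matrix(anti, "absolute")[1, 2], 1)
  expect_equal(correlation_matrix(anti, "signed")[1, 2], -1)

  expect_error(correlation_matrix(ts[, 1:2]), "timepoints")
  const <- ts; const[2, ] <- 1
  expect_error(correlation_matrix(const), "ROI 2")
})

test_that("correlation matrices are symmetric with zero diagonal", {
  for (seed in 1:5) {
    set.seed(seed)
    ts <- matrix(rnorm(8 * 30), 8, 30)
    m <- correlation_matrix(ts, mode = sample(c("absolute", "signed"), 1))
    expect_equal(m, t(m))
    expect_equal(diag(m), rep(0, 8))
  }
})

test_that("proportional thresholding retains exactly the strongest k edges", {
  w <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- c(0.9, 0.8, 0.3, 0.7, 0.2, 0.1)  # column-major fill
  m <- m + t(m)
  thr <- proportional_threshold(m, 0.5)
  kept <- sort(thr[upper.tri(thr)][thr[upper.tri(thr)] != 0], decreasing = TRUE)
  expect_equal(kept, c(0.9, 0.8, 0.7))

  # proportion 1 leaves the matrix unchanged (diagonal already zero)
  expect_equal(proportional_threshold(m, 1), m, ignore_attr = TRUE)

  # all-equal weights: the tie-break still retains exactly k edges
  eq <- matrix(0.5, 5, 5); diag(eq) <- 0
  thr_eq <- proportional_threshold(eq, 0.5)
  expect_equal(sum(thr_eq[upper.tri(thr_eq)] != 0), round(0.5 * 10))

  expect_error(proportional_threshold(m, 0), "proportion")
  expect_error(proportional_threshold(m, 1.2), "proportion")
})

test_that("signed-mode thresholding ranks by magnitude", {
  m <- matrix(0, 3, 3)
  m[upper.tri(m)] <- c(-0.9, 0.5, 0.1)
  m <- m + t(m)
  thr <- proportional_threshold(m, 1 / 3, mode = "signed")
  expect_equal(sum(thr != 0) / 2, 1)
  expect_equal(thr[1, 2], -0.9)   # strongest by magnitude survives
})

test_that("retained edge sets are exact and nested across proportions", {
  for (seed in 1:3) {
    m <- random_weight_matrix(12, seed = seed)
    E <- 12 * 11 / 2
    prev <- NULL
    for (p in c(0.1, 0.3, 0.5, 0.7)) {
      thr <- proportional_threshold(m, p)
      kept <- which(thr[upper.tri(thr)] != 0)
      expect_length(kept, round(p * E))
      if (!is.null(prev)) expect_true(all(prev %in% kept))
      prev <- kept
    }
    # re-thresholding at a smaller proportion equals thresholding once
    once <- proportional_threshold(m, 0.3)
    twice <- proportional_threshold(proportional_threshold(m, 0.7), 0.3)
    expect_equal(once, twice, ignore_attr = TRUE)
  }
})

test_that("mean connectivity averages retained edges only", {
  m <- matrix(0, 4, 4)
  m[upper.tri(m)] <- c(0.9, 0.8, 0.3, 0.7, 0.2, 0.1)
  m <- m + t(m)
  thr <- proportional_threshold(m, 0.5)
  expect_equal(mean_connectivity(thr), (0.9 + 0.8 + 0.7) / 3)

  const <- matrix(0.4, 5, 5); diag(const) <- 0
  expect_equal(mean_connectivity(const), 0.4)

  empty <- matrix(0, 4, 4)
  expect_error(mean_connectivity(empty), "undefined")

  # mask restricts the mean to the named edges
  mask <- rbind(c(1, 2))
  expect_equal(mean_connectivity(m, mask), m[1, 2])
})

test_that("network means split within and between edges correctly", {
  parc <- tibble::tibble(roi_index = 1:4,
                         roi_name = paste0("R", 1:4),
                         network = c("a", "a", "b", "b"))
  m <- matrix(0.2, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.6
  m[3, 4] <- m[4, 3] <- 0.6
  diag(m) <- 0
  nm <- network_means(m, parc)
  expect_equal(nm$mean_fc[nm$scope == "within"], 0.6)
  expect_equal(nm$mean_fc[nm$scope == "between"], 0.2)
  expect_equal(nm$mean_fc[nm$scope == "network" & nm$network == "a"], 0.6)

  # constant matrix: all means coincide
  const <- matrix(0.4, 4, 4); diag(const) <- 0
  nmc <- network_means(const, parc)
  expect_true(all(abs(nmc$mean_fc - 0.4) < 1e-12))

  # single-ROI network flagged undefined, other rows still computed
  parc2 <- parc; parc2$network <- c("a", "a", "a", "solo")
  nm2 <- network_means(const, parc2)
  solo <- nm2[nm2$scope == "network" & nm2$network == "solo", ]
  expect_false(solo$defined)
  expect_true(nm2$defined[nm2$scope == "global"])
})

test_that("group difference maps subtract old from young entrywise", {
  base <- random_weight_matrix(5, seed = 4)
  young <- list(base, base)
  oldm <- base; oldm[2, 4] <- oldm[4, 2] <- base[2, 4] + 0.3
  old <- list(oldm, oldm)
  d <- group_difference_map(c(young, old), c("young", "young", "old", "old"))
  expect_equal(d[2, 4], -0.3)
  d0 <- group_difference_map(c(young, young), c("young", "young", "old", "old"))
  expect_equal(d0, matrix(0, 5, 5))
  # singleton groups reduce to a plain difference
  d1 <- group_difference_map(list(base, oldm), c("young", "old"))
  expect_equal(d1[2, 4], -0.3)
  expect_error(group_difference_map(young, c("young", "young")), "non-empty")
})

test_that("psmd is the 95th minus 5th percentile with interpolation", {
  expect_equal(psmd(rep(3e-4, 10)), 0)
  grid <- seq(0, 0.001, by = 0.00001)   # 101 values
  expect_equal(psmd(grid), 0.0009, tolerance = 1e-12)
  expect_error(psmd(c(1e-4, NaN, 3e-4)), "non-finite")
  expect_error(psmd(2e-4), "two values")

  # translation invariance and positive-scale equivariance
  set.seed(2)
  x <- runif(50)
  expect_equal(psmd(x + 5), psmd(x), tolerance = 1e-12)
  expect_equal(psmd(3 * x), 3 * psmd(x), tolerance = 1e-12)
})

test_that("the TMT ratio divides B by A with guards", {
  expect_equal(tmt_ratio(79, 36), 79 / 36)
  expect_equal(tmt_ratio(42, 42), 1)
  expect_error(tmt_ratio(79, 0), "positive")
  expect_equal(tmt_ratio(c(80, 60), c(40, 30)), c(2, 2))
})
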