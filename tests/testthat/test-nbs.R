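# Build a stack whose edges are pure noise except an optional planted
# linear effect of the predictor on chosen edges.
make_stack <- function(n_subj, n_roi, seed, planted = NULL, slope = 0,
                       noise_sd = 1) {
  set.seed(seed)
  x <- rnorm(n_subj)
  E <- n_roi * (n_roi - 1) / 2
  vals <- matrix(rnorm(n_subj * E, sd = noise_sd), n_subj, E)
  if (!is.null(planted)) {
    pos <- agefc:::edge_positions(planted, n_roi)
    vals[, pos] <- vals[, pos] + slope * x
  }
  stack <- lapply(seq_len(n_subj), function(s)
    agefc:::edge_vector_to_matrix(vals[s, ], n_roi))
  list(stack = stack, x = x)
}

test_that("edge statistics match per-edge lm t values", {
  d <- make_stack(30, 6, seed = 1)
  tmap <- edge_statistics(d$stack, d$x)
  for (pair in list(c(1, 2), c(2, 5), c(3, 6))) {
    edge <- vapply(d$stack, function(m) m[pair[1], pair[2]], numeric(1))
    tref <- summary(lm(edge ~ d$x))$coefficients[2, "t value"]
    expect_equal(tmap[pair[1], pair[2]], tref, tolerance = 1e-8)
  }
  # covariate-adjusted model
  z <- rnorm(30)
  tmap_z <- edge_statistics(d$stack, d$x, covariates = data.frame(z = z))
  edge <- vapply(d$stack, function(m) m[1, 2], numeric(1))
  tref <- summary(lm(edge ~ d$x + z))$coefficients[2, "t value"]
  expect_equal(tmap_z[1, 2], tref, tolerance = 1e-8)
})

test_that("edge statistics handle degenerate and permuted input", {
  d <- make_stack(25, 5, seed = 2)
  # perfect-fit edge is capped at the sentinel
  perfect <- lapply(seq_along(d$stack), function(s) {
    m <- d$stack[[s]]; m[1, 2] <- m[2, 1] <- 2 * d$x[s]; m
  })
  tmap <- edge_statistics(perfect, d$x)
  expect_equal(abs(tmap[1, 2]), 1e6)

  # constant edge excluded with a message
  const <- lapply(d$stack, function(m) { m[1, 3] <- m[3, 1] <- 0.5; m })
  expect_message(tmap_c <- edge_statistics(const, d$x), "constant")
  expect_true(is.na(tmap_c[1, 3]))

  # relabeling subjects together with the predictor changes nothing
  perm <- sample(25)
  t1 <- edge_statistics(d$stack, d$x)
  t2 <- edge_statistics(d$stack[perm], d$x[perm])
  expect_equal(t1, t2, tolerance = 1e-12)

  expect_error(edge_statistics(d$stack, rep(1, 25)), "constant")
})

test_that("suprathreshold component extraction handles toy graphs", {
  n <- 8
  tmap <- matrix(0, n, n)
  set_t <- function(i, j, v) tmap[c(i, j), c(j, i)][1] # helper unused
  put <- function(i, j, v) { tmap[i, j] <<- v; tmap[j, i] <<- v }

  expect_identical(suprathreshold_components(tmap, 3.2, "negative"), list())

  # two vertex-disjoint triangles below -3.2
  for (e in list(c(1, 2), c(2, 3), c(1, 3))) put(e[1], e[2], -4)
  for (e in list(c(4, 5), c(5, 6), c(4, 6))) put(e[1], e[2], -5)
  comps <- suprathreshold_components(tmap, 3.2, "negative")
  expect_length(comps, 2)
  expect_equal(vapply(comps, `[[`, integer(1), "size"), c(3L, 3L))

  # positive direction finds nothing here
  expect_length(suprathreshold_components(tmap, 3.2, "positive"), 0)

  # path a-b-c: sizes and degrees
  tpath <- matrix(0, 5, 5)
  tpath[1, 2] <- tpath[2, 1] <- 4.1
  tpath[2, 3] <- tpath[3, 2] <- 3.9
  cp <- suprathreshold_components(tpath, 3.2, "positive")
  expect_length(cp, 1)
  expect_equal(cp[[1]]$size, 2L)
  expect_equal(cp[[1]]$nodes, c(1L, 2L, 3L))
  expect_equal(unname(cp[[1]]$degrees), c(1L, 2L, 1L))
  expect_equal(sum(cp[[1]]$degrees), 2L * cp[[1]]$size)
})

test_that("component extraction agrees with a depth-first-search oracle", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(5:30, 1)
    tmap <- matrix(0, n, n)
    density <- runif(1, 0.02, 0.3)
    ut <- which(upper.tri(tmap))
    sel <- ut[runif(length(ut)) < density]
    tmap[sel] <- -runif(length(sel), 3.3, 8)
    tmap <- pmin(tmap, t(tmap))
    comps <- suprathreshold_components(tmap, 3.2, "negative")
    pairs <- which(tmap < -3.2 & upper.tri(tmap), arr.ind = TRUE)
    oracle <- dfs_components(pairs)
    expect_length(comps, length(oracle))
    if (length(comps)) {
      expect_equal(lapply(comps, function(cc) list(nodes = cc$nodes,
                                                   n_edges = cc$size)),
                   lapply(oracle, function(cc) list(nodes = as.integer(cc$nodes),
                                                    n_edges = as.integer(cc$n_edges))))
    }
  }
})

test_that("nbs_test is deterministic and controls the boundary cases", {
  planted <- cbind(c(1, 2, 3, 1), c(2, 3, 4, 3))
  d <- make_stack(80, 10, seed = 5, planted = planted, slope = 1.2)
  cfg <- nbs_config(n_permutations = 200, seed = 9)
  r1 <- nbs_test(d$stack, d$x, cfg)
  r2 <- nbs_test(d$stack, d$x, cfg)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(r1$null_max_sizes, r2$null_max_sizes)

  # planted effect is negative-direction: slope positive -> test positive tail
  cfg_pos <- nbs_config(direction = "positive", n_permutations = 200, seed = 9)
  rp <- nbs_test(d$stack, d$x, cfg_pos)
  expect_gte(length(rp$components), 1)
  expect_true(all(planted[, 1] %in% rp$components[[1]]$nodes))

  # observed larger than every null max gives fwe_p = 0 under the plain rule
  if (rp$components[[1]]$size > max(rp$null_max_sizes)) {
    expect_equal(rp$components[[1]]$fwe_p, 0)
  }
  # the (k+1)/(B+1) variant never returns exactly zero
  cfg_p1 <- nbs_config(direction = "positive", n_permutations = 200, seed = 9,
                       p_variant = "plus_one")
  rp1 <- nbs_test(d$stack, d$x, cfg_p1)
  expect_gt(rp1$components[[1]]$fwe_p, 0)

  # fwe_p depends on the null distribution only as a multiset
  comp <- rp$components[[1]]
  expect_equal(comp$fwe_p, mean(sample(comp$null_max_sizes) >= comp$size))
})

test_that("raising the primary threshold never grows a component", {
  d <- make_stack(60, 12, seed = 6,
                  planted = cbind(1:4, 2:5), slope = 0.8)
  t_map <- edge_statistics(d$stack, d$x)
  sizes <- vapply(c(2.0, 2.5, 3.0, 3.5), function(thr) {
    comps <- suprathreshold_components(t_map, thr, "positive")
    if (length(comps)) comps[[1]]$size else 0L
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("component masks feed per-subject subnetwork connectivity", {
  const <- lapply(1:4, function(s) {
    m <- matrix(0.5, 6, 6); diag(m) <- 0; m
  })
  comp <- list(edges = tibble::tibble(node_i = c(1L, 2L, 1L),
                                      node_j = c(2L, 3L, 3L),
                                      t = c(-4, -4, -4)),
               nodes = 1:3,
               degrees = stats::setNames(c(2L, 2L, 2L), 1:3),
               size = 3L)
  mask <- component_edge_mask(comp)
  expect_equal(subnetwork_mean_fc(const, mask), rep(0.5, 4))

  single <- mask[1, , drop = FALSE]
  vals <- vapply(const, function(m) m[1, 2], numeric(1))
  expect_equal(subnetwork_mean_fc(const, single), vals)

  deg <- node_degree_table(comp)
  expect_equal(deg$degree, c(2L, 2L, 2L))

  # star graph degrees
  star <- list(edges = tibble::tibble(node_i = rep(1L, 4), node_j = 2:5,
                                      t = rep(-4, 4)),
               nodes = 1:5,
               degrees = stats::setNames(c(4L, 1L, 1L, 1L, 1L), 1:5),
               size = 4L)
  expect_equal(node_degree_table(star)$degree, c(4L, 1L, 1L, 1L, 1L))

  expect_error(component_edge_mask(list(edges = tibble::tibble())), "empty")
})

test_that("covariate-adjusted NBS runs with Freedman-Lane permutation", {
  d <- make_stack(50, 8, seed = 12, planted = cbind(c(1, 2), c(2, 3)),
                  slope = -1.5)
  z <- data.frame(z1 = rnorm(50), z2 = rbinom(50, 1, 0.5))
  cfg <- nbs_config(n_permutations = 100, seed = 2, include_covariates = TRUE)
  res <- nbs_test(d$stack, d$x, cfg, covariates = z)
  expect_s3_class(res, "nbs_result")
  expect_length(res$null_max_sizes, 100)
  res2 <- nbs_test(d$stack, d$x, cfg, covariates = z)
  expect_identical(res$null_max_sizes, res2$null_max_sizes)
})
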