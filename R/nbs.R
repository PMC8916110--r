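#' Configuration for the network-based statistic
#'
#' @param t_threshold Primary edge-level test-statistic cutoff (default
#'   3.2, which at large residual degrees of freedom corresponds to a
#'   one-sided tail probability of about 0.0007).
#' @param n_permutations Number of permutations for the null distribution
#'   of the maximal component size (default 5000).
#' @param direction `"negative"` tests for edges whose connectivity
#'   decreases with the predictor (t < -threshold, the primary aging
#'   test); `"positive"` tests the opposite tail.
#' @param include_covariates Adjust each edge model for covariates; when
#'   on, permutation uses the Freedman-Lane residual scheme.
#' @param seed Integer seed; results are deterministic given the seed.
#' @param size_metric Component size metric; only `"edge_count"` (extent)
#'   is implemented.
#' @param p_variant `"proportion"` computes the FWE p as the plain
#'   proportion of null maxima at least as large as the observed size;
#'   `"plus_one"` uses (k + 1) / (B + 1).
#' @return An `nbs_config` list.
#' @export
nbs_config <- function(t_threshold = 3.2, n_permutations = 5000,
                       direction = c("negative", "positive"),
                       include_covariates = FALSE, seed = 1,
                       size_metric = "edge_count",
                       p_variant = c("proportion", "plus_one")) {
  direction <- match.arg(direction)
  p_variant <- match.arg(p_variant)
  if (!is.numeric(t_threshold) || t_threshold <= 0) {
    stop("`t_threshold` must be positive", call. = FALSE)
  }
  if (!is.numeric(n_permutations) || n_permutations < 1) {
    stop("`n_permutations` must be at least 1", call. = FALSE)
  }
  if (!identical(size_metric, "edge_count")) {
    stop("only the edge-count (extent) size metric is implemented", call. = FALSE)
  }
  structure(list(
    t_threshold = t_threshold,
    n_permutations = as.integer(n_permutations),
    direction = direction,
    include_covariates = include_covariates,
    seed = seed, size_metric = size_metric, p_variant = p_variant
  ), class = "nbs_config")
}

# Sentinel for perfect-fit edges whose t statistic is unbounded; above
# any plausible finite threshold.
T_SENTINEL <- 1e6

# Normalize columns of a matrix to zero mean / unit norm after optional
# residualization on a design (intercept + covariates). Zero-variance
# columns get norm NA.
normalize_cols <- function(M, Q = NULL) {
  if (is.null(Q)) {
    M <- sweep(M, 2, colMeans(M))
  } else {
    M <- M - Q %*% crossprod(Q, M)
  }
  nrm <- sqrt(colSums(M^2))
  nrm[nrm < 1e-12] <- NA_real_
  list(M = sweep(M, 2, nrm, "/"), norm = nrm)
}

r_to_t <- function(r, df) {
  denom <- 1 - r^2
  t <- r * sqrt(df) / sqrt(pmax(denom, 0))
  capped <- is.finite(r) & denom < 1e-12
  t[capped] <- sign(r[capped]) * T_SENTINEL
  t
}

#' Edge-wise t statistics of a predictor across a connectome stack
#'
#' For every upper-triangle edge, the t statistic of the predictor's
#' slope in a per-edge linear model of edge weight on the predictor
#' (simple regression by default; adjusted for `covariates` when given).
#' Edges that are constant across subjects have no defined statistic and
#' are excluded (`NA` in the map, indices recorded in the
#' `excluded_edges` attribute, with a message). Perfect-fit edges are
#' capped at a large sentinel (1e6) above any finite threshold.
#'
#' @param stack List of per-subject connectivity matrices (or an
#'   n x n x S array), one per subject.
#' @param predictor Numeric vector, one value per subject (e.g. age).
#' @param covariates Optional numeric matrix or data frame of adjustment
#'   covariates.
#' @return A symmetric matrix of t values (diagonal 0, excluded edges
#'   `NA`) with attributes `df` and `excluded_edges`.
#' @export
edge_statistics <- function(stack, predictor, covariates = NULL) {
  Y <- stack_to_edge_matrix(stack)
  n_rois <- attr(Y, "n_rois")
  n <- nrow(Y)
  if (length(predictor) != n) {
    stop("`predictor` must have one value per subject", call. = FALSE)
  }
  if (n < 3) stop("at least 3 subjects are required", call. = FALSE)
  if (stats::sd(predictor) == 0) stop("`predictor` is constant", call. = FALSE)
  Z <- prepare_covariates(covariates, n)
  Q <- if (is.null(Z)) NULL else qr.Q(qr(cbind(1, Z)))
  df <- n - 2 - (if (is.null(Z)) 0 else ncol(Z))
  if (df < 1) stop("not enough subjects for the covariate-adjusted model", call. = FALSE)

  xn <- normalize_cols(matrix(predictor, ncol = 1), Q)$M[, 1]
  yn <- normalize_cols(Y, Q)
  r <- as.vector(crossprod(yn$M, xn))
  t <- r_to_t(r, df)
  excluded <- which(is.na(yn$norm))
  if (length(excluded)) {
    message(sprintf("excluded %d constant edge(s) from the t map", length(excluded)))
  }
  tmap <- edge_vector_to_matrix(ifelse(is.na(t), 0, t), n_rois)
  tmap[edge_vector_to_matrix(as.numeric(is.na(t)), n_rois) > 0] <- NA
  attr(tmap, "df") <- df
  attr(tmap, "excluded_edges") <- excluded
  tmap
}

prepare_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  Z <- as.matrix(as.data.frame(covariates))
  if (nrow(Z) != n) stop("covariates must have one row per subject", call. = FALSE)
  storage.mode(Z) <- "double"
  Z
}

# Edge-count sizes of the connected components induced by a set of edges
# (2-column matrix). Returns an integer vector of component edge counts.
component_edge_counts <- function(pairs) {
  if (nrow(pairs) == 0) return(integer(0))
  if (nrow(pairs) == 1) return(1L)
  g <- igraph::graph_from_edgelist(cbind(as.character(pairs[, 1]),
                                         as.character(pairs[, 2])),
                                   directed = FALSE)
  memb <- igraph::components(g)$membership
  as.integer(table(memb[as.character(pairs[, 1])]))
}

#' Connected components of suprathreshold edges
#'
#' Keeps the edges whose t statistic exceeds the primary threshold in the
#' tested direction (t > threshold for `"positive"`, t < -threshold for
#' `"negative"`) and returns the connected components of the resulting
#' graph. An empty result is valid.
#'
#' @param t_map Symmetric edge t-statistic matrix (as from
#'   [edge_statistics()]).
#' @param t_threshold Positive primary threshold.
#' @param direction `"negative"` or `"positive"`.
#' @return A list of components, largest first; each is a list with
#'   `edges` (tibble `node_i`, `node_j`, `t`), `nodes` (sorted integer
#'   vector), `degrees` (named integer vector) and `size` (edge count).
#' @export
suprathreshold_components <- function(t_map, t_threshold,
                                      direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  check_symmetric(t_map, what = "`t_map`")
  n <- nrow(t_map)
  edges <- edge_index_table(n)
  t <- t_map[cbind(edges$node_i, edges$node_j)]
  sel <- if (direction == "positive") !is.na(t) & t > t_threshold
         else !is.na(t) & t < -t_threshold
  if (!any(sel)) return(list())
  pairs <- cbind(edges$node_i[sel], edges$node_j[sel])
  tv <- t[sel]
  g <- igraph::graph_from_edgelist(cbind(as.character(pairs[, 1]),
                                         as.character(pairs[, 2])),
                                   directed = FALSE)
  memb <- igraph::components(g)$membership
  edge_comp <- memb[as.character(pairs[, 1])]
  comps <- lapply(sort(unique(edge_comp)), function(cid) {
    in_c <- edge_comp == cid
    e <- tibble::tibble(node_i = pairs[in_c, 1], node_j = pairs[in_c, 2],
                        t = tv[in_c])
    nodes <- sort(unique(c(e$node_i, e$node_j)))
    degs <- table(factor(c(e$node_i, e$node_j), levels = nodes))
    structure(list(
      edges = e,
      nodes = nodes,
      degrees = stats::setNames(as.integer(degs), nodes),
      size = nrow(e)
    ), class = "nbs_component")
  })
  ord <- order(-vapply(comps, `[[`, integer(1), "size"),
               vapply(comps, function(cc) min(cc$nodes), integer(1)))
  comps[ord]
}

#' Network-based statistic with permutation FWE control
#'
#' Runs the NBS: edge-wise t statistics of the predictor, suprathreshold
#' connected components in the tested direction, and a permutation null
#' distribution of the maximal component size obtained by permuting the
#' predictor across subjects (`n_permutations` times). Each observed
#' component receives a family-wise-error-corrected p-value: the
#' proportion of permutations whose maximal component size is at least
#' the observed size. With covariates, permutation follows the
#' Freedman-Lane scheme (residuals of the reduced covariate-only model
#' are permuted).
#'
#' @param stack List of per-subject connectivity matrices (or an
#'   n x n x S array).
#' @param predictor Numeric vector, one value per subject.
#' @param config An [nbs_config()].
#' @param covariates Optional covariates, used when
#'   `config$include_covariates` is `TRUE`.
#' @return An object of class `nbs_result`: a list with `components`
#'   (each as in [suprathreshold_components()], plus `fwe_p`), `t_map`,
#'   `null_max_sizes` (length `n_permutations`), `config`, `n_subjects`.
#' @export
nbs_test <- function(stack, predictor, config = nbs_config(), covariates = NULL) {
  stopifnot(inherits(config, "nbs_config"))
  Y <- stack_to_edge_matrix(stack)
  n_rois <- attr(Y, "n_rois")
  n <- nrow(Y)
  if (length(predictor) != n) {
    stop("`predictor` must have one value per subject", call. = FALSE)
  }
  if (stats::sd(predictor) == 0) stop("`predictor` is constant", call. = FALSE)
  use_cov <- config$include_covariates && !is.null(covariates)
  Z <- if (use_cov) prepare_covariates(covariates, n) else NULL
  Q <- if (is.null(Z)) NULL else qr.Q(qr(cbind(1, Z)))
  df <- n - 2 - (if (is.null(Z)) 0 else ncol(Z))

  edges <- edge_index_table(n_rois)
  yn <- normalize_cols(Y, Q)
  ok <- !is.na(yn$norm)
  Yn <- yn$M[, ok, drop = FALSE]
  pairs_ok <- cbind(edges$node_i[ok], edges$node_j[ok])
  xn <- normalize_cols(matrix(predictor, ncol = 1), Q)$M[, 1]

  thr <- config$t_threshold
  dir_neg <- config$direction == "negative"
  max_comp_size <- function(tvec) {
    sel <- if (dir_neg) tvec < -thr else tvec > thr
    k <- sum(sel)
    if (k == 0) return(0L)
    if (k == 1) return(1L)
    max(component_edge_counts(pairs_ok[sel, , drop = FALSE]))
  }

  # observed map and components
  t_obs <- r_to_t(as.vector(crossprod(Yn, xn)), df)
  t_full <- rep(NA_real_, nrow(edges))
  t_full[ok] <- t_obs
  t_map <- edge_vector_to_matrix(ifelse(is.na(t_full), 0, t_full), n_rois)
  t_map[edge_vector_to_matrix(as.numeric(is.na(t_full)), n_rois) > 0] <- NA
  attr(t_map, "df") <- df
  components <- suprathreshold_components(t_map, thr, config$direction)

  # permutation null of the maximal component size
  set.seed(config$seed)
  B <- config$n_permutations
  null_max <- integer(B)
  if (is.null(Q)) {
    chunk <- max(1L, min(B, floor(4e6 / max(1, ncol(Yn)))))
    done <- 0L
    while (done < B) {
      b <- min(chunk, B - done)
      Xp <- vapply(seq_len(b), function(i) xn[sample.int(n)], numeric(n))
      Tm <- r_to_t(crossprod(Yn, Xp), df)       # E x b
      for (i in seq_len(b)) null_max[done + i] <- max_comp_size(Tm[, i])
      done <- done + b
    }
  } else {
    # Freedman-Lane: permute reduced-model residuals of Y; the permuted
    # outcome re-residualized on the covariates is (I - Hz) P Rz, and the
    # t statistic is the partial correlation of that with the
    # covariate-residualized predictor.
    Rz <- Y[, ok, drop = FALSE] - Q %*% crossprod(Q, Y[, ok, drop = FALSE])
    for (i in seq_len(B)) {
      W <- Rz[sample.int(n), , drop = FALSE]
      wn <- normalize_cols(W, Q)
      tvec <- r_to_t(as.vector(crossprod(wn$M, xn)), df)
      tvec[is.na(tvec)] <- 0
      null_max[i] <- max_comp_size(tvec)
    }
  }

  components <- lapply(components, function(comp) {
    k <- sum(null_max >= comp$size)
    comp$fwe_p <- if (config$p_variant == "plus_one") (k + 1) / (B + 1) else k / B
    comp$null_max_sizes <- null_max
    comp
  })

  structure(list(
    components = components,
    t_map = t_map,
    null_max_sizes = null_max,
    config = config,
    n_subjects = n,
    excluded_edges = which(!ok)
  ), class = "nbs_result")
}

#' Upper-triangle edge set of a component
#'
#' Returns the component's edges as a 2-column matrix of (node_i,
#' node_j) pairs, usable as the `edge_mask` of [mean_connectivity()] to
#' produce per-subject subnetwork connectivity.
#'
#' @param component An `nbs_component` (an element of
#'   `nbs_result$components`).
#' @return Integer matrix with columns `node_i`, `node_j`.
#' @export
component_edge_mask <- function(component) {
  if (is.null(component$edges) || nrow(component$edges) == 0) {
    stop("component is empty", call. = FALSE)
  }
  as.matrix(component$edges[, c("node_i", "node_j")])
}

#' Node degrees within a component
#'
#' Degree of each node counted over the component's own edges only.
#'
#' @param component An `nbs_component`.
#' @return A tibble with columns `node`, `degree`, sorted by node.
#' @export
node_degree_table <- function(component) {
  if (is.null(component$edges) || nrow(component$edges) == 0) {
    stop("component is empty", call. = FALSE)
  }
  tibble::tibble(node = as.integer(names(component$degrees)),
                 degree = as.integer(component$degrees))
}

#' Per-subject mean connectivity over a fixed edge set
#'
#' Mean of the named edges in each subject's (typically unthresholded)
#' matrix — the per-subject subnetwork FC fed into mediation models.
#'
#' @param stack List of connectivity matrices or an n x n x S array.
#' @param edge_mask 2-column matrix of (node_i, node_j) pairs.
#' @return Numeric vector, one value per subject.
#' @export
subnetwork_mean_fc <- function(stack, edge_mask) {
  Y <- stack_to_edge_matrix(stack)
  pos <- edge_positions(edge_mask, attr(Y, "n_rois"))
  rowMeans(Y[, pos, drop = FALSE])
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("Network-based statistic: %d subject(s), t threshold %.3g (%s), %d permutation(s)\n",
              x$n_subjects, x$config$t_threshold, x$config$direction,
              x$config$n_permutations))
  if (length(x$components) == 0) {
    cat("No suprathreshold components.\n")
  } else {
    print(generics::tidy(x))
  }
  invisible(x)
}

#' Tidy an NBS result
#'
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @return A tibble with one row per suprathreshold component: its index,
#'   edge count, node count and FWE-corrected p-value.
#' @export
tidy.nbs_result <- function(x, ...) {
  if (length(x$components) == 0) {
    return(tibble::tibble(component = integer(0), size = integer(0),
                          n_nodes = integer(0), fwe_p = numeric(0)))
  }
  purrr::imap_dfr(x$components, function(comp, i) {
    tibble::tibble(component = i, size = comp$size,
                   n_nodes = length(comp$nodes), fwe_p = comp$fwe_p)
  })
}

#' Glance at an NBS result
#'
#' @param x An `nbs_result`.
#' @param ... Unused.
#' @return A one-row tibble summarising the test.
#' @export
glance.nbs_result <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    t_threshold = x$config$t_threshold,
    direction = x$config$direction,
    n_permutations = x$config$n_permutations,
    n_components = length(x$components),
    max_component_size = if (length(x$components)) x$components[[1]]$size else 0L,
    min_fwe_p = if (length(x$components))
      min(vapply(x$components, `[[`, numeric(1), "fwe_p")) else NA_real_
  )
}
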