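#' Pearson correlation connectome from ROI time series
#'
#' Computes the pairwise Pearson correlation of ROI time series, the
#' standard construction of a resting-state functional connectome. In
#' absolute mode (the primary analysis mode) the absolute value of each
#' correlation is taken, so anticorrelations contribute their magnitude;
#' signed mode keeps the raw coefficients. Self-connections (the
#' diagonal) are set to zero.
#'
#' @param timeseries ROI x time numeric matrix (rows are ROIs).
#' @param mode `"absolute"` (default) or `"signed"`.
#' @return A symmetric zero-diagonal connectivity matrix with attributes
#'   `mode` and `retained_proportion = "unthresholded"`.
#' @export
correlation_matrix <- function(timeseries, mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (!is.matrix(timeseries) || !is.numeric(timeseries)) {
    stop("`timeseries` must be a numeric ROI x time matrix", call. = FALSE)
  }
  if (ncol(timeseries) < 3) {
    stop("at least 3 timepoints are required to estimate correlations", call. = FALSE)
  }
  sds <- apply(timeseries, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop(sprintf("constant time series for ROI %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  r <- stats::cor(t(timeseries))
  if (mode == "absolute") r <- abs(r)
  diag(r) <- 0
  r <- (r + t(r)) / 2
  attr(r, "mode") <- mode
  attr(r, "retained_proportion") <- "unthresholded"
  r
}

#' Proportional thresholding of a connectivity matrix
#'
#' Retains the strongest `proportion` of the `E = n (n - 1) / 2`
#' upper-triangle edges and zeroes the rest, preserving symmetry. The
#' retained count is `k = round(proportion * E)` with halves rounded up.
#' "Strongest" means largest value in absolute mode and largest magnitude
#' in signed mode (so strong anticorrelations survive). Ties at the cut
#' are broken deterministically by (weight descending, row ascending,
#' column ascending), so exactly `k` edges are always retained.
#'
#' @param m Connectivity matrix (symmetric).
#' @param proportion Proportion of edges to retain, in (0, 1].
#' @param mode Ranking mode; defaults to the matrix's `mode` attribute or
#'   `"absolute"`.
#' @return The thresholded matrix with `retained_proportion` set.
#' @export
proportional_threshold <- function(m, proportion,
                                   mode = attr(m, "mode") %||% "absolute") {
  check_symmetric(m, what = "connectivity matrix")
  if (!is.numeric(proportion) || length(proportion) != 1 ||
      proportion <= 0 || proportion > 1) {
    stop("`proportion` must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(m)
  edges <- edge_index_table(n)
  w <- m[cbind(edges$node_i, edges$node_j)]
  strength <- if (identical(mode, "signed")) abs(w) else w
  E <- nrow(edges)
  k <- floor(proportion * E + 0.5)
  ord <- order(-strength, edges$node_i, edges$node_j)
  keep <- ord[seq_len(k)]
  out_w <- numeric(E)
  out_w[keep] <- w[keep]
  out <- edge_vector_to_matrix(out_w, n)
  attr(out, "mode") <- mode
  attr(out, "retained_proportion") <- proportion
  out
}

#' Mean functional connectivity over retained edges
#'
#' Arithmetic mean of the nonzero (retained) upper-triangle edges;
#' thresholded-out edges do not enter the denominator. With an
#' `edge_mask` the mean is restricted to the listed edges, which is how
#' per-subject subnetwork connectivity is computed from an extracted
#' component.
#'
#' @param m Connectivity matrix.
#' @param edge_mask Optional 2-column matrix or data frame of (node_i,
#'   node_j) pairs restricting the edge set.
#' @return The mean connectivity (scalar).
#' @export
mean_connectivity <- function(m, edge_mask = NULL) {
  check_symmetric(m, what = "connectivity matrix")
  n <- nrow(m)
  edges <- edge_index_table(n)
  w <- m[cbind(edges$node_i, edges$node_j)]
  in_scope <- rep(TRUE, length(w))
  if (!is.null(edge_mask)) {
    in_scope <- seq_along(w) %in% edge_positions(edge_mask, n)
  }
  retained <- in_scope & w != 0
  if (!any(retained)) {
    stop("no retained edges in scope: mean connectivity is undefined", call. = FALSE)
  }
  mean(w[retained])
}

#' Within-, between- and per-network mean connectivity
#'
#' Splits the retained edges of a connectivity matrix by the network
#' labels of their endpoints: within-network edges join two ROIs with the
#' same label, between-network edges join differing labels, and each
#' network's own mean is taken over its internal edges. Networks with
#' fewer than two ROIs (or no retained internal edges) are flagged
#' undefined rather than dropped.
#'
#' @param m Connectivity matrix.
#' @param parcellation Tibble with columns `roi_index` (1-based,
#'   contiguous, covering every ROI) and `network`.
#' @return A tibble with columns `scope` (`"global"`, `"within"`,
#'   `"between"`, or `"network"`), `network` (label, `NA` for the global
#'   rows), `mean_fc`, `n_edges`, `defined`.
#' @export
network_means <- function(m, parcellation) {
  check_symmetric(m, what = "connectivity matrix")
  n <- nrow(m)
  if (!all(c("roi_index", "network") %in% names(parcellation))) {
    stop("`parcellation` needs columns `roi_index` and `network`", call. = FALSE)
  }
  if (!setequal(parcellation$roi_index, seq_len(n))) {
    stop("parcellation must cover every ROI exactly once", call. = FALSE)
  }
  labels <- parcellation$network[order(parcellation$roi_index)]
  edges <- edge_index_table(n)
  w <- m[cbind(edges$node_i, edges$node_j)]
  retained <- w != 0
  li <- labels[edges$node_i]
  lj <- labels[edges$node_j]
  same <- li == lj

  row_of <- function(scope, network, sel) {
    sel <- sel & retained
    tibble::tibble(
      scope = scope, network = network,
      mean_fc = if (any(sel)) mean(w[sel]) else NA_real_,
      n_edges = sum(sel),
      defined = any(sel)
    )
  }
  nets <- unique(labels)
  per_net <- purrr::map_dfr(nets, function(nm) {
    if (sum(labels == nm) < 2) {
      return(tibble::tibble(scope = "network", network = nm,
                            mean_fc = NA_real_, n_edges = 0L, defined = FALSE))
    }
    row_of("network", nm, same & li == nm)
  })
  dplyr::bind_rows(
    row_of("global", NA_character_, rep(TRUE, length(w))),
    row_of("within", NA_character_, same),
    row_of("between", NA_character_, !same),
    per_net
  )
}

#' Entrywise group difference of mean connectomes
#'
#' The difference map between age strata: entrywise mean over the young
#' group minus entrywise mean over the old group.
#'
#' @param stack List of connectivity matrices (or an n x n x S array).
#' @param group_labels Character vector, one of `"young"`/`"old"` per
#'   subject.
#' @return A symmetric matrix of mean differences (young minus old).
#' @export
group_difference_map <- function(stack, group_labels) {
  em <- stack_to_edge_matrix(stack)
  n <- attr(em, "n_rois")
  if (length(group_labels) != nrow(em)) {
    stop("`group_labels` must have one label per subject", call. = FALSE)
  }
  young <- group_labels == "young"
  old <- group_labels == "old"
  if (!any(young) || !any(old)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  d <- colMeans(em[young, , drop = FALSE]) - colMeans(em[old, , drop = FALSE])
  edge_vector_to_matrix(d, n)
}

#' Peak width of skeletonized mean diffusivity
#'
#' The PSMD statistic: the spread of mean-diffusivity values on the
#' white-matter skeleton, computed as the difference between the 95th and
#' 5th percentiles (by default). Percentiles use linear interpolation
#' between closest ranks ([stats::quantile()] type 7); the convention is
#' configurable.
#'
#' @param md_values Numeric vector of skeleton MD values (mm^2/s), at
#'   least two, all finite.
#' @param lower,upper Percentile bounds as probabilities (defaults 0.05
#'   and 0.95).
#' @param type Quantile algorithm passed to [stats::quantile()].
#' @return The peak width (mm^2/s), non-negative.
#' @export
psmd <- function(md_values, lower = 0.05, upper = 0.95, type = 7) {
  if (!is.numeric(md_values) || length(md_values) < 2) {
    stop("`md_values` must contain at least two values", call. = FALSE)
  }
  if (any(!is.finite(md_values))) {
    stop("`md_values` contains non-finite values", call. = FALSE)
  }
  stopifnot(lower < upper)
  q <- stats::quantile(md_values, c(lower, upper), type = type, names = FALSE)
  q[2] - q[1]
}

#' Trail Making Test B/A ratio score
#'
#' The ratio of TMT part B to part A completion times, which adjusts the
#' executive set-shifting component (B) for psychomotor and visual-search
#' speed (A). Vectorized over subjects.
#'
#' @param tmtb_s,tmta_s Completion times in seconds (positive).
#' @return `tmtb_s / tmta_s` (dimensionless).
#' @export
tmt_ratio <- function(tmtb_s, tmta_s) {
  if (any(!is.finite(tmtb_s)) || any(!is.finite(tmta_s)) ||
      any(tmtb_s <= 0) || any(tmta_s <= 0)) {
    stop("TMT times must be positive and finite", call. = FALSE)
  }
  tmtb_s / tmta_s
}
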