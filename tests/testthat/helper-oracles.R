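# Independent oracles used across the suite.

# Brute-force connected components by depth-first search over an edge
# list (2-column matrix). Returns a list of components, each a list with
# sorted `nodes` and `n_edges`, ordered by decreasing edge count then
# smallest node.
dfs_components <- function(pairs) {
  if (nrow(pairs) == 0) return(list())
  nodes <- sort(unique(c(pairs[, 1], pairs[, 2])))
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    c(pairs[pairs[, 1] == v, 2], pairs[pairs[, 2] == v, 1])
  })
  visited <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (v in nodes) {
    if (visited[as.character(v)]) next
    stack <- v
    members <- integer(0)
    while (length(stack)) {
      u <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      if (visited[as.character(u)]) next
      visited[as.character(u)] <- TRUE
      members <- c(members, u)
      stack <- c(stack, adj[[as.character(u)]])
    }
    members <- sort(members)
    in_comp <- pairs[, 1] %in% members
    comps[[length(comps) + 1]] <- list(nodes = members, n_edges = sum(in_comp))
  }
  ord <- order(-vapply(comps, `[[`, numeric(1), "n_edges"),
               vapply(comps, function(cc) min(cc$nodes), numeric(1)))
  comps[ord]
}

# Normal-equations OLS oracle: coefficients, standard errors, t and
# two-sided p-values for y ~ X (X includes the intercept column).
ols_oracle <- function(X, y) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(sigma2 * diag(XtX_inv))
  t <- as.vector(beta) / se
  list(beta = as.vector(beta), se = se, t = t,
       p = 2 * stats::pt(-abs(t), df), df = df)
}

# Small valid correlation matrix (positive-definite, unit diagonal).
random_corr_matrix <- function(n, seed = 1) {
  set.seed(seed)
  A <- matrix(stats::rnorm(n * n), n, n)
  S <- crossprod(A) + diag(n) * 0.5
  stats::cov2cor(S)
}

# Random symmetric zero-diagonal weight matrix with distinct entries.
random_weight_matrix <- function(n, seed = 1) {
  set.seed(seed)
  w <- stats::runif(n * (n - 1) / 2)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- w
  m + t(m)
}
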