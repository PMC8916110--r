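#' Plot an NBS permutation null distribution
#'
#' Histogram of the null distribution of the maximal suprathreshold
#' component size, with the observed component sizes marked; the FWE p
#' of a component is the fraction of the null at or beyond its size.
#'
#' @param object An `nbs_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nbs_result <- function(object, ...) {
  null_df <- tibble::tibble(max_size = object$null_max_sizes)
  p <- ggplot2::ggplot(null_df, ggplot2::aes(x = .data$max_size)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey70", colour = "grey30") +
    ggplot2::labs(
      x = "maximal component size under permutation (edges)",
      y = "permutations",
      title = sprintf("NBS null distribution (t threshold %.3g, %s direction)",
                      object$config$t_threshold, object$config$direction)
    ) +
    ggplot2::theme_minimal()
  if (length(object$components)) {
    obs <- generics::tidy(object)
    p <- p + ggplot2::geom_vline(
      data = obs, ggplot2::aes(xintercept = .data$size),
      colour = "firebrick", linetype = "dashed"
    )
  }
  p
}

#' Plot mediation effects with bootstrap intervals
#'
#' Point estimates of the total, direct and indirect effects with their
#' bootstrap confidence intervals (when the fit was bootstrapped).
#'
#' @param object A `mediation_fit`.
#' @param standardized Plot standardized effects instead of raw ones.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mediation_fit <- function(object, standardized = FALSE, ...) {
  eff <- object$effects
  eff$label <- ifelse(is.na(eff$mediator), eff$effect,
                      paste0(eff$effect, " (", eff$mediator, ")"))
  eff$value <- if (standardized) eff$std_estimate else eff$estimate
  p <- ggplot2::ggplot(eff, ggplot2::aes(x = .data$value, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = if (standardized) "standardized effect" else "effect (outcome units)",
      y = NULL,
      title = sprintf("%s -> {%s} -> %s", object$model$exposure,
                      paste(object$model$mediators, collapse = ", "),
                      object$model$outcome)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(eff$ci_low) && !standardized) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    )
  }
  p
}

#' Heatmap of a group difference map
#'
#' Tile plot of an entrywise connectivity difference matrix (young minus
#' old), optionally ordered and annotated by network.
#'
#' @param diff_map Symmetric difference matrix from
#'   [group_difference_map()].
#' @return A ggplot object.
#' @export
plot_difference_map <- function(diff_map) {
  n <- nrow(diff_map)
  df <- tidyr::expand_grid(node_i = seq_len(n), node_j = seq_len(n))
  df$difference <- diff_map[cbind(df$node_i, df$node_j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node_j, y = .data$node_i,
                                   fill = .data$difference)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "ROI", y = "ROI", fill = "young - old",
                  title = "Functional connectivity difference map") +
    ggplot2::theme_minimal()
}
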