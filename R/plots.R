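#' Plot a cross-tree summary
#'
#' One point-range per model term: the range of per-tree posterior medians,
#' coloured by whether the term clears the two-part significance rule.
#' Lambda is shown alongside the coefficients; sigma2 is omitted (different
#' scale).
#'
#' @param object A `cross_tree_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cross_tree_summary <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::filter(.data$term != "sigma2") |>
    dplyr::mutate(
      mid = (.data$median_min + .data$median_max) / 2,
      status = dplyr::case_when(
        is.na(.data$significant) ~ "estimated",
        .data$significant ~ "significant",
        TRUE ~ "not significant"
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$mid,
                                   ymin = .data$median_min,
                                   ymax = .data$median_max,
                                   colour = .data$status)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "range of per-tree posterior medians",
                  colour = NULL,
                  title = attr(object, "model"),
                  subtitle = paste0(attr(object, "n_trees"), " trees")) +
    ggplot2::theme_minimal()
}

#' Plot a predictive distribution against the observed value
#'
#' The density of imputed response values for one taxon on one tree, with the
#' observed value marked; an observed value far in the tail indicates the model
#' cannot account for this taxon.
#'
#' @param object A `predictive_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.predictive_distribution <- function(object, ...) {
  df <- tibble(value = object$draws)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = object$observed, colour = "darkgreen",
                        linewidth = 1) +
    ggplot2::labs(x = "imputed response (log10 units)", y = "density",
                  title = object$taxon,
                  subtitle = paste0("tree ", object$tree_id, "; observed in green")) +
    ggplot2::theme_minimal()
}

#' Plot per-tree outlier evidence
#'
#' For each tested taxon, the distribution of per-tree predictive tail masses
#' with the per-tree threshold marked; a taxon is a consensus outlier when the
#' mass below the threshold exceeds the tree-fraction rule.
#'
#' @param object An `outlier_result` (from [outlier_test()] or
#'   [run_outlier_analysis()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.outlier_result <- function(object, ...) {
  per_tree <- attr(object, "per_tree")
  flagged <- as_tibble(object)[, c("taxon", "is_outlier")]
  df <- dplyr::left_join(per_tree, flagged, by = "taxon")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tail, fill = .data$is_outlier)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::geom_vline(xintercept = attr(object, "threshold"),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~ .data$taxon) +
    ggplot2::labs(x = "predictive tail mass at observed value", y = "trees",
                  fill = "consensus outlier") +
    ggplot2::theme_minimal()
}

#' Plot traces and marginal densities of a posterior sample
#'
#' @param object A `pgls_posterior`.
#' @param ... Unused.
#' @return A ggplot of per-parameter traces.
#' @export
autoplot.pgls_posterior <- function(object, ...) {
  df <- as_tibble(object$beta) |>
    dplyr::mutate(lambda = object$lambda, sigma2 = object$sigma2,
                  draw = dplyr::row_number()) |>
    tidyr::pivot_longer(-"draw", names_to = "parameter")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$draw, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~ .data$parameter, scales = "free_y") +
    ggplot2::labs(x = "retained draw", y = NULL) +
    ggplot2::theme_minimal()
}
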