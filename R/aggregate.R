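#' Aggregate per-tree fit summaries across a tree sample
#'
#' Each model is fitted once per tree in the sample; a variable counts as
#' significant overall only when its per-tree `p_x` is at or below `sig_level`
#' in at least `tree_fraction` of the trees (the two-part rule: per-tree
#' posterior support, robust across topologies). Point estimates are reported as
#' the range of per-tree posterior medians.
#'
#' @param fits A list of per-tree summaries from [summarize_fit()], or a single
#'   tibble binding them (one row per tree x term), all from the same model.
#' @param sig_level Per-tree threshold on `p_x` (default 0.05).
#' @param tree_fraction Fraction of trees that must individually be significant
#'   (default 0.95; the overall flag uses `>=`).
#' @return A `cross_tree_summary` tibble with one row per term: `median_min`,
#'   `median_max` (range of per-tree posterior medians), `frac_significant`
#'   (share of trees with `p_x <= sig_level`; `NA` for lambda/sigma2) and
#'   `significant`. Attributes `n_trees` and `model` record provenance.
#' @export
aggregate_over_trees <- function(fits, sig_level = 0.05, tree_fraction = 0.95) {
  if (is.data.frame(fits)) {
    tab <- fits
    models <- attr(fits, "model")
  } else {
    models <- unique(purrr::map(fits, attr, "model"))
    if (length(models) > 1) {
      abort("fit summaries come from different models and cannot be aggregated")
    }
    models <- models[[1]]
    tab <- dplyr::bind_rows(fits)
  }
  required <- c("tree_id", "term", "estimate", "p_x")
  if (!all(required %in% names(tab))) {
    abort("fit summaries must have columns tree_id, term, estimate, p_x")
  }
  n_trees <- dplyr::n_distinct(tab$tree_id)
  per_term <- dplyr::count(tab, .data$term)
  if (any(per_term$n != n_trees)) {
    abort("expected exactly one fit per tree per term")
  }

  out <- tab |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      median_min = min(.data$estimate),
      median_max = max(.data$estimate),
      frac_significant = if (all(is.na(.data$p_x))) NA_real_ else
        mean(.data$p_x <= sig_level),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      significant = .data$frac_significant >= tree_fraction,
      term = factor(.data$term, levels = unique(tab$term))
    ) |>
    dplyr::arrange(.data$term) |>
    dplyr::mutate(term = as.character(.data$term))

  structure(out,
            class = c("cross_tree_summary", class(out)),
            n_trees = n_trees, model = models,
            sig_level = sig_level, tree_fraction = tree_fraction)
}

#' @export
print.cross_tree_summary <- function(x, ...) {
  model <- attr(x, "model")
  cat("<cross_tree_summary>", if (!is.null(model)) model else "",
      "over", attr(x, "n_trees"), "trees\n")
  print(as_tibble(x), ...)
  invisible(x)
}

#' @rdname aggregate_over_trees
#' @param x A `cross_tree_summary`.
#' @param ... Unused.
#' @export
tidy.cross_tree_summary <- function(x, ...) as_tibble(x)

#' @rdname aggregate_over_trees
#' @export
glance.cross_tree_summary <- function(x, ...) {
  coef_rows <- !x$term %in% c("lambda", "sigma2")
  tibble(
    model = attr(x, "model") %||% NA_character_,
    n_trees = attr(x, "n_trees"),
    n_terms = sum(coef_rows),
    n_significant = sum(x$significant[coef_rows], na.rm = TRUE),
    lambda_median_min = x$median_min[x$term == "lambda"],
    lambda_median_max = x$median_max[x$term == "lambda"]
  )
}
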