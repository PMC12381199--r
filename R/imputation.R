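#' Phylogenetic imputation: posterior predictive draws for a held-out taxon
#'
#' For each retained posterior draw (beta, sigma2, lambda), predicts the
#' response of `target` from both the regression and the taxon's position on the
#' tree. With the joint lambda-scaled covariance over observed taxa and target
#' partitioned as (V_oo, v_ot, v_tt), each draw is
#' `N( x_t' beta + v_ot' V_oo^-1 (y_o - X_o beta),
#'     sigma2 * (v_tt - v_ot' V_oo^-1 v_ot) )`,
#' where the lambda transform is applied to all off-diagonal entries before
#' conditioning. So a taxon with close observed relatives borrows heavily from
#' them (small predictive variance); at `lambda = 0` no borrowing occurs and the
#' prediction collapses to the regression line.
#'
#' The model behind `ps` must have been fitted excluding `target` (and any
#' co-excluded set, e.g. all hominins); the fitting design is rebuilt here from
#' `table`, `spec` and the tree, and an error is raised if `target` is part of it.
#'
#' @param ps A `pgls_posterior` for this tree.
#' @param tree The `phylo` the model was fitted on (must contain `target` and
#'   the fitting taxa).
#' @param table The trait table (log scale).
#' @param spec The [model_spec()] used for the fit, including its exclusions.
#' @param target Taxon label to predict.
#' @return A `predictive_distribution`: `taxon`, `tree_id`, `draws` (one
#'   predicted response per posterior draw, log units) and `observed` (the
#'   taxon's true response value, `NA` if unknown).
#' @export
predictive_draws <- function(ps, tree, table, spec, target) {
  stopifnot(inherits(ps, "pgls_posterior"), inherits(spec, "model_spec"),
            length(target) == 1)
  if (!target %in% tree$tip.label) {
    abort(paste0("target taxon '", target, "' is not in the tree"))
  }
  fit_taxa <- intersect(tree$tip.label, table$species)
  des <- build_design(table, spec, taxa_order = fit_taxa)
  if (target %in% des$taxa) {
    abort(paste0("contract violation: target '", target,
                 "' is part of the fitting set; refit excluding it"))
  }
  if (!identical(sort(colnames(ps$beta)), sort(colnames(des$X)))) {
    abort("posterior coefficients do not match the model spec's design columns")
  }

  trow <- table[table$species == target, , drop = FALSE]
  if (nrow(trow) != 1) abort(paste0("target '", target, "' not found in trait table"))
  pvals <- purrr::map_dbl(spec$predictors, ~ as.numeric(trow[[.x]]))
  if (anyNA(pvals)) {
    abort(paste0("target '", target, "' is missing predictor values"))
  }
  x_t <- c(1, pvals,
           purrr::map_dbl(spec$interactions,
                          ~ prod(pvals[match(.x, spec$predictors)])))
  names(x_t) <- colnames(des$X)
  x_t <- x_t[colnames(ps$beta)]

  sub <- prune_to_taxa(tree, c(des$taxa, target))
  V <- phylo_vcv(sub, taxa_order = c(des$taxa, target))
  n_o <- length(des$taxa)
  B <- ps$beta[, colnames(ps$beta), drop = FALSE]
  Xo <- des$X[, colnames(ps$beta), drop = FALSE]

  d <- nrow(B)
  out <- numeric(d)
  clamped <- FALSE
  groups <- split(seq_len(d), ps$lambda[seq_len(d)])
  for (g in groups) {
    lam <- ps$lambda[g[1]]
    Vl <- lambda_transform(V, lam)
    Voo <- Vl[1:n_o, 1:n_o, drop = FALSE]
    vot <- Vl[1:n_o, n_o + 1]
    vtt <- Vl[n_o + 1, n_o + 1]
    L <- tryCatch(t(chol(Voo)), error = function(e) {
      abort(paste0("conditioning covariance singular at lambda = ", lam,
                   ": ", conditionMessage(e)))
    })
    u <- forwardsolve(L, vot)
    base_var <- vtt - sum(u^2)
    if (base_var < 0) {
      clamped <- TRUE
      base_var <- 0
    }
    a <- backsolve(t(L), u)                       # V_oo^-1 v_ot
    resid <- des$y - Xo %*% t(B[g, , drop = FALSE])  # n_o x |g|
    mu <- as.numeric(B[g, , drop = FALSE] %*% x_t) + as.numeric(crossprod(a, resid))
    out[g] <- rnorm(length(g), mean = mu, sd = sqrt(ps$sigma2[g] * base_var))
  }
  if (clamped) {
    warn("negative conditional variance clamped at 0 (numerical)")
  }

  structure(
    list(taxon = target, tree_id = ps$tree_id, draws = out,
         observed = as.numeric(trow[[spec$response]])),
    class = "predictive_distribution"
  )
}

#' @export
print.predictive_distribution <- function(x, ...) {
  cat("<predictive_distribution>", x$taxon,
      if (!is.na(x$tree_id)) paste0("(tree ", x$tree_id, ")"),
      ":", length(x$draws), "draws, median",
      signif(median(x$draws), 4), "| observed", signif(x$observed, 4), "\n")
  invisible(x)
}

#' @rdname predictive_draws
#' @param x A `predictive_distribution`.
#' @param ... Unused.
#' @export
tidy.predictive_distribution <- function(x, ...) {
  tibble(taxon = x$taxon, tree_id = x$tree_id, draw = seq_along(x$draws),
         value = x$draws, observed = x$observed)
}

#' Predictive tail mass at the observed value
#'
#' How far into the tail of its own predictive distribution a taxon's observed
#' value falls: the smaller of the estimated probabilities of draws at or below
#' and at or above the observed value. A perfectly predicted taxon scores about
#' 0.5; a taxon the model cannot explain scores near 0.
#'
#' With the default `"add-one"` correction, a tail count of r among N draws is
#' estimated as (r + 1) / (N + 1), so a finite draw set never yields an exact 0;
#' `"none"` uses the raw proportion r / N.
#'
#' @param pd A `predictive_distribution` with a non-missing observed value.
#' @param correction `"add-one"` (default) or `"none"`.
#' @param side `"min"` (default; the smaller of the two tails, two-sided
#'   protection), `"upper"` (mass at or above the observed value — small when
#'   the observed value is surprisingly large), or `"lower"`.
#' @return A value in \[0, 1\] (at most ~0.5 plus draw resolution for `"min"`).
#' @export
tail_mass <- function(pd, correction = c("add-one", "none"),
                      side = c("min", "upper", "lower")) {
  correction <- match.arg(correction)
  side <- match.arg(side)
  stopifnot(inherits(pd, "predictive_distribution"))
  if (length(pd$draws) == 0) abort("empty predictive draw set")
  if (is.na(pd$observed)) abort("observed value is missing; tail mass undefined")
  n <- length(pd$draws)
  r <- switch(side,
    min = min(sum(pd$draws <= pd$observed), sum(pd$draws >= pd$observed)),
    upper = sum(pd$draws >= pd$observed),
    lower = sum(pd$draws <= pd$observed)
  )
  if (correction == "add-one") (r + 1) / (n + 1) else r / n
}

#' Multi-tree phylogenetic outlier test
#'
#' A taxon is declared a phylogenetic outlier when its predictive distribution
#' overlaps the observed value by less than `threshold` (tail mass below 5%) in
#' strictly more than `tree_fraction` of the trees in the sample — i.e. the
#' model fails to account for it robustly across plausible phylogenies.
#'
#' @param pds List of `predictive_distribution`s for the same taxon, one per
#'   tree.
#' @param threshold Per-tree tail-mass threshold (default 0.05).
#' @param tree_fraction Fraction of trees that must individually flag the taxon;
#'   the consensus flag uses a strict `>` (default 0.95, so 96/100 trees flag
#'   and 95/100 do not).
#' @param correction,side Tail estimation rules, see [tail_mass()].
#' @return An `outlier_result` tibble with one row: `taxon`, `n_trees`,
#'   `fraction_trees_below_threshold`, `is_outlier`. The per-tree tail masses
#'   are in the `per_tree` attribute.
#' @export
outlier_test <- function(pds, threshold = 0.05, tree_fraction = 0.95,
                         correction = c("add-one", "none"),
                         side = c("min", "upper", "lower")) {
  correction <- match.arg(correction)
  side <- match.arg(side)
  stopifnot(length(pds) >= 1)
  taxa <- unique(purrr::map_chr(pds, "taxon"))
  if (length(taxa) != 1) {
    abort(paste0("predictive distributions mix taxa: ", paste(taxa, collapse = ", ")))
  }
  per_tree <- tibble(
    taxon = taxa,
    tree_id = purrr::map_int(pds, ~ as.integer(.x$tree_id)),
    tail = purrr::map_dbl(pds, tail_mass, correction = correction, side = side),
    predictive_median = purrr::map_dbl(pds, ~ median(.x$draws)),
    conf.low = purrr::map_dbl(pds, ~ quantile(.x$draws, 0.025)),
    conf.high = purrr::map_dbl(pds, ~ quantile(.x$draws, 0.975)),
    observed = purrr::map_dbl(pds, "observed")
  )
  frac <- mean(per_tree$tail < threshold)
  out <- tibble(
    taxon = taxa,
    n_trees = length(pds),
    fraction_trees_below_threshold = frac,
    is_outlier = frac > tree_fraction
  )
  structure(out, class = c("outlier_result", class(out)),
            per_tree = per_tree, threshold = threshold,
            tree_fraction = tree_fraction)
}

#' @rdname outlier_test
#' @param x An `outlier_result`.
#' @param ... Unused.
#' @export
tidy.outlier_result <- function(x, ...) attr(x, "per_tree")
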