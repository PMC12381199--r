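#' Specify a PGLS regression model
#'
#' A model specification names the response trait, the predictor traits (in
#' order), optional pairwise interactions (product columns), and taxa to
#' exclude before fitting (e.g. all hominins for the non-hominin model
#' variants). An intercept is always included.
#'
#' @param response Name of the response column in the trait table (e.g. `"mc1"`,
#'   log thumb length).
#' @param predictors Character vector of predictor column names, in the order
#'   their columns should appear in the design matrix.
#' @param interactions List of length-2 character vectors; each adds a product
#'   column of two declared predictors (e.g. `list(c("brain", "tool_any"))` for
#'   a slope difference between tool users and non-users).
#' @param exclude Character vector of taxon names dropped before fitting.
#' @param label Short model label used in reports; defaults to a formula-like
#'   string.
#' @return A `model_spec` object.
#' @examples
#' model_spec("mc1", c("mc2", "brain"))
#' @export
model_spec <- function(response, predictors, interactions = list(),
                       exclude = character(), label = NULL) {
  stopifnot(is.character(response), length(response) == 1,
            is.character(predictors), length(predictors) >= 1)
  if (response %in% predictors) {
    abort("the response must not appear among the predictors")
  }
  if (anyDuplicated(predictors)) {
    abort("duplicated predictor names")
  }
  interactions <- lapply(interactions, as.character)
  for (ia in interactions) {
    if (length(ia) != 2 || !all(ia %in% predictors)) {
      abort("every interaction must be a pair of declared predictors")
    }
  }
  if (is.null(label)) {
    rhs <- c(predictors, purrr::map_chr(interactions, paste, collapse = ":"))
    label <- paste(response, "~", paste(rhs, collapse = " + "))
  }
  structure(
    list(response = response, predictors = predictors,
         interactions = interactions, exclude = unique(as.character(exclude)),
         label = label),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$label, "\n")
  if (length(x$exclude)) {
    cat("  excluding", length(x$exclude), "taxa\n")
  }
  invisible(x)
}

#' MCMC configuration for the PGLS sampler
#'
#' Defaults follow the study schedule: 1,000,000 post-burn-in iterations sampled
#' every 10,000 (100 retained draws per tree), a burn-in of 100,000, and at
#' least 3 replicate chains whose agreement is checked with a split-chain
#' potential scale reduction factor. Regression coefficients get independent
#' wide normal priors (mean 0, sd 5); lambda a uniform prior on \[0, 1\]; the
#' residual scale a half-Cauchy prior on sigma (scale 5). Reduced schedules
#' (fewer iterations, thinner chains) are appropriate for simulation studies.
#'
#' @param iterations Post-burn-in iteration count; must be divisible by
#'   `thinning`. Retained draws = `iterations / thinning`.
#' @param thinning Sampling interval.
#' @param burn_in Iterations discarded before sampling (adaptation of proposal
#'   scales happens only here).
#' @param prior_beta_sd Standard deviation of the normal prior on each
#'   coefficient (mean is 0).
#' @param sigma_prior_scale Scale of the half-Cauchy prior on sigma.
#' @param proposal_lambda,proposal_log_sigma2 Initial random-walk proposal
#'   standard deviations (adapted during burn-in).
#' @param lambda_fixed,sigma2_fixed Optional fixed values; when supplied the
#'   corresponding parameter is not sampled (degenerate prior), which is how the
#'   conjugate closed-form posterior checks are run.
#' @param seed Integer seed fixing the entire draw sequence.
#' @param replicates Number of independent chains (>= 1). Draws are returned
#'   from the first chain; the others feed the convergence diagnostic.
#' @return An `mcmc_config` object.
#' @export
mcmc_config <- function(iterations = 1e6, thinning = 1e4, burn_in = 1e5,
                        prior_beta_sd = 5, sigma_prior_scale = 5,
                        proposal_lambda = 0.15, proposal_log_sigma2 = 0.6,
                        lambda_fixed = NULL, sigma2_fixed = NULL,
                        seed = 1L, replicates = 3L) {
  iterations <- as.integer(round(iterations))
  thinning <- as.integer(round(thinning))
  burn_in <- as.integer(round(burn_in))
  stopifnot(iterations > 0, thinning > 0, burn_in >= 0,
            prior_beta_sd > 0, sigma_prior_scale > 0,
            proposal_lambda > 0, proposal_log_sigma2 > 0, replicates >= 1)
  if (iterations %% thinning != 0) {
    abort("iterations must be divisible by thinning")
  }
  if (!is.null(lambda_fixed) &&
      (lambda_fixed < 0 || lambda_fixed > 1)) {
    abort("lambda_fixed must lie in [0, 1]")
  }
  if (!is.null(sigma2_fixed) && sigma2_fixed <= 0) {
    abort("sigma2_fixed must be positive")
  }
  structure(
    list(iterations = iterations, thinning = thinning, burn_in = burn_in,
         prior_beta_sd = prior_beta_sd, sigma_prior_scale = sigma_prior_scale,
         proposal_lambda = proposal_lambda,
         proposal_log_sigma2 = proposal_log_sigma2,
         lambda_fixed = lambda_fixed, sigma2_fixed = sigma2_fixed,
         seed = as.integer(seed), replicates = as.integer(replicates)),
    class = "mcmc_config"
  )
}

#' @export
print.mcmc_config <- function(x, ...) {
  cat("<mcmc_config>", x$iterations, "iterations / thin", x$thinning,
      "/ burn-in", x$burn_in, "/", x$replicates, "chain(s), seed", x$seed, "\n")
  invisible(x)
}

#' Build the design matrix and response for a model specification
#'
#' Applies the spec's taxon exclusions, drops (and reports) taxa with any
#' missing required value, and assembles the design matrix: an intercept column
#' of ones, predictor columns in spec order, then interaction product columns.
#' Logical predictors (e.g. tool-use indicators) are dummy-coded 0/1.
#'
#' @param table Trait table: a data frame with a `species` column and one column
#'   per trait, values already on the log scale where applicable.
#' @param spec A [model_spec()].
#' @param taxa_order Character vector giving the row order (usually the taxon
#'   order of a phylogenetic covariance matrix); taxa absent from the table or
#'   incomplete are dropped from this order.
#' @return A list with `X` (design matrix), `y` (response vector), `taxa`
#'   (retained taxa, row order of `X`), and `dropped` (a tibble of excluded or
#'   incomplete taxa and the reason).
#' @export
build_design <- function(table, spec, taxa_order = NULL) {
  stopifnot(inherits(spec, "model_spec"), is.data.frame(table))
  if (!"species" %in% names(table)) abort("trait table must have a 'species' column")
  needed <- c(spec$response, spec$predictors)
  miss_col <- setdiff(needed, names(table))
  if (length(miss_col) > 0) {
    abort(paste0("trait table lacks required columns: ", paste(miss_col, collapse = ", ")))
  }
  if (is.null(taxa_order)) taxa_order <- table$species
  taxa_order <- as.character(taxa_order)

  tab <- table[match(taxa_order, table$species), , drop = FALSE]
  in_table <- !is.na(tab$species)
  excluded <- in_table & tab$species %in% spec$exclude
  vals <- tab[, needed, drop = FALSE]
  complete <- in_table & stats::complete.cases(vals)
  keep <- complete & !excluded

  dropped <- tibble(
    species = taxa_order[!keep],
    reason = dplyr::case_when(
      !in_table[!keep] ~ "absent from trait table",
      excluded[!keep] ~ "excluded by model spec",
      TRUE ~ "missing required trait value"
    )
  )

  tab <- tab[keep, , drop = FALSE]
  p_cols <- lapply(spec$predictors, function(v) as.numeric(tab[[v]]))
  names(p_cols) <- spec$predictors
  X <- cbind(`(Intercept)` = rep(1, nrow(tab)), do.call(cbind, p_cols))
  colnames(X) <- c("(Intercept)", spec$predictors)
  for (ia in spec$interactions) {
    X <- cbind(X, p_cols[[ia[1]]] * p_cols[[ia[2]]])
    colnames(X)[ncol(X)] <- paste(ia, collapse = ":")
  }
  y <- as.numeric(tab[[spec$response]])

  if (nrow(X) < ncol(X) + 2) {
    abort(paste0("under-determined model: ", nrow(X), " complete taxa for ",
                 ncol(X), " design columns (need at least ", ncol(X) + 2, ")"))
  }
  if (qr(X)$rank < ncol(X)) {
    abort("under-determined model: design matrix is rank deficient (constant or collinear predictor)")
  }
  list(X = X, y = y, taxa = tab$species, dropped = dropped)
}
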