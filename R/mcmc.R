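#' Log-likelihood of the lambda-scaled PGLS model
#'
#' Evaluates `log N(y; X beta, sigma2 * V(lambda))` through a Cholesky
#' factorization (no explicit inverse):
#' `-0.5 * (n log(2 pi sigma2) + log|V(lambda)| + r' V(lambda)^-1 r / sigma2)`
#' with `r = y - X beta`.
#'
#' @param y Response vector.
#' @param X Design matrix (rows match `y`).
#' @param beta Coefficient vector (length `ncol(X)`).
#' @param sigma2 Residual scale (> 0).
#' @param lambda Pagel's lambda in \[0, 1\].
#' @param V Phylogenetic covariance matrix, taxa in row order of `X`.
#' @return The log-density (a single number).
#' @export
gls_loglik <- function(y, X, beta, sigma2, lambda, V) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, length(beta) == ncol(X), nrow(V) == n, ncol(V) == n)
  if (sigma2 <= 0) abort("sigma2 must be positive")
  Vl <- lambda_transform(V, lambda)
  L <- tryCatch(t(chol(Vl)), error = function(e) {
    abort(paste0("V(lambda) is numerically singular (", conditionMessage(e),
                 "); add jitter to branch lengths or check for duplicated tips"))
  })
  r <- y - X %*% beta
  u <- forwardsolve(L, r)
  logdet <- 2 * sum(log(diag(L)))
  as.numeric(-0.5 * (n * log(2 * pi * sigma2) + logdet + sum(u^2) / sigma2))
}

#' Draw from the posterior of a lambda-scaled PGLS model
#'
#' Runs the MCMC sampler for `y ~ N(X beta, sigma2 V(lambda))` with wide normal
#' priors on the coefficients, a uniform prior on lambda and a half-Cauchy prior
#' on sigma (see [mcmc_config()]). Draws are returned from the first chain; when
#' `replicates >= 2`, the extra chains feed a split-chain potential scale
#' reduction diagnostic (values above 1.05 trigger a warning, as do
#' Metropolis acceptance rates outside \[0.05, 0.8\]).
#'
#' @param y Response vector.
#' @param X Design matrix with column names (taxa in rows).
#' @param V Phylogenetic covariance matrix in the same taxon order.
#' @param cfg An [mcmc_config()].
#' @param tree_id Optional integer identifying the tree this fit belongs to.
#' @return A `pgls_posterior`: retained draws of `beta` (matrix draws x
#'   coefficients), `sigma2`, `lambda`, plus `tree_id`, the config, and chain
#'   diagnostics (`rhat`, acceptance rates, effective sample sizes).
#' @export
sample_posterior <- function(y, X, V, cfg = mcmc_config(), tree_id = NA_integer_) {
  stopifnot(inherits(cfg, "mcmc_config"))
  X <- as.matrix(X)
  V <- as.matrix(V)
  n <- length(y)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n) {
    abort("dimensions of y, X and V are inconsistent")
  }
  if (is.null(colnames(X))) {
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[seq_len(ncol(X))]
  }

  chains <- vector("list", cfg$replicates)
  for (k in seq_len(cfg$replicates)) {
    set.seed(chain_seed(cfg$seed, k))
    chains[[k]] <- .pgls_mcmc_chain(
      y, X, V,
      iterations = cfg$iterations, burn_in = cfg$burn_in, thinning = cfg$thinning,
      prior_beta_sd = cfg$prior_beta_sd, sigma_prior_scale = cfg$sigma_prior_scale,
      prop_lambda = cfg$proposal_lambda, prop_log_sigma2 = cfg$proposal_log_sigma2,
      lambda_is_fixed = !is.null(cfg$lambda_fixed),
      lambda_value = cfg$lambda_fixed %||% 0.5,
      sigma2_is_fixed = !is.null(cfg$sigma2_fixed),
      sigma2_value = cfg$sigma2_fixed %||% 1
    )
  }

  first <- chains[[1]]
  beta <- first$beta
  colnames(beta) <- colnames(X)

  diag_pars <- c(
    stats::setNames(lapply(seq_len(ncol(beta)), function(j) {
      lapply(chains, function(ch) ch$beta[, j])
    }), colnames(beta)),
    if (is.null(cfg$sigma2_fixed)) list(sigma2 = lapply(chains, `[[`, "sigma2")),
    if (is.null(cfg$lambda_fixed)) list(lambda = lapply(chains, `[[`, "lambda"))
  )
  rhat <- purrr::map_dbl(diag_pars, split_rhat)
  ess <- purrr::map_dbl(diag_pars, function(ds) sum(purrr::map_dbl(ds, ess_single)))
  if (cfg$replicates >= 2 && any(is.finite(rhat) & rhat > 1.05)) {
    bad <- names(rhat)[is.finite(rhat) & rhat > 1.05]
    warn(paste0("split-chain Rhat > 1.05 for: ", paste(bad, collapse = ", "),
                " — chains may not have converged; lengthen burn-in/iterations"))
  }
  acc <- c(lambda = first$accept_lambda, sigma2 = first$accept_sigma2)
  acc_ok <- is.na(acc) | (acc >= 0.05 & acc <= 0.8)
  if (!all(acc_ok)) {
    warn(paste0("Metropolis acceptance rate outside [0.05, 0.8] for: ",
                paste(names(acc)[!acc_ok], collapse = ", ")))
  }

  structure(
    list(beta = beta,
         sigma2 = as.numeric(first$sigma2),
         lambda = as.numeric(first$lambda),
         tree_id = tree_id,
         config = cfg,
         diagnostics = list(rhat = rhat, ess = ess, accept = acc,
                            replicates = cfg$replicates)),
    class = "pgls_posterior"
  )
}

# per-chain seeds derived from the config seed; kept well under 2^31
chain_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 67 + (k - 1) * 10007) %% 2147483647)
}

#' Construct a posterior sample from explicit draws
#'
#' Mainly useful for predictive experiments where the regression parameters are
#' held at known values (e.g. validating the imputation machinery against
#' closed-form conditional moments).
#'
#' @param beta Matrix of coefficient draws (draws x coefficients), with column
#'   names.
#' @param sigma2,lambda Numeric vectors of draws, recycled to `nrow(beta)`.
#' @param tree_id Optional tree index.
#' @return A `pgls_posterior`.
#' @export
pgls_posterior <- function(beta, sigma2, lambda, tree_id = NA_integer_) {
  beta <- as.matrix(beta)
  d <- nrow(beta)
  sigma2 <- rep_len(as.numeric(sigma2), d)
  lambda <- rep_len(as.numeric(lambda), d)
  if (any(sigma2 <= 0)) abort("all sigma2 draws must be positive")
  if (any(lambda < 0 | lambda > 1)) abort("all lambda draws must lie in [0, 1]")
  structure(
    list(beta = beta, sigma2 = sigma2, lambda = lambda, tree_id = tree_id,
         config = NULL, diagnostics = NULL),
    class = "pgls_posterior"
  )
}

#' @export
print.pgls_posterior <- function(x, ...) {
  cat("<pgls_posterior>", nrow(x$beta), "draws,",
      ncol(x$beta), "coefficients", if (!is.na(x$tree_id)) paste0("(tree ", x$tree_id, ")"), "\n")
  print(summarize_fit(x), ...)
  invisible(x)
}

#' Proportion of the posterior crossing zero
#'
#' The per-tree significance statistic: the smaller of the posterior mass at or
#' below zero and at or above zero, so a coefficient whose posterior sits firmly
#' on either side of zero scores near 0 and one straddling zero scores near 0.5.
#' Significance is declared elsewhere at `p_x <= 0.05`.
#'
#' @param draws Numeric vector of posterior draws (at least 2).
#' @return A proportion in \[0, 0.5\].
#' @export
p_x <- function(draws) {
  draws <- as.numeric(draws)
  if (length(draws) < 2 || anyNA(draws)) {
    abort("p_x needs at least 2 non-missing draws")
  }
  min(mean(draws <= 0), mean(draws >= 0), 0.5)
}

#' Summarise one posterior sample
#'
#' Per-coefficient posterior medians and `p_x`, plus the medians of lambda and
#' sigma2, as one tidy row per term. Medians are the study's point summary;
#' ranges of these medians across trees are reported downstream.
#'
#' @param ps A `pgls_posterior`.
#' @param model Optional model label carried into cross-tree aggregation.
#' @return A tibble with columns `tree_id`, `term`, `estimate` (posterior
#'   median) and `p_x` (`NA` for lambda and sigma2).
#' @export
summarize_fit <- function(ps, model = NULL) {
  stopifnot(inherits(ps, "pgls_posterior"))
  if (nrow(ps$beta) == 0) abort("empty posterior sample")
  coefs <- tibble(
    tree_id = ps$tree_id,
    term = colnames(ps$beta),
    estimate = unname(apply(ps$beta, 2, median)),
    p_x = unname(apply(ps$beta, 2, p_x))
  )
  extras <- tibble(
    tree_id = ps$tree_id,
    term = c("lambda", "sigma2"),
    estimate = c(median(ps$lambda), median(ps$sigma2)),
    p_x = NA_real_
  )
  out <- dplyr::bind_rows(coefs, extras)
  attr(out, "model") <- model
  out
}

#' @rdname sample_posterior
#' @param x A `pgls_posterior`.
#' @param conf_level Credible-interval mass for `tidy()`.
#' @param ... Unused.
#' @export
tidy.pgls_posterior <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  tibble(
    term = colnames(x$beta),
    estimate = unname(apply(x$beta, 2, median)),
    conf.low = unname(apply(x$beta, 2, quantile, probs = a)),
    conf.high = unname(apply(x$beta, 2, quantile, probs = 1 - a)),
    p_x = unname(apply(x$beta, 2, p_x))
  )
}

#' @rdname sample_posterior
#' @export
glance.pgls_posterior <- function(x, ...) {
  tibble(
    n_draws = nrow(x$beta),
    lambda = median(x$lambda),
    sigma2 = median(x$sigma2),
    max_rhat = if (!is.null(x$diagnostics)) suppressWarnings(max(x$diagnostics$rhat)) else NA_real_,
    min_ess = if (!is.null(x$diagnostics)) suppressWarnings(min(x$diagnostics$ess)) else NA_real_,
    tree_id = x$tree_id
  )
}

# split-chain potential scale reduction factor (each chain halved)
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(d) {
    h <- length(d) %/% 2
    if (h < 2) return(list(d))
    list(d[1:h], d[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- min(lengths(halves))
  if (m < 2 || n < 2) return(NA_real_)
  halves <- lapply(halves, function(d) d[1:n])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# initial-positive-sequence effective sample size for one chain
ess_single <- function(d) {
  n <- length(d)
  if (n < 4 || var(d) == 0) return(n)
  ac <- stats::acf(d, lag.max = min(n - 2, 100), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq(1, length(ac) - 1, by = 2)) {
    pair <- ac[k] + ac[k + 1]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
  }
  max(1, min(n, n / (1 + 2 * s)))
}
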