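# small world shared by the imputation tests: 6 taxa, one held-out target
imputation_world <- function(seed = 1, sigma2_true = 0.002) {
  tr <- simulate_tree(6, seed = seed)
  sc <- simulation_scenario(n_taxa = 6, sigma2_true = sigma2_true, seed = seed)
  tab <- simulate_traits(tr, sc)
  target <- tab$species[4]
  spec <- model_spec("mc1", c("mc2", "brain"), exclude = target)
  list(tree = tr, table = tab, spec = spec, target = target)
}

test_that("tail_mass counts the smaller tail, with and without the add-one correction", {
  pd <- make_pd(draws = 1:100, observed = 50.5)
  expect_equal(tail_mass(pd, correction = "none"), 0.5)
  expect_equal(tail_mass(pd), 51 / 101)

  # observed above every draw
  hi <- make_pd(draws = 1:100, observed = 1000)
  expect_equal(tail_mass(hi, correction = "none"), 0)
  expect_equal(tail_mass(hi), 1 / 101)

  # 4 of 100 draws at or above the observed value
  four <- make_pd(draws = c(rep(0, 96), rep(10, 4)), observed = 5)
  expect_equal(tail_mass(four, correction = "none"), 0.04)
  expect_equal(tail_mass(four), 5 / 101)

  expect_error(tail_mass(make_pd(numeric(), 1)), "empty")
  expect_error(tail_mass(make_pd(1:10, NA_real_)), "missing")
})

test_that("outlier_test applies the strict >95%-of-trees consensus rule", {
  centred <- lapply(1:100, function(i) make_pd(rnorm(100), 0, tree_id = i))
  res <- outlier_test(centred)
  expect_false(res$is_outlier)

  # tails below threshold in 96/100 trees: outlier
  pds96 <- lapply(1:100, function(i) {
    make_pd(draws = 1:100, observed = if (i <= 96) 1000 else 50.5, tree_id = i)
  })
  res96 <- outlier_test(pds96)
  expect_equal(res96$fraction_trees_below_threshold, 0.96)
  expect_true(res96$is_outlier)

  # 95/100 is not strictly more than 95%: no flag
  pds95 <- lapply(1:100, function(i) {
    make_pd(draws = 1:100, observed = if (i <= 95) 1000 else 50.5, tree_id = i)
  })
  res95 <- outlier_test(pds95)
  expect_equal(res95$fraction_trees_below_threshold, 0.95)
  expect_false(res95$is_outlier)

  mixed <- list(make_pd(1:10, 5, taxon = "a"), make_pd(1:10, 5, taxon = "b"))
  expect_error(outlier_test(mixed), "mix taxa")
})

test_that("noise-free posteriors predict exactly on the regression line", {
  w <- imputation_world(seed = 3, sigma2_true = 0)
  beta <- c(`(Intercept)` = 0, mc2 = 0.9, brain = 0.12)
  ps <- pgls_posterior(matrix(beta, 50, 3, byrow = TRUE,
                              dimnames = list(NULL, names(beta))),
                       sigma2 = 1e-18, lambda = 0.85, tree_id = 1L)
  pd <- predictive_draws(ps, w$tree, w$table, w$spec, w$target)
  x_t <- c(1, w$table$mc2[w$table$species == w$target],
           w$table$brain[w$table$species == w$target])
  expect_equal(pd$draws, rep(sum(x_t * beta), 50), tolerance = 1e-6)
  expect_equal(pd$observed, sum(x_t * beta), tolerance = 1e-12)
})

test_that("lambda = 0 removes phylogenetic borrowing", {
  w <- imputation_world(seed = 4)
  beta <- c(`(Intercept)` = 0.1, mc2 = 0.9, brain = 0.12)
  s2 <- 0.04
  set.seed(42)
  ps <- pgls_posterior(matrix(beta, 4e4, 3, byrow = TRUE,
                              dimnames = list(NULL, names(beta))),
                       sigma2 = s2, lambda = 0, tree_id = 1L)
  pd <- predictive_draws(ps, w$tree, w$table, w$spec, w$target)
  x_t <- c(1, w$table$mc2[w$table$species == w$target],
           w$table$brain[w$table$species == w$target])
  v_tt <- phylo_vcv(w$tree)[w$target, w$target]
  expect_equal(mean(pd$draws), sum(x_t * beta),
               tolerance = 4 * sqrt(s2 * v_tt / 4e4) / abs(sum(x_t * beta)))
  expect_equal(var(pd$draws), s2 * v_tt,
               tolerance = 4 * sqrt(2 / 4e4))
})

test_that("predictive moments match brute-force joint-MVN conditioning", {
  w <- imputation_world(seed = 5)
  beta <- c(`(Intercept)` = 0.05, mc2 = 0.85, brain = 0.1)
  s2 <- 0.03
  lam <- 0.7
  N <- 2e4
  set.seed(7)
  ps <- pgls_posterior(matrix(beta, N, 3, byrow = TRUE,
                              dimnames = list(NULL, names(beta))),
                       sigma2 = s2, lambda = lam, tree_id = 1L)
  pd <- predictive_draws(ps, w$tree, w$table, w$spec, w$target)

  # oracle: condition the dense joint normal directly with solve()
  des <- build_design(w$table, w$spec,
                      taxa_order = setdiff(w$tree$tip.label, w$target))
  ord <- c(des$taxa, w$target)
  Vl <- lambda_transform(phylo_vcv(w$tree, taxa_order = ord), lam)
  n_o <- length(des$taxa)
  Voo <- Vl[1:n_o, 1:n_o]
  vot <- Vl[1:n_o, n_o + 1]
  x_t <- c(1, w$table$mc2[w$table$species == w$target],
           w$table$brain[w$table$species == w$target])
  mu_or <- sum(x_t * beta) +
    as.numeric(t(vot) %*% solve(Voo) %*% (des$y - des$X %*% beta))
  var_or <- s2 * as.numeric(Vl[n_o + 1, n_o + 1] - t(vot) %*% solve(Voo) %*% vot)

  expect_equal(mean(pd$draws), mu_or, tolerance = 3 * sqrt(var_or / N) / abs(mu_or))
  expect_equal(var(pd$draws), var_or, tolerance = 3 * sqrt(2 / N))
})

test_that("a target inside the fitting set is a contract violation", {
  w <- imputation_world(seed = 6)
  spec_bad <- model_spec("mc1", c("mc2", "brain"))  # no exclusion
  ps <- pgls_posterior(matrix(0, 10, 3,
                              dimnames = list(NULL, c("(Intercept)", "mc2", "brain"))),
                       sigma2 = 1, lambda = 1)
  expect_error(predictive_draws(ps, w$tree, w$table, spec_bad, w$target),
               "contract violation")
})

test_that("per-tree flag rate increases with the injected shift", {
  # one fitted world; shift the target's observed value by 0..4 predictive SDs
  w <- imputation_world(seed = 8)
  des <- build_design(w$table, w$spec,
                      taxa_order = setdiff(w$tree$tip.label, w$target))
  V <- phylo_vcv(prune_to_taxa(w$tree, des$taxa), taxa_order = des$taxa)
  ps <- suppressWarnings(      # tiny 5-taxon world: acceptance-rate warnings expected
    sample_posterior(des$y, des$X, V, quick_cfg(seed = 2, draws = 100),
                     tree_id = 1L)
  )
  base <- predictive_draws(ps, w$tree, w$table, w$spec, w$target)
  sd_pred <- sd(base$draws)
  tails <- vapply(c(0, 1, 2, 4), function(k) {
    pd <- base
    pd$observed <- median(base$draws) + k * sd_pred
    tail_mass(pd)
  }, 0)
  expect_true(all(diff(tails) <= 0))
  expect_lt(tails[4], 0.05)
})
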