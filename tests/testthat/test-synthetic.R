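test_that("simulate_tree yields deterministic unit-depth ultrametric Yule trees", {
  tr2 <- simulate_tree(2, seed = 1)
  d <- ape::node.depth.edgelength(tr2)[1:2]
  expect_equal(d, c(1, 1))

  tr <- simulate_tree(37, seed = 10)
  depths <- ape::node.depth.edgelength(tr)[1:37]
  expect_true(all(abs(depths - 1) < 1e-12))

  expect_identical(ape::write.tree(simulate_tree(15, seed = 3)),
                   ape::write.tree(simulate_tree(15, seed = 3)))
  expect_false(identical(ape::write.tree(simulate_tree(15, seed = 3)),
                         ape::write.tree(simulate_tree(15, seed = 4))))
})

test_that("jitter_tree_sample perturbs branch lengths and topology as asked", {
  tr <- simulate_tree(20, seed = 2)

  none <- jitter_tree_sample(tr, k = 4, jitter_sd = 0, n_nni = 0, seed = 1)
  expect_length(none, 4)
  for (t in unclass(none)) expect_identical(ape::write.tree(t), ape::write.tree(tr))

  js <- jitter_tree_sample(tr, k = 10, jitter_sd = 0.1, n_nni = 2, seed = 1)
  expect_length(js, 10)
  # tree 1 is the unmodified original
  expect_identical(ape::write.tree(js[[1]]), ape::write.tree(tr))
  # NNI moves change topology: Robinson-Foulds distance (independent routine) > 0
  rf <- vapply(unclass(js)[-1], function(t) phangorn::RF.dist(tr, t), 0)
  expect_true(all(rf > 0))
  # branch lengths jittered but taxa intact
  for (t in unclass(js)[-1]) expect_setequal(t$tip.label, tr$tip.label)
})

test_that("noise-free traits are exactly linear in the predictors", {
  tr <- simulate_tree(30, seed = 4)
  sc <- simulation_scenario(n_taxa = 30, sigma2_true = 0, seed = 4)
  tab <- simulate_traits(tr, sc)
  fit <- lm(mc1 ~ mc2 + brain, data = tab)
  expect_equal(unname(coef(fit)), c(0, 0.9, 0.12), tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-12)
})

test_that("residuals have the lambda-scaled Brownian covariance (Monte Carlo)", {
  tr <- simulate_tree(25, seed = 6)
  sc <- simulation_scenario(n_taxa = 25, sigma2_true = 0.01, lambda_true = 0.6,
                            seed = 6)
  V_target <- 0.01 * lambda_transform(phylo_vcv(tr), 0.6)
  R <- 600
  eps <- matrix(NA_real_, R, 25)
  X_true <- NULL
  for (r in 1:R) {
    tab <- simulate_traits(tr, sc, seed = 5000 + r)
    eps[r, ] <- tab$mc1 - (0.9 * tab$mc2 + 0.12 * tab$brain)
  }
  emp <- cov(eps)
  se <- sqrt((outer(diag(V_target), diag(V_target)) + V_target^2) / R)
  within <- abs(emp - V_target) <= 3 * se
  # allow the usual multiple-testing leakage past 3 SE
  expect_gt(mean(within), 0.98)
})

test_that("the liability threshold delivers the target tool-use frequency on average", {
  counts <- vapply(1:20, function(s) {
    tr <- simulate_tree(95, seed = 100 + s)
    tab <- simulate_traits(tr, simulation_scenario(n_taxa = 95, seed = 100 + s))
    sum(tab$tool_any)
  }, 0L)
  expect_gte(mean(counts), 24)
  expect_lte(mean(counts), 32)
  expect_true(all(tabulate(counts) >= 0))  # counts vary but stay positive
  expect_true(all(counts > 0 & counts < 95))
})

test_that("outlier taxa receive the response shift, directly or via the driver", {
  tr <- simulate_tree(20, seed = 8)
  targets <- tr$tip.label[1:3]
  base <- simulate_traits(tr, simulation_scenario(n_taxa = 20, sigma2_true = 0, seed = 8))
  direct <- simulate_traits(tr, simulation_scenario(
    n_taxa = 20, sigma2_true = 0, outlier_taxa = targets, outlier_shift = 0.15,
    seed = 8))
  idx <- match(targets, base$species)
  expect_equal(direct$mc1[idx] - base$mc1[idx], rep(0.15, 3))
  expect_equal(direct$mc1[-idx], base$mc1[-idx])
  expect_equal(direct$brain, base$brain)

  driven <- simulate_traits(tr, simulation_scenario(
    n_taxa = 20, sigma2_true = 0, outlier_taxa = targets, outlier_shift = 0.15,
    outlier_driver = "brain", seed = 8))
  expect_equal(driven$mc1[idx] - base$mc1[idx], rep(0.15, 3))
  expect_equal(driven$brain[idx] - base$brain[idx], rep(0.15 / 0.12, 3))
})

test_that("the study fixture has the study's shape and is deterministic", {
  fx <- make_study_fixture(seed = 5, tree_sample_size = 8)
  expect_equal(nrow(fx$traits), 95)
  expect_length(fx$trees, 8)
  expect_length(fx$hominin_taxa, 6)
  expect_true(ape::is.monophyletic(fx$tree, fx$hominin_taxa))
  expect_equal(sum(fx$traits$tool_any), 28)
  expect_equal(sum(!is.na(fx$traits$neocortex)), 49)
  expect_equal(sum(!is.na(fx$traits$cerebellum)), 49)
  expect_equal(sum(fx$traits$is_hominin), 6)
  expect_equal(sum(fx$traits$is_hominin & fx$traits$is_extant), 1)
  # tool flags only among extant taxa; hominin fossils never tool users
  expect_true(all(fx$traits$is_extant[fx$traits$tool_any]))
  expect_true(all(fx$traits$tool_any[fx$traits$tool_true]))
  expect_true(all(fx$traits$tool_any[fx$traits$tool_manufacture]))

  fx2 <- make_study_fixture(seed = 5, tree_sample_size = 8)
  expect_identical(fx$traits, fx2$traits)
  expect_identical(purrr::map_chr(unclass(fx$trees), ape::write.tree),
                   purrr::map_chr(unclass(fx2$trees), ape::write.tree))
})

test_that("fixture files round-trip through the pipeline readers", {
  dir <- withr::local_tempdir()
  fx <- make_study_fixture(seed = 6, tree_sample_size = 3, dir = dir)
  expect_true(all(file.exists(file.path(dir, c("traits.csv", "trees.nwk", "scenario.yaml")))))

  tab <- load_trait_table(file.path(dir, "traits.csv"))
  expect_equal(tab$mc1, fx$traits$mc1, tolerance = 1e-12)
  expect_equal(tab$brain, fx$traits$brain, tolerance = 1e-12)
  expect_identical(tab$tool_any, fx$traits$tool_any)

  ts <- read_tree_sample(file.path(dir, "trees.nwk"))
  expect_length(ts, 3)
  expect_setequal(ts[[1]]$tip.label, fx$traits$species)

  sc <- yaml::read_yaml(file.path(dir, "scenario.yaml"))
  expect_equal(sc$n_taxa, 95)
  expect_equal(sc$outlier_driver, "brain")
})
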