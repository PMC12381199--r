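#' Scenario for the synthetic comparative dataset
#'
#' Bundles every knob of the generative model the PGLS assumes: a linear
#' regression on log-scale traits with residuals drawn from a lambda-scaled
#' Brownian covariance, a binary tool-use covariate with a fixed expected
#' frequency, and an optional set of taxa whose response is shifted upward
#' (emulating a clade of long-thumbed taxa the regression cannot explain).
#' Defaults mirror the study conditions: 95 taxa, slopes of 0.9 (finger) and
#' 0.12 (brain), lambda 0.85, about 28/95 tool users, a 100-tree sample, and a
#' +0.15 log-unit outlier shift.
#'
#' The shift can be applied two ways. With `outlier_driver = NULL` it is added
#' directly to the response after the regression. With a driver (e.g.
#' `"brain"`), the driver trait itself is elevated by `outlier_shift /
#' beta_true[driver]` before the response is computed, so the response rises by
#' the same `outlier_shift` — but *through* the regression. Only driver-mediated
#' shifts vanish when the driver is included as a covariate, which is the
#' structure the outlier analyses probe (taxa anomalous under a reduced model
#' yet conforming under the full one).
#'
#' @param n_taxa Number of taxa.
#' @param beta_true Named coefficient vector; the first element is the
#'   intercept, remaining names must be generated trait columns (e.g. `mc2`,
#'   `brain`, `tool_any`).
#' @param sigma2_true Residual scale of the response around the regression, in
#'   squared log10 units (default 0.0015, i.e. a residual sd of ~0.039).
#' @param lambda_true Pagel's lambda of the residuals.
#' @param outlier_taxa Taxon labels whose response is shifted by `outlier_shift`.
#' @param outlier_shift Response shift in log10 units.
#' @param outlier_driver `NULL` for a direct response shift, or the name of a
#'   predictor in `beta_true` that mediates it (see Details).
#' @param tool_fraction Expected share of tool users.
#' @param tree_sample_size Number of trees in the jittered sample.
#' @param jitter_sd Lognormal sd of the per-branch length multipliers in the
#'   tree sample.
#' @param n_nni Nearest-neighbour interchanges applied to each jittered tree.
#' @param seed Integer seed; identical scenario + seed reproduces the dataset
#'   exactly.
#' @return A `simulation_scenario` list.
#' @export
simulation_scenario <- function(n_taxa = 95,
                                beta_true = c("(Intercept)" = 0, mc2 = 0.9, brain = 0.12),
                                sigma2_true = 0.0015,
                                lambda_true = 0.85,
                                outlier_taxa = character(),
                                outlier_shift = 0.15,
                                outlier_driver = NULL,
                                tool_fraction = 28 / 95,
                                tree_sample_size = 100,
                                jitter_sd = 0.15,
                                n_nni = 8,
                                seed = 1L) {
  stopifnot(n_taxa >= 2, sigma2_true >= 0,
            lambda_true >= 0, lambda_true <= 1,
            tool_fraction > 0, tool_fraction < 1,
            tree_sample_size >= 1, jitter_sd >= 0, n_nni >= 0)
  if (is.null(names(beta_true)) || any(!nzchar(names(beta_true)))) {
    abort("beta_true must be a fully named vector (intercept first)")
  }
  if (!is.null(outlier_driver)) {
    if (!outlier_driver %in% names(beta_true)[-1]) {
      abort("outlier_driver must name a predictor in beta_true")
    }
    if (beta_true[outlier_driver] == 0) {
      abort("outlier_driver has a zero coefficient; the shift cannot be mediated")
    }
  }
  structure(
    list(n_taxa = as.integer(n_taxa), beta_true = beta_true,
         sigma2_true = sigma2_true, lambda_true = lambda_true,
         outlier_taxa = as.character(outlier_taxa),
         outlier_shift = outlier_shift, outlier_driver = outlier_driver,
         tool_fraction = tool_fraction,
         tree_sample_size = as.integer(tree_sample_size),
         jitter_sd = jitter_sd, n_nni = n_nni, seed = as.integer(seed)),
    class = "simulation_scenario"
  )
}

#' Simulate an ultrametric pure-birth tree
#'
#' A Yule tree on `n_taxa` tips, rescaled to unit root-to-tip depth so trait
#' variances are directly interpretable as per-total-time rates.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed; the same seed yields an identical tree.
#' @return A `phylo` with tips labelled `t1..tn` and depth 1.
#' @export
simulate_tree <- function(n_taxa, seed = 1L) {
  stopifnot(n_taxa >= 2)
  set.seed(as.integer(seed))
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr
}

#' Build a jittered tree sample from one reference tree
#'
#' Emulates a sample of plausible dated phylogenies: each tree after the first
#' gets independent lognormal(0, `jitter_sd`) multipliers on every branch and
#' `n_nni` random nearest-neighbour interchanges; tree 1 is the unmodified
#' original.
#'
#' @param tree Reference `phylo`.
#' @param k Sample size (>= 1).
#' @param jitter_sd Lognormal sd of branch-length multipliers (0 = none).
#' @param n_nni Number of NNI moves per tree (0 = topology unchanged).
#' @param seed Integer seed.
#' @return A `tree_sample` of `k` trees.
#' @export
jitter_tree_sample <- function(tree, k = 100, jitter_sd = 0.15, n_nni = 8, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), k >= 1, jitter_sd >= 0, n_nni >= 0)
  set.seed(as.integer(seed))
  trees <- vector("list", k)
  trees[[1]] <- tree
  for (i in seq_len(k)[-1]) {
    ti <- tree
    if (jitter_sd > 0) {
      ti$edge.length <- ti$edge.length *
        rlnorm(length(ti$edge.length), 0, jitter_sd)
    }
    if (n_nni > 0) {
      ti <- phangorn::rNNI(ti, moves = n_nni)
    }
    trees[[i]] <- ti
  }
  as_tree_sample(trees)
}

# one multivariate-normal draw with covariance sig2 * V, via Cholesky
rmvn_tree <- function(V, mean = 0, sig2 = 1) {
  n <- nrow(V)
  as.numeric(mean + t(chol(sig2 * V)) %*% rnorm(n))
}

#' Simulate a trait table on a tree
#'
#' Implements the generative model the PGLS assumes. Predictors (log finger
#' lengths, log brain mass, log brain-region volumes) evolve as Brownian motion
#' on the tree; a binary tool-use covariate comes from thresholding an
#' independent Brownian liability at the `(1 - tool_fraction)` quantile of its
#' marginal distribution; the response is `X beta_true` plus noise from
#' `N(0, sigma2_true * V(lambda_true))`; taxa in `scenario$outlier_taxa` get an
#' extra `outlier_shift` on the response.
#'
#' All values are on the log10 scale the analysis uses. Columns `mc3`-`mc5` are
#' the finger trait plus small Brownian perturbations, so alternative-digit
#' model variants see realistic, strongly correlated measurements.
#'
#' @param tree A `phylo` whose tips are the taxa.
#' @param scenario A [simulation_scenario()]; `scenario$n_taxa` must match the
#'   tree.
#' @param seed Seed (defaults to the scenario's).
#' @return A trait-table tibble (species, mc1..mc5, brain, neocortex,
#'   cerebellum, tool and status flags) with the tool liability in the
#'   `tool_liability` attribute.
#' @export
simulate_traits <- function(tree, scenario = simulation_scenario(n_taxa = length(tree$tip.label)),
                            seed = scenario$seed) {
  stopifnot(inherits(tree, "phylo"), inherits(scenario, "simulation_scenario"))
  n <- length(tree$tip.label)
  if (n != scenario$n_taxa) {
    abort("tree size does not match scenario$n_taxa")
  }
  bad <- setdiff(scenario$outlier_taxa, tree$tip.label)
  if (length(bad) > 0) {
    abort(paste0("outlier taxa not on the tree: ", paste(bad, collapse = ", ")))
  }
  set.seed(as.integer(seed))
  V <- phylo_vcv(tree)
  depth <- mean(diag(V))

  # Brownian predictors, log10 scale (means/rates chosen to span realistic
  # primate ranges: metacarpals ~5-80 mm, brains of a few g to a few hundred g
  # before any driver-mediated elevation, regions in cm^3)
  mc2 <- rmvn_tree(V, mean = 1.2, sig2 = 0.09)
  brain <- rmvn_tree(V, mean = 1.5, sig2 = 0.10)
  neocortex <- rmvn_tree(V, mean = 1.3, sig2 = 0.20)
  cerebellum <- rmvn_tree(V, mean = 0.9, sig2 = 0.20)
  mc3 <- mc2 + rmvn_tree(V, 0, 0.02)
  mc4 <- mc2 + rmvn_tree(V, 0, 0.02)
  mc5 <- mc2 + rmvn_tree(V, 0, 0.02)

  liability <- rmvn_tree(V, 0, 1)
  tool_any <- liability > qnorm(1 - scenario$tool_fraction, 0, sqrt(depth))
  tool_true <- liability > qnorm(1 - 0.6 * scenario$tool_fraction, 0, sqrt(depth))
  tool_manufacture <- liability > qnorm(1 - 0.3 * scenario$tool_fraction, 0, sqrt(depth))

  traits <- list(mc2 = mc2, mc3 = mc3, mc4 = mc4, mc5 = mc5, brain = brain,
                 neocortex = neocortex, cerebellum = cerebellum,
                 tool_any = as.numeric(tool_any),
                 tool_true = as.numeric(tool_true),
                 tool_manufacture = as.numeric(tool_manufacture))
  bnames <- names(scenario$beta_true)[-1]
  missing <- setdiff(bnames, names(traits))
  if (length(missing) > 0) {
    abort(paste0("beta_true names a trait the generator does not produce: ",
                 paste(missing, collapse = ", ")))
  }
  shift_idx <- match(scenario$outlier_taxa, tree$tip.label)
  if (!is.null(scenario$outlier_driver)) {
    drv <- scenario$outlier_driver
    traits[[drv]][shift_idx] <- traits[[drv]][shift_idx] +
      scenario$outlier_shift / scenario$beta_true[drv]
  }
  X <- cbind(1, do.call(cbind, traits[bnames]))
  y <- as.numeric(X %*% scenario$beta_true)
  if (scenario$sigma2_true > 0) {
    y <- y + rmvn_tree(lambda_transform(V, scenario$lambda_true),
                       0, scenario$sigma2_true)
  }
  if (is.null(scenario$outlier_driver)) {
    y[shift_idx] <- y[shift_idx] + scenario$outlier_shift
  }

  out <- tibble(
    species = tree$tip.label,
    mc1 = y, mc2 = mc2, mc3 = mc3, mc4 = mc4, mc5 = mc5,
    brain = traits$brain, neocortex = neocortex, cerebellum = cerebellum,
    tool_any = tool_any, tool_true = tool_true,
    tool_manufacture = tool_manufacture,
    tool_single_individual = FALSE, tool_captive_only = FALSE,
    is_hominin = tree$tip.label %in% scenario$outlier_taxa,
    is_extant = TRUE
  )
  attr(out, "tool_liability") <- setNames(liability, tree$tip.label)
  attr(out, "scenario") <- scenario
  out
}

#' Generate the packaged study-shaped fixture
#'
#' One call producing a dataset with the shape of the study: 95 taxa on a
#' unit-depth Yule tree, a 6-taxon monophyletic "hominin-analogue" clade whose
#' response (log thumb length) sits +0.15 log units above the finger-only
#' relationship — mediated by an elevated brain trait, so the clade conforms
#' again once brain size enters the model (five fossil members plus one extant
#' member standing in for modern humans),
#' exactly 28 tool users among extant taxa (the extant clade member always one
#' of them), brain-region volumes retained for a 49-taxon subset containing that
#' member, and a sample of `tree_sample_size` jittered trees whose first tree is
#' the generating one.
#'
#' @param seed Integer seed; the fixture is byte-identical across runs with the
#'   same seed.
#' @param dir Optional directory; when given, writes `traits.csv` (raw
#'   measurement scale, the schema [load_trait_table()] reads), `trees.nwk`
#'   (multi-tree newick) and `scenario.yaml`.
#' @param tree_sample_size,jitter_sd,n_nni Tree-sample settings passed to the
#'   scenario.
#' @return A list: `tree` (the generating `phylo`), `trees` (`tree_sample`),
#'   `traits` (log-scale trait tibble), `scenario`, and `hominin_taxa`.
#' @export
make_study_fixture <- function(seed = 1L, dir = NULL, tree_sample_size = 100,
                               jitter_sd = 0.15, n_nni = 8) {
  seed <- as.integer(seed)
  # find a seed offset whose Yule tree contains an exactly-6-tip clade
  tree <- NULL
  clade <- NULL
  for (off in 0:200) {
    cand <- simulate_tree(95, seed = (seed + off * 1009L) %% 2000000000L)
    parts <- ape::prop.part(cand)
    sizes <- lengths(parts)
    hit <- which(sizes == 6)
    if (length(hit) > 0) {
      tree <- cand
      clade <- attr(parts, "labels")[parts[[hit[1]]]]
      break
    }
  }
  if (is.null(tree)) abort("could not find a 6-taxon clade; try another seed")

  scenario <- simulation_scenario(
    n_taxa = 95, outlier_taxa = clade, outlier_driver = "brain",
    tree_sample_size = tree_sample_size,
    jitter_sd = jitter_sd, n_nni = n_nni, seed = seed
  )
  traits <- simulate_traits(tree, scenario, seed = seed)
  liability <- attr(traits, "tool_liability")

  # clade member playing the extant hominin; the rest are fossils
  human <- clade[1]
  traits$is_extant[traits$species %in% setdiff(clade, human)] <- FALSE

  # exactly 28 tool users among extant non-hominins plus the extant hominin
  eligible <- traits$species[traits$is_extant & !traits$is_hominin]
  users <- c(human, eligible[order(liability[eligible], decreasing = TRUE)][1:27])
  rank_users <- users[order(liability[users], decreasing = TRUE)]
  traits$tool_any <- traits$species %in% users
  traits$tool_true <- traits$species %in% rank_users[1:15]
  traits$tool_manufacture <- traits$species %in% unique(c(human, rank_users[1:8]))
  traits$tool_single_individual <- traits$species %in% rank_users[25:27]
  traits$tool_captive_only <- traits$species %in% rank_users[22:24]

  # brain-region volumes only for a 49-taxon subset that includes the extant hominin
  set.seed(seed + 7L)
  region_taxa <- c(human, sample(setdiff(eligible, human), 48))
  mask <- !traits$species %in% region_taxa
  traits$neocortex[mask] <- NA_real_
  traits$cerebellum[mask] <- NA_real_

  trees <- jitter_tree_sample(tree, k = tree_sample_size,
                              jitter_sd = jitter_sd, n_nni = n_nni,
                              seed = seed + 11L)

  fixture <- list(tree = tree, trees = trees, traits = traits,
                  scenario = scenario, hominin_taxa = clade)
  if (!is.null(dir)) {
    write_fixture(fixture, dir)
  }
  fixture
}

# write fixture files in the formats the pipeline reads
write_fixture <- function(fixture, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  raw <- fixture$traits
  for (col in c("mc1", "mc2", "mc3", "mc4", "mc5", "brain",
                "neocortex", "cerebellum")) {
    raw[[col]] <- 10^raw[[col]]
  }
  attr(raw, "tool_liability") <- NULL
  attr(raw, "scenario") <- NULL
  readr::write_csv(raw, file.path(dir, "traits.csv"))
  ape::write.tree(structure(unclass(fixture$trees), class = "multiPhylo"),
                  file = file.path(dir, "trees.nwk"))
  sc <- fixture$scenario
  yaml::write_yaml(
    list(n_taxa = sc$n_taxa, beta_true = as.list(sc$beta_true),
         sigma2_true = sc$sigma2_true, lambda_true = sc$lambda_true,
         outlier_taxa = sc$outlier_taxa, outlier_shift = sc$outlier_shift,
         outlier_driver = sc$outlier_driver,
         tool_fraction = sc$tool_fraction,
         tree_sample_size = sc$tree_sample_size, jitter_sd = sc$jitter_sd,
         n_nni = sc$n_nni, seed = sc$seed),
    file.path(dir, "scenario.yaml")
  )
  invisible(dir)
}
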