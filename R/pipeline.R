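#' Taxa eligible for analysis
#'
#' The analysis set for a model: species present in every tree of the sample
#' and carrying non-missing values for the response and all predictors (the
#' spec's exclusions are applied on top). Keeping the set fixed across trees
#' makes per-tree results comparable.
#'
#' @param table Trait table (log scale).
#' @param tree_sample A `tree_sample`.
#' @param spec A [model_spec()].
#' @return Character vector of analysis taxa, in tree-1 tip order.
#' @export
analysis_taxa <- function(table, tree_sample, spec) {
  common <- Reduce(intersect, purrr::map(unclass(tree_sample), "tip.label"))
  ord <- unclass(tree_sample)[[1]]$tip.label
  candidates <- ord[ord %in% intersect(common, table$species)]
  des <- build_design(table, spec, taxa_order = candidates)
  des$taxa
}

# deterministic per-tree seed, kept below 2^31
tree_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 131 + i * 9973) %% 2147483647)
}

#' Fit one model over every tree of a sample
#'
#' For each tree: prune to the analysis taxa, build the phylogenetic covariance,
#' run the MCMC, and summarise; then aggregate the per-tree summaries into the
#' cross-tree verdict. Per-tree chains get seeds derived deterministically from
#' `cfg$seed` and the tree index, so reruns (sequential or not) are identical.
#'
#' @param spec A [model_spec()].
#' @param table Trait table (log scale).
#' @param tree_sample A `tree_sample` (or `multiPhylo`).
#' @param cfg An [mcmc_config()]; its seed is the master seed.
#' @param sig_level,tree_fraction Passed to [aggregate_over_trees()].
#' @return A `cross_tree_summary`; attributes `per_tree` (tibble of all per-tree
#'   term summaries), `n_taxa` and `taxa` record the analysis set.
#' @export
run_model <- function(spec, table, tree_sample, cfg = mcmc_config(),
                      sig_level = 0.05, tree_fraction = 0.95) {
  stopifnot(inherits(spec, "model_spec"), inherits(cfg, "mcmc_config"))
  trees <- unclass(tree_sample)
  taxa <- analysis_taxa(table, tree_sample, spec)
  des <- build_design(table, spec, taxa_order = taxa)

  fits <- purrr::imap(trees, function(tree, i) {
    res <- tryCatch({
      sub <- prune_to_taxa(tree, des$taxa)
      V <- phylo_vcv(sub, taxa_order = des$taxa)
      cfg_i <- cfg
      cfg_i$seed <- tree_seed(cfg$seed, i)
      ps <- sample_posterior(des$y, des$X, V, cfg_i, tree_id = as.integer(i))
      summarize_fit(ps, model = spec$label)
    }, error = function(e) {
      abort(paste0("model '", spec$label, "' failed on tree ", i, ": ",
                   conditionMessage(e)))
    })
    res
  })

  out <- aggregate_over_trees(fits, sig_level = sig_level,
                              tree_fraction = tree_fraction)
  attr(out, "per_tree") <- dplyr::bind_rows(fits)
  attr(out, "n_taxa") <- length(des$taxa)
  attr(out, "taxa") <- des$taxa
  attr(out, "dropped") <- des$dropped
  out
}

#' Phylogenetic outlier analysis for a set of target taxa
#'
#' Refits the model per tree with all `targets` (jointly) excluded from the
#' fitting set, imputes each target's response from the fitted parameters and
#' its tree position (conditioning only on observed, non-target taxa), and
#' applies the multi-tree outlier rule to each target.
#'
#' @param spec A [model_spec()] (targets are added to its exclusions).
#' @param table Trait table (log scale).
#' @param tree_sample A `tree_sample`.
#' @param targets Character vector of taxa to test; each needs predictor values.
#' @param cfg An [mcmc_config()].
#' @param threshold,tree_fraction,correction Passed to [outlier_test()].
#' @return A tibble with one row per target (`taxon`, `n_trees`,
#'   `fraction_trees_below_threshold`, `is_outlier`); per-tree tail masses and
#'   predictive intervals are in the `per_tree` attribute.
#' @export
run_outlier_analysis <- function(spec, table, tree_sample, targets,
                                 cfg = mcmc_config(), threshold = 0.05,
                                 tree_fraction = 0.95,
                                 correction = c("add-one", "none")) {
  correction <- match.arg(correction)
  stopifnot(length(targets) >= 1)
  fit_spec <- spec
  fit_spec$exclude <- unique(c(spec$exclude, targets))

  trees <- unclass(tree_sample)
  taxa <- analysis_taxa(table, tree_sample, fit_spec)
  des <- build_design(table, fit_spec, taxa_order = taxa)
  missing_target <- setdiff(targets, intersect(table$species, trees[[1]]$tip.label))
  if (length(missing_target) > 0) {
    abort(paste0("targets absent from table or trees: ",
                 paste(missing_target, collapse = ", ")))
  }

  pds <- purrr::imap(trees, function(tree, i) {
    sub_fit <- prune_to_taxa(tree, des$taxa)
    V <- phylo_vcv(sub_fit, taxa_order = des$taxa)
    cfg_i <- cfg
    cfg_i$seed <- tree_seed(cfg$seed, i)
    ps <- sample_posterior(des$y, des$X, V, cfg_i, tree_id = as.integer(i))
    purrr::map(setNames(targets, targets), function(tg) {
      predictive_draws(ps, prune_to_taxa(tree, c(des$taxa, tg)),
                       table, fit_spec, tg)
    })
  })

  results <- purrr::map(setNames(targets, targets), function(tg) {
    outlier_test(purrr::map(pds, tg), threshold = threshold,
                 tree_fraction = tree_fraction, correction = correction)
  })
  out <- dplyr::bind_rows(results)
  structure(out,
            class = c("outlier_result", class(tibble())),
            per_tree = dplyr::bind_rows(purrr::map(results, attr, "per_tree")),
            threshold = threshold, tree_fraction = tree_fraction,
            model = spec$label, n_taxa = length(des$taxa))
}

#' The study's named model variants
#'
#' Builds the model specifications the full suite knows about, resolved against
#' a trait table: the finger-only allometry (thumb on finger length), the
#' whole-brain model adding log brain mass, their hominin-excluded versions,
#' tool-use models (finger + brain + a tool indicator + its interaction with
#' brain, testing an intercept and slope difference for tool users) under three
#' indicator definitions and two record-quality exclusions, the brain-regions
#' model (neocortex and cerebellum volumes jointly), and alternative-digit
#' sensitivity variants using MC3-MC5 as the finger measure.
#'
#' @param table Trait table (used to resolve flag-based exclusions).
#' @param digit Finger-length column for the core variants (default `"mc2"`).
#' @return Named list of [model_spec()] objects.
#' @export
study_model_specs <- function(table, digit = "mc2") {
  hominins <- table$species[table$is_hominin]
  extant_hominins <- table$species[table$is_hominin & table$is_extant]
  single <- table$species[table$tool_single_individual]
  captive <- table$species[table$tool_captive_only]

  tool_spec <- function(col, exclude = character()) {
    model_spec("mc1", c(digit, "brain", col),
               interactions = list(c("brain", col)),
               exclude = exclude,
               label = paste0("mc1 ~ ", digit, " + brain * ", col,
                              if (length(exclude)) " (records excluded)" else ""))
  }

  specs <- list(
    finger_only = model_spec("mc1", digit),
    finger_only_no_hominins = model_spec(
      "mc1", digit, exclude = hominins,
      label = paste0("mc1 ~ ", digit, " (no hominins)")),
    whole_brain = model_spec("mc1", c(digit, "brain")),
    whole_brain_no_hominins = model_spec(
      "mc1", c(digit, "brain"), exclude = hominins,
      label = paste0("mc1 ~ ", digit, " + brain (no hominins)")),
    tool_any = tool_spec("tool_any"),
    tool_true = tool_spec("tool_true"),
    tool_manufacture = tool_spec("tool_manufacture"),
    tool_any_no_single = tool_spec("tool_any", exclude = single),
    tool_any_no_captive = tool_spec("tool_any", exclude = captive),
    brain_regions = model_spec("mc1", c(digit, "neocortex", "cerebellum")),
    brain_regions_no_human = model_spec(
      "mc1", c(digit, "neocortex", "cerebellum"), exclude = extant_hominins,
      label = paste0("mc1 ~ ", digit, " + neocortex + cerebellum (no extant hominins)"))
  )
  for (d in c("mc3", "mc4", "mc5")) {
    specs[[paste0("finger_only_", d)]] <- model_spec("mc1", d)
    specs[[paste0("whole_brain_", d)]] <- model_spec("mc1", c(d, "brain"))
  }
  specs
}

#' Run the full model suite over a tree sample
#'
#' Executes every requested model variant and the requested outlier analyses
#' (hominin taxa predicted from models fitted on all non-hominin taxa), and
#' returns everything with a provenance block sufficient to reproduce any
#' number in the report.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   * `traits`: trait tibble (log scale) or path to a raw-scale CSV for
#'     [load_trait_table()];
#'   * `trees`: a `tree_sample` or path for [read_tree_sample()];
#'   * `variants`: character vector of variant names from [study_model_specs()]
#'     (default: finger-only, whole-brain, their no-hominin versions, tool_any,
#'     brain_regions);
#'   * `outlier_models`: variants to run the outlier analysis under (default
#'     `c("finger_only", "whole_brain")`);
#'   * `targets`: taxa to test (default: all hominins in the table);
#'   * `seed`: master seed;
#'   * `mcmc`: named list of [mcmc_config()] overrides (e.g. a reduced
#'     schedule for simulation studies).
#' @return A `suite_report`: `models` (named `cross_tree_summary` list),
#'   `outliers` (named list of outlier tibbles) and `provenance`.
#' @export
run_suite <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  table <- config$traits
  if (is.character(table)) table <- load_trait_table(table)
  trees <- config$trees
  if (is.character(trees)) trees <- read_tree_sample(trees)
  if (is.null(table) || is.null(trees)) {
    abort("config must supply 'traits' and 'trees'")
  }
  variants <- config$variants %||%
    c("finger_only", "finger_only_no_hominins", "whole_brain",
      "whole_brain_no_hominins", "tool_any", "brain_regions")
  specs <- study_model_specs(table, digit = config$digit %||% "mc2")
  unknown <- setdiff(variants, names(specs))
  if (length(unknown) > 0) {
    abort(paste0("unknown model variant(s): ", paste(unknown, collapse = ", "),
                 "; available: ", paste(names(specs), collapse = ", ")))
  }
  outlier_models <- config$outlier_models %||% c("finger_only", "whole_brain")
  unknown <- setdiff(outlier_models, names(specs))
  if (length(unknown) > 0) {
    abort(paste0("unknown outlier model(s): ", paste(unknown, collapse = ", ")))
  }
  targets <- config$targets %||% table$species[table$is_hominin]
  seed <- as.integer(config$seed %||% 1L)
  mcmc_args <- config$mcmc %||% list()

  make_cfg <- function(block) {
    do.call(mcmc_config, utils::modifyList(mcmc_args, list(seed = block)))
  }

  models <- purrr::imap(setNames(variants, variants), function(v, nm) {
    idx <- match(v, names(specs))
    run_model(specs[[v]], table, trees, cfg = make_cfg(seed + idx * 37L))
  })
  outliers <- list()
  if (length(targets) > 0) {
    outliers <- purrr::map(setNames(outlier_models, outlier_models), function(v) {
      idx <- match(v, names(specs))
      run_outlier_analysis(specs[[v]], table, trees, targets,
                           cfg = make_cfg(seed + 5000L + idx * 37L))
    })
  }

  provenance <- list(
    seed = seed,
    n_trees = length(trees),
    n_taxa_by_model = purrr::map_int(models, attr, "n_taxa"),
    variants = variants,
    outlier_models = if (length(targets) > 0) outlier_models else character(),
    targets = targets,
    mcmc = mcmc_args,
    trait_checksum = rlang::hash(table),
    tree_checksum = rlang::hash(purrr::map_chr(unclass(trees), ape::write.tree)),
    config_hash = rlang::hash(list(variants, outlier_models, targets, seed, mcmc_args)),
    package_version = as.character(utils::packageVersion("bayespgls")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  structure(list(models = models, outliers = outliers, provenance = provenance),
            class = "suite_report")
}

#' @export
print.suite_report <- function(x, ...) {
  cat("<suite_report>", length(x$models), "model variant(s),",
      length(x$outliers), "outlier analysis(es) over",
      x$provenance$n_trees, "trees\n\n")
  for (nm in names(x$models)) {
    cat("--", nm, "(n =", attr(x$models[[nm]], "n_taxa"), ")\n")
    print(as_tibble(x$models[[nm]]))
  }
  for (nm in names(x$outliers)) {
    cat("-- outliers |", nm, "\n")
    print(as_tibble(x$outliers[[nm]]))
  }
  invisible(x)
}

#' @rdname run_suite
#' @param x A `suite_report`.
#' @param ... Unused.
#' @export
tidy.suite_report <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$models, function(m, nm) {
    dplyr::mutate(as_tibble(m), variant = nm, .before = 1)
  }))
}

#' Serialize a suite report
#'
#' Writes the cross-tree summaries and outlier verdicts as JSON, and the
#' per-tree term-level results as CSV, for audit and downstream rendering.
#'
#' @param report A `suite_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_suite_report <- function(report, dir) {
  stopifnot(inherits(report, "suite_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    list(
      models = purrr::map(report$models, ~ as.list(as_tibble(.x))),
      outliers = purrr::map(report$outliers, ~ as.list(as_tibble(.x))),
      provenance = report$provenance
    ),
    file.path(dir, "suite_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  per_tree <- dplyr::bind_rows(purrr::imap(report$models, function(m, nm) {
    dplyr::mutate(attr(m, "per_tree"), variant = nm, .before = 1)
  }))
  readr::write_csv(per_tree, file.path(dir, "per_tree_fits.csv"))
  if (length(report$outliers) > 0) {
    tails <- dplyr::bind_rows(purrr::imap(report$outliers, function(o, nm) {
      dplyr::mutate(attr(o, "per_tree"), variant = nm, .before = 1)
    }))
    readr::write_csv(tails, file.path(dir, "per_tree_imputation.csv"))
  }
  invisible(dir)
}
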