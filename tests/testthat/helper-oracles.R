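# Independent oracles and small fixtures used across test files.

# brute-force shared-path covariance: V[i,j] = (depth_i + depth_j - d_ij)/2,
# from patristic distances and root-to-tip depths (independent of ape::vcv)
bruteforce_vcv <- function(tree) {
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)[seq_len(n)]
  D <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
  V <- outer(depths, depths, "+") - D
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  V / 2
}

# dense multivariate-normal log-density via explicit inverse and determinant
dense_mvn_loglik <- function(y, mu, S) {
  n <- length(y)
  r <- y - mu
  as.numeric(-0.5 * (n * log(2 * pi) + determinant(S, logarithm = TRUE)$modulus +
                       t(r) %*% solve(S) %*% r))
}

# random non-ultrametric tree with positive branch lengths
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- runif(length(tr$edge.length), 0.1, 2)
  tr
}

# short MCMC schedule for unit tests
quick_cfg <- function(seed = 1, draws = 100, thin = 10, burn = 400,
                      replicates = 1, ...) {
  mcmc_config(iterations = draws * thin, thinning = thin, burn_in = burn,
              replicates = replicates, seed = seed, ...)
}

# predictive_distribution built directly from draws (for rule-level tests)
make_pd <- function(draws, observed, taxon = "tX", tree_id = 1L) {
  structure(list(taxon = taxon, tree_id = as.integer(tree_id),
                 draws = draws, observed = observed),
            class = "predictive_distribution")
}

# per-tree fit-summary tibble with chosen p_x values (for rule-level tests)
make_fits <- function(p_values, estimates = seq_along(p_values) * 0 + 0.88,
                      term = "slope", model = "toy") {
  fits <- lapply(seq_along(p_values), function(i) {
    out <- tibble::tibble(tree_id = i, term = term,
                          estimate = estimates[i], p_x = p_values[i])
    attr(out, "model") <- model
    out
  })
  fits
}
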