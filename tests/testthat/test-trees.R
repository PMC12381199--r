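test_that("read_tree_sample reads newick and nexus files in order", {
  tf <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1);", tf)
  ts <- read_tree_sample(tf)
  expect_length(ts, 1)
  expect_setequal(ts[[1]]$tip.label, c("A", "B"))

  multi <- withr::local_tempfile(fileext = ".nwk")
  set.seed(4)
  trees <- lapply(1:5, function(i) ape::rtree(4 + i))
  writeLines(vapply(trees, ape::write.tree, ""), multi)
  ts <- read_tree_sample(multi)
  expect_length(ts, 5)
  # file order preserved: tip counts increase by construction
  expect_equal(vapply(unclass(ts), function(t) length(t$tip.label), 0L), 5:9)

  nex <- withr::local_tempfile(fileext = ".nex")
  set.seed(8)
  same_taxa <- lapply(1:5, function(i) ape::rtree(6))
  ape::write.nexus(same_taxa, file = nex)
  tsn <- read_tree_sample(nex)
  expect_length(tsn, 5)
  # file order preserved: the i-th tree read matches the i-th tree written
  for (i in 1:5) {
    expect_true(ape::all.equal.phylo(tsn[[i]], same_taxa[[i]],
                                     use.edge.length = FALSE))
  }
})

test_that("read_tree_sample rejects malformed or empty input with a useful message", {
  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1", bad)
  expect_error(read_tree_sample(bad), "unclosed|malformed")

  noterm <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:1,B:1)", noterm)
  expect_error(read_tree_sample(noterm), "terminator")

  empty <- withr::local_tempfile(fileext = ".nwk")
  writeLines(character(), empty)
  expect_error(read_tree_sample(empty), "empty")

  expect_error(read_tree_sample(tempfile()), "not found")
})

test_that("taxon labels are whitespace-normalised on read", {
  tf <- withr::local_tempfile(fileext = ".nwk")
  writeLines("('A b':1,' C':1);", tf)
  ts <- read_tree_sample(tf)
  expect_setequal(ts[[1]]$tip.label, c("A_b", "C"))
})

test_that("pruning preserves path lengths between retained taxa", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  pr <- prune_to_taxa(tr, c("A", "C"))
  expect_equal(unname(ape::cophenetic.phylo(pr)["A", "C"]), 4)

  # identity prune
  full <- prune_to_taxa(tr, tr$tip.label)
  expect_equal(ape::cophenetic.phylo(full)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr)[tr$tip.label, tr$tip.label])

  expect_error(prune_to_taxa(tr, "A"), "at least 2")
  expect_error(prune_to_taxa(tr, c("A", "Z")), "Z")

  # property: random trees, random subsets, exact path conservation
  for (s in 1:20) {
    tr <- random_tree(12, seed = s)
    keep <- sample(tr$tip.label, sample(2:8, 1))
    pr <- prune_to_taxa(tr, keep)
    expect_equal(ape::cophenetic.phylo(pr)[keep, keep],
                 ape::cophenetic.phylo(tr)[keep, keep])
  }
})

test_that("phylo_vcv matches the shared-path definition", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(unname(phylo_vcv(cherry, c("A", "B"))),
               diag(2), ignore_attr = TRUE)

  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V <- phylo_vcv(tr, c("A", "B", "C"))
  expect_equal(unname(V), rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)))

  # brute-force path-enumeration oracle on random trees
  for (s in 1:25) {
    tr <- random_tree(sample(3:12, 1), seed = 100 + s)
    expect_equal(phylo_vcv(tr, tr$tip.label),
                 bruteforce_vcv(tr)[tr$tip.label, tr$tip.label],
                 tolerance = 1e-12)
  }
})

test_that("phylo_vcv honours taxa_order and validates it", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V <- phylo_vcv(tr, c("C", "A", "B"))
  expect_equal(rownames(V), c("C", "A", "B"))
  expect_equal(unname(V["A", "B"]), 1)
  expect_error(phylo_vcv(tr, c("A", "B")), "permutation")
  expect_error(phylo_vcv(tr, c("A", "B", "Z")), "permutation")
})

test_that("vcv of a pruned tree equals the submatrix of the full vcv", {
  for (s in 1:15) {
    tr <- random_tree(10, seed = 200 + s)
    keep <- sample(tr$tip.label, 5)
    V_full <- phylo_vcv(tr)[keep, keep]
    V_sub <- phylo_vcv(prune_to_taxa(tr, keep), taxa_order = keep)
    expect_equal(V_sub, V_full, tolerance = 1e-12)
  }
})

test_that("lambda transform scales only the off-diagonal and stays PSD", {
  V <- rbind(c(2, 1), c(1, 2))
  expect_equal(lambda_transform(V, 1), V)
  expect_equal(lambda_transform(V, 0), diag(c(2, 2)))
  expect_equal(lambda_transform(V, 0.5), rbind(c(2, 0.5), c(0.5, 2)))
  expect_error(lambda_transform(V, -0.1), "lambda")
  expect_error(lambda_transform(V, 1.1), "lambda")

  # monotone in lambda off-diagonally; Cholesky succeeds on ultrametric trees
  tr <- simulate_tree(20, seed = 9)
  V <- phylo_vcv(tr)
  prev <- lambda_transform(V, 0)
  for (lam in c(0.25, 0.5, 0.75, 1)) {
    cur <- lambda_transform(V, lam)
    off <- row(cur) != col(cur)
    expect_true(all(cur[off] >= prev[off]))
    expect_no_error(chol(cur))
    prev <- cur
  }
})
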