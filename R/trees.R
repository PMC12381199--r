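#' Read a sample of phylogenies from a newick or nexus file
#'
#' Comparative analyses here are repeated over a sample of dated trees so that
#' topological and dating uncertainty propagates into the final verdicts. This
#' reader loads such a sample (typically 100 trees) in file order, so per-tree
#' results stay joinable by index.
#'
#' Taxon labels are whitespace-normalised on read: surrounding whitespace is
#' trimmed and internal spaces are replaced by underscores, matching the
#' convention used to join trait tables to trees.
#'
#' @param path Path to a newick file (one or more `;`-terminated trees) or a
#'   nexus file with a TREES block.
#' @param format `"auto"` (default; nexus is detected from the `#NEXUS` header),
#'   `"newick"`, or `"nexus"`.
#' @return A `tree_sample`: a `multiPhylo` list of `phylo` trees, in file order.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", tf)
#' ts <- read_tree_sample(tf)
#' length(ts)
#' @export
read_tree_sample <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("tree file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    abort(paste0("tree file is empty: ", path))
  }
  if (format == "auto") {
    first <- trimws(lines[nzchar(trimws(lines))][1])
    format <- if (grepl("^#NEXUS", first, ignore.case = TRUE)) "nexus" else "newick"
  }
  if (format == "newick") {
    check_newick_tokens(paste(lines, collapse = ""))
  }
  trees <- tryCatch(
    if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path),
    error = function(e) abort(paste0("failed to parse ", format, " file '", path, "': ", conditionMessage(e)))
  )
  if (is.null(trees)) {
    abort(paste0("failed to parse ", format, " file '", path, "': no tree could be read"))
  }
  if (inherits(trees, "phylo")) {
    trees <- structure(list(trees), class = "multiPhylo")
  }
  if (!is.null(attr(trees, "TipLabel"))) {
    # nexus readers may compress shared tip labels onto the container
    trees <- ape::.uncompressTipLabel(trees)
  }
  trees <- purrr::map(unclass(trees), normalize_tip_labels)
  as_tree_sample(trees)
}

# balanced-parenthesis / terminator pre-check so malformed newick fails with the
# offending token rather than whatever ape happens to return
check_newick_tokens <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(paste0("malformed newick: unmatched ')' at character ", i))
      }
    }
  }
  if (depth != 0L) {
    abort(paste0("malformed newick: ", depth, " unclosed '(' — first at character ",
                 which(chars == "(")[1]))
  }
  if (!grepl(";", txt, fixed = TRUE)) {
    abort("malformed newick: no ';' statement terminator found")
  }
  invisible(TRUE)
}

normalize_tip_labels <- function(tree) {
  lab <- gsub("^['\"]|['\"]$", "", tree$tip.label)
  tree$tip.label <- gsub("[[:space:]]+", "_", trimws(lab))
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("duplicate taxon labels in tree: ", paste(dup, collapse = ", ")))
  }
  tree
}

as_tree_sample <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  structure(unclass(trees), class = c("tree_sample", "multiPhylo"))
}

#' @export
print.tree_sample <- function(x, ...) {
  taxa <- purrr::map_int(unclass(x), ~ length(.x$tip.label))
  cat("<tree_sample> of", length(x), "trees;",
      if (length(unique(taxa)) == 1) paste(taxa[1], "tips each") else
        paste("tips ranging", min(taxa), "-", max(taxa)), "\n")
  invisible(x)
}

#' Prune a phylogeny to a subset of taxa
#'
#' Drops all tips outside `keep`, collapsing the resulting degree-2 internal
#' nodes and summing their branch lengths, so that every path length between
#' retained tips is exactly preserved. When the pruned subtree hangs below the
#' original root, the dropped stem is retained as the tree's root edge, so
#' root-to-tip depths — and hence the phylogenetic covariance — are measured
#' from the original root. Needed because each model variant runs on a different
#' analysis subset (e.g. excluding hominins or taxa with missing brain-region
#' data).
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return A `phylo` with exactly the `keep` taxa.
#' @export
prune_to_taxa <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(as.character(keep))
  missing <- setdiff(keep, tree$tip.label)
  if (length(missing) > 0) {
    abort(paste0("taxa not present in tree: ", paste(missing, collapse = ", ")))
  }
  if (length(keep) < 2) {
    abort("at least 2 taxa must be retained when pruning")
  }
  old_root <- tree$root.edge %||% 0
  # stem dropped below the new root = depth of the MRCA of the kept taxa
  stem <- if (length(keep) < length(tree$tip.label)) {
    ape::node.depth.edgelength(tree)[ape::getMRCA(tree, keep)]
  } else 0
  out <- ape::keep.tip(tree, keep)
  out$root.edge <- stem + old_root
  out
}

#' Phylogenetic variance-covariance matrix
#'
#' Builds the matrix V at the heart of PGLS: `V[i, j]` is the total branch
#' length shared from the root by taxa i and j (the time they evolved as one
#' lineage), and `V[i, i]` is the root-to-tip distance of taxon i. Under
#' Brownian trait evolution the trait vector is multivariate normal with
#' covariance proportional to V. For an ultrametric tree the diagonal is
#' constant; fossil tips at internal dates shorten their own diagonal entries,
#' which the GLS machinery handles without special cases. A root edge (e.g. the
#' stem retained by [prune_to_taxa()]) is history shared by all taxa and is
#' added to every entry, so pruning commutes exactly with taking a submatrix.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param taxa_order Optional character vector, a permutation of the tip labels,
#'   giving the row/column order of the result. Defaults to tree tip order.
#' @return A symmetric positive semidefinite numeric matrix with taxon dimnames.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' phylo_vcv(tr, c("A", "B", "C"))
#' @export
phylo_vcv <- function(tree, taxa_order = NULL) {
  stopifnot(inherits(tree, "phylo"))
  V <- ape::vcv(tree)
  if (!is.null(tree$root.edge)) {
    V <- V + tree$root.edge
  }
  if (!is.null(taxa_order)) {
    taxa_order <- as.character(taxa_order)
    if (!setequal(taxa_order, rownames(V)) || length(taxa_order) != nrow(V)) {
      abort("taxa_order must be a permutation of the tree's tip labels")
    }
    V <- V[taxa_order, taxa_order, drop = FALSE]
  }
  V
}

#' Pagel's lambda transformation of a phylogenetic covariance matrix
#'
#' Multiplies the off-diagonal (shared-history) entries of V by `lambda`,
#' leaving the diagonal untouched. `lambda = 1` keeps the full Brownian
#' covariance; `lambda = 0` collapses to a star phylogeny (statistical
#' independence among taxa). Intermediate values attenuate phylogenetic signal
#' and are estimated from the data in the MCMC.
#'
#' @param V Square symmetric covariance matrix (e.g. from [phylo_vcv()]).
#' @param lambda A value in \[0, 1\].
#' @return The transformed matrix, same dimnames as `V`.
#' @export
lambda_transform <- function(V, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    abort("lambda must be a single value in [0, 1]")
  }
  V <- as.matrix(V)
  Vl <- lambda * V
  diag(Vl) <- diag(V)
  Vl
}
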