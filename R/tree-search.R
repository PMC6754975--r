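#' Search configuration
#'
#' Settings for the two-step heuristic search: random-addition stepwise
#' construction holding the `hold` best trees per replicate, then TBR branch
#' swapping of the pooled best trees. The published analysis this package
#' replicates used 100,000 replicates holding 5, with TBR swapping; the
#' default replicate count here is scaled down to 1,000 (the study matrix's
#' optimal island is reached within a handful of replicates).
#'
#' @param n_replicates Number of random addition replicates (>= 1).
#' @param hold Number of best partial trees held during each addition.
#' @param seed Integer seed driving the stream of random addition orders;
#'   replicate r always uses the r-th drawn permutation, so shorter runs are
#'   prefixes of longer ones.
#' @param swap Branch-swapping move; only `"TBR"` (tree
#'   bisection-reconnection, which contains SPR and NNI as subsets) is
#'   implemented.
#' @param max_trees Cap on the number of equally best trees stored.
#' @param collapse_rule Branch-collapse convention applied when counting
#'   distinct most-parsimonious trees: `"min_length_zero"` collapses every
#'   internal branch whose minimum length over all most-parsimonious
#'   reconstructions is zero, `"max_length_zero"` only branches that have
#'   zero length in every such reconstruction, `"none"` keeps binary trees.
#' @return A list of class `search_config`.
#' @export
search_config <- function(n_replicates = 1000, hold = 5, seed = 1,
                          swap = "TBR", max_trees = 10000,
                          collapse_rule = c("min_length_zero", "max_length_zero", "none")) {
  swap <- match.arg(toupper(swap), "TBR")
  stopifnot(n_replicates >= 1, hold >= 1, max_trees >= 1)
  structure(list(n_replicates = as.integer(n_replicates), hold = as.integer(hold),
                 seed = seed, swap = swap, max_trees = as.integer(max_trees),
                 collapse_rule = match.arg(collapse_rule)),
            class = "search_config")
}

#' Stepwise addition of taxa in a given order
#'
#' Builds trees by starting from the unique unrooted topology of the first
#' three taxa in `addition_order` and inserting each subsequent taxon on
#' every branch of every held tree, keeping at most `hold` best-scoring
#' (distinct) partial trees. Ties are broken stably: the first-encountered
#' placement wins.
#'
#' @param m A [character_matrix].
#' @param addition_order Permutation of the matrix taxa (labels or indices).
#' @param hold Number of trees held.
#' @return A `multiPhylo` of the held full trees, with an attribute
#'   `lengths` giving their Fitch lengths.
#' @export
stepwise_addition <- function(m, addition_order, hold = 5) {
  stopifnot(inherits(m, "character_matrix"))
  if (is.character(addition_order)) addition_order <- match(addition_order, m$taxa)
  if (anyNA(addition_order) || !setequal(addition_order, seq_along(m$taxa))) {
    stop("addition_order must be a permutation of the matrix taxa")
  }
  if (length(m$taxa) < 3) stop("need at least 3 taxa")
  res <- cpp_stepwise_addition(state_masks(m), as.integer(addition_order) - 1L,
                               as.integer(hold))
  trees <- lapply(res$edges, new_phylo, tip.label = m$taxa)
  out <- as_multiphylo(trees)
  attr(out, "lengths") <- res$lengths
  out
}

#' All TBR neighbors of a tree
#'
#' Enumerates every distinct topology obtained by bisecting the unrooted
#' tree at a branch and reconnecting each branch of one fragment to each
#' branch of the other. Bisection is applied at every branch (pendant
#' branches included), so the SPR neighborhood -- and hence NNI -- is a
#' subset of the result. The original topology is excluded.
#'
#' @param tree An unrooted binary `phylo` with at least 4 tips (a rooted
#'   binary tree is accepted and treated as unrooted).
#' @return A `multiPhylo` of neighbor topologies.
#' @export
tbr_neighbors <- function(tree) {
  check_phylo(tree)
  if (length(tree$tip.label) < 4) stop("TBR needs at least 4 tips")
  res <- cpp_tbr_neighbors(tree$edge, length(tree$tip.label))
  as_multiphylo(lapply(res, new_phylo, tip.label = tree$tip.label))
}

#' Two-step heuristic search for most-parsimonious trees
#'
#' Step 1 runs `n_replicates` stepwise additions with independent random
#' taxon orders drawn from a stream seeded by `config$seed`, holding the
#' `hold` best trees in each. Step 2 pools the distinct best-length trees
#' found across replicates and TBR-swaps them to completion, accepting any
#' equally long unseen topology (and restarting from any shorter tree), so
#' that all most-parsimonious topologies connected to the pool by equal-or-
#' better TBR moves are collected, up to `max_trees`.
#'
#' @param m A [character_matrix] with at least 4 taxa.
#' @param config A [search_config()].
#' @return An object of class `search_result`: a list with `best_length`,
#'   `trees` (binary `multiPhylo`, pairwise distinct unrooted topologies),
#'   `replicates_hitting_best`, `log` (per-replicate best lengths),
#'   `truncated`, and the `config` used.
#' @export
heuristic_search <- function(m, config = search_config()) {
  stopifnot(inherits(m, "character_matrix"), inherits(config, "search_config"))
  ntax <- length(m$taxa)
  if (ntax < 4) stop("heuristic search needs at least 4 taxa")
  masks <- state_masks(m)
  orders <- with_seed(config$seed, lapply(seq_len(config$n_replicates),
                                          function(i) sample.int(ntax)))
  rep_best <- numeric(config$n_replicates)
  pool <- vector("list", config$n_replicates * config$hold)
  npool <- 0L
  pool_keys <- new.env(parent = emptyenv())
  for (r in seq_len(config$n_replicates)) {
    res <- cpp_stepwise_addition(masks, orders[[r]] - 1L, config$hold)
    lens <- res$lengths
    rep_best[r] <- min(lens)
    # pool every held tree: each distinct one is an independent swap start
    for (i in seq_along(lens)) {
      key <- cpp_tree_key(res$edges[[i]], ntax)
      if (is.null(pool_keys[[key]]) && npool < config$max_trees) {
        npool <- npool + 1L
        pool[[npool]] <- res$edges[[i]]
        pool_keys[[key]] <- TRUE
      }
    }
  }
  pool <- pool[seq_len(npool)]
  swp <- cpp_tbr_search(pool, ntax, masks, config$max_trees)
  trees <- as_multiphylo(lapply(swp$edges, new_phylo, tip.label = m$taxa))
  structure(list(
    best_length = as.integer(swp$best_length),
    trees = trees,
    replicates_hitting_best = sum(rep_best == swp$best_length),
    log = as.integer(rep_best),
    truncated = isTRUE(swp$truncated),
    n_rearrangements_scored = swp$n_scored,
    config = config), class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("parsimony search result:\n")
  cat(sprintf("  best length: %d steps\n", x$best_length))
  cat(sprintf("  trees at best length: %d%s\n", length(x$trees),
              if (x$truncated) " (truncated at max_trees)" else ""))
  cat(sprintf("  replicates hitting best length: %d / %d\n",
              x$replicates_hitting_best, length(x$log)))
  invisible(x)
}

#' Exhaustive search over all unrooted binary topologies
#'
#' Scores every distinct unrooted binary topology ((2n-5)!! of them) and
#' returns the exact optimum set. Supported for 4 to 9 taxa.
#'
#' @param m A [character_matrix] with 4..9 taxa.
#' @param max_trees Cap on stored optimal trees.
#' @return A `search_result` with an extra field `n_topologies`.
#' @export
exhaustive_search <- function(m, max_trees = 10000) {
  stopifnot(inherits(m, "character_matrix"))
  ntax <- length(m$taxa)
  if (ntax < 4 || ntax > 9) stop("exhaustive search supports 4 to 9 taxa")
  res <- cpp_exhaustive_search(state_masks(m), as.integer(max_trees))
  trees <- as_multiphylo(lapply(res$edges, new_phylo, tip.label = m$taxa))
  structure(list(best_length = as.integer(res$best_length), trees = trees,
                 n_topologies = res$n_topologies,
                 replicates_hitting_best = NA_integer_, log = integer(0),
                 truncated = isTRUE(res$truncated), config = NULL),
            class = "search_result")
}

#' Collapse unsupported branches and deduplicate topologies
#'
#' Applies a branch-collapse convention to each tree and removes duplicate
#' unrooted topologies. Under `"min_length_zero"` every internal branch
#' whose minimum length over all most-parsimonious reconstructions is zero
#' becomes a polytomy (the stricter convention, yielding fewer resolved
#' branches); under `"max_length_zero"` only branches with zero length in
#' every reconstruction are collapsed; `"none"` only deduplicates.
#'
#' @param trees A `multiPhylo` (or list) of trees on the same leaf set.
#' @param m The [character_matrix] the trees were scored on.
#' @param rule Collapse rule.
#' @return A `multiPhylo` of distinct collapsed topologies.
#' @export
collapse_and_dedupe <- function(trees, m,
                                rule = c("min_length_zero", "max_length_zero", "none")) {
  rule <- match.arg(rule)
  if (inherits(trees, "phylo")) trees <- list(trees)
  labs <- trees[[1]]$tip.label
  for (t in trees) if (!setequal(t$tip.label, labs)) stop("trees must share one leaf set")
  collapsed <- lapply(trees, function(tr) {
    if (rule == "none") return(tr)
    rng <- branch_length_range(tr, m)
    len <- if (rule == "min_length_zero") rng$min_len else rng$max_len
    po <- postorder_tree(tr)
    ntip <- length(tr$tip.label)
    po$edge.length <- ifelse(po$edge[, 2] > ntip & len == 0, 0, 1)
    out <- ape::di2multi(po, tol = 0.5)
    out$edge.length <- NULL
    out
  })
  keys <- vapply(collapsed, topology_key, "")
  as_multiphylo(collapsed[!duplicated(keys)])
}
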