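#' Strict consensus of a set of trees
#'
#' The tree containing exactly the non-trivial bipartitions shared by every
#' input tree; conflicting or non-universal groupings collapse to polytomies.
#'
#' @param trees A `multiPhylo` (or list of `phylo`) on identical leaf sets.
#' @return An unrooted `phylo`.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("need at least one tree")
  labs <- trees[[1]]$tip.label
  for (t in trees) {
    if (!setequal(t$tip.label, labs)) stop("trees must share an identical leaf set")
  }
  if (length(trees) == 1) {
    out <- ape::unroot(trees[[1]])
    out$edge.length <- NULL
    return(out)
  }
  out <- ape::consensus(as_multiphylo(trees), p = 1, rooted = FALSE)
  out$edge.length <- NULL
  out
}

# tip sets below each edge (list indexed by edge row)
edge_tip_sets <- function(tree) {
  po <- postorder_tree(tree)
  ntip <- length(tree$tip.label)
  below <- vector("list", max(po$edge))
  for (i in seq_len(ntip)) below[[i]] <- i
  for (r in seq_len(nrow(po$edge))) {
    p <- po$edge[r, 1]; ch <- po$edge[r, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(r) sort(below[[tree$edge[r, 2]]]))
}

#' Root a tree with a designated outgroup
#'
#' Roots on the branch separating the outgroup taxa from the rest. When the
#' outgroup is not monophyletic on the unrooted tree, the tree is rooted at
#' the branch whose bipartition best matches the outgroup/ingroup division
#' (fewest misplaced taxa; first such branch on ties), a warning is issued
#' and the result carries `attr(., "outgroup_monophyletic") = FALSE`.
#'
#' @param tree A `phylo`.
#' @param outgroup Character vector of outgroup tip labels (a proper,
#'   non-empty subset of the tips).
#' @return A rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  check_phylo(tree)
  labs <- tree$tip.label
  if (!length(outgroup)) stop("outgroup must be non-empty")
  if (!all(outgroup %in% labs)) {
    stop("outgroup taxa not in tree: ",
         paste(setdiff(outgroup, labs), collapse = ", "))
  }
  if (setequal(outgroup, labs)) stop("outgroup cannot contain every leaf")
  og <- sort(match(outgroup, labs))
  ntip <- length(labs)
  sets <- edge_tip_sets(tree)
  tipsets <- lapply(sets, function(s) s[s <= ntip])
  mono <- vapply(tipsets, function(s) {
    identical(s, og) || identical(sort(setdiff(seq_len(ntip), s)), og)
  }, TRUE)
  if (any(mono) || length(og) == 1) {
    out <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
    attr(out, "outgroup_monophyletic") <- TRUE
    return(out)
  }
  mis <- vapply(tipsets, function(s) {
    min(length(setdiff(og, s)) + length(setdiff(s, og)),
        length(intersect(og, s)) + (ntip - length(s) - length(setdiff(og, s))))
  }, 0L)
  r <- which.min(mis)
  edge <- cpp_root_on_edge(tree$edge, ntip, tree$edge[r, 1], tree$edge[r, 2])
  out <- new_phylo(edge, labs)
  warning("outgroup is not monophyletic on this tree; rooted at the best-matching branch")
  attr(out, "outgroup_monophyletic") <- FALSE
  out
}
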