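# Internal helpers shared across modules.

MISSING_TOKEN <- "?"
INAPPLICABLE_TOKEN <- "-"

# unify hyphen, en dash, em dash, minus sign to the ASCII inapplicable token
normalize_dash <- function(x) {
  gsub("‐|‑|‒|–|—|−", "-", x)
}

is_equivocal <- function(x) x == MISSING_TOKEN | x == INAPPLICABLE_TOKEN

#' @noRd
observed_codes <- function(cells, j) {
  v <- cells[, j]
  sort(unique(as.integer(v[!is_equivocal(v)])))
}

# Bitmask encoding of cells over each character's observed state set.
# Equivocal cells expand to the full observed set; characters with no
# observed state get mask 1 (a single dummy state) so they score 0 steps.
state_masks <- function(m) {
  cells <- m$cells
  k <- ncol(cells)
  out <- matrix(0L, nrow(cells), k)
  for (j in seq_len(k)) {
    obs <- observed_codes(cells, j)
    full <- if (length(obs)) sum(bitwShiftL(1L, obs)) else 1L
    v <- cells[, j]
    eq <- is_equivocal(v)
    col <- rep(full, length(v))
    col[!eq] <- bitwShiftL(1L, as.integer(v[!eq]))
    out[, j] <- as.integer(col)
  }
  rownames(out) <- m$taxa
  out
}

# masks reordered to a tree's tip labels; errors on unknown leaves
masks_for_tree <- function(tree, m) {
  idx <- match(tree$tip.label, m$taxa)
  if (anyNA(idx)) {
    stop("leaf not present in matrix: ", paste(tree$tip.label[is.na(idx)], collapse = ", "))
  }
  state_masks(m)[idx, , drop = FALSE]
}

new_phylo <- function(edge, tip.label) {
  storage.mode(edge) <- "integer"
  structure(list(edge = edge, tip.label = tip.label,
                 Nnode = max(edge) - length(tip.label)),
            class = "phylo")
}

as_multiphylo <- function(trees) {
  class(trees) <- "multiPhylo"
  trees
}

check_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape \"phylo\" object")
  if (length(tree$tip.label) > 64) stop("trees with more than 64 tips are not supported")
  invisible(tree)
}

#' Canonical topology key of an unrooted tree
#'
#' A string identifying the unrooted topology of a tree (its set of
#' non-trivial bipartitions), invariant under rerooting, node rotation and
#' tip-label order. Two trees on the same leaf set get the same key if and
#' only if they induce the same bipartitions.
#'
#' @param tree A `phylo` object (at most 64 tips).
#' @return A character scalar.
#' @export
topology_key <- function(tree) {
  check_phylo(tree)
  perm <- match(seq_along(tree$tip.label), order(tree$tip.label))
  edge <- tree$edge
  tipn <- edge[, 2] <= length(tree$tip.label)
  edge[tipn, 2] <- perm[edge[tipn, 2]]
  cpp_tree_key(edge, length(tree$tip.label))
}

# Non-trivial splits of an unrooted tree as canonical strings: the side not
# containing the alphabetically first label, as sorted labels joined by "|".
unrooted_splits <- function(tree) {
  check_phylo(tree)
  labs <- tree$tip.label
  ntip <- length(labs)
  anchor <- labs[order(labs)][1]
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (clade in pp) {
    side <- labs[clade]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2 && length(side) <= ntip - 2) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  unique(out)
}

# TRUE if every non-trivial split of `tree` is also a split of `reference`
# (i.e. `reference` refines or equals `tree`); both must share leaf sets.
splits_compatible <- function(tree, reference) {
  if (!setequal(tree$tip.label, reference$tip.label)) stop("leaf sets differ")
  all(unrooted_splits(tree) %in% unrooted_splits(reference))
}

# postorder edge ordering; ape::reorder.phylo is exported, and calling the
# method directly is robust in non-interactive sessions
postorder_tree <- function(tree) ape::reorder.phylo(tree, "postorder")

# seeded evaluation that does not disturb the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
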