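#' Fitch parsimony length of a tree
#'
#' Minimum number of character-state changes (steps) required by a tree for
#' unordered multistate characters under equal weights. Missing and
#' inapplicable cells are expanded to the full set of states observed for
#' that character (equivocal). The length is invariant under rerooting;
#' polytomies are scored exactly (Fitch-Hartigan counting).
#'
#' @param tree A `phylo` tree whose tip labels are a subset of the matrix taxa.
#' @param m A [character_matrix].
#' @return A list with `total` (integer) and `per_character` (integer vector).
#' @export
fitch_length <- function(tree, m) {
  check_phylo(tree)
  stopifnot(inherits(m, "character_matrix"))
  masks <- masks_for_tree(tree, m)
  if (length(tree$tip.label) < 2) {
    return(list(total = 0L, per_character = integer(ncol(m$cells))))
  }
  per <- cpp_fitch_counts(tree$edge, length(tree$tip.label), masks)
  list(total = sum(per), per_character = per)
}

#' Sankoff parsimony length under unit costs
#'
#' Dynamic programming over states at every node (the generalized parsimony
#' algorithm with a uniform unit cost matrix). For unit costs this equals
#' [fitch_length()]; the implementation is an independent code path written
#' for cross-validation of the Fitch scorer.
#'
#' @inheritParams fitch_length
#' @return Integer total length.
#' @export
sankoff_length <- function(tree, m) {
  check_phylo(tree)
  stopifnot(inherits(m, "character_matrix"))
  ntip <- length(tree$tip.label)
  if (ntip < 2) return(0L)
  masks <- masks_for_tree(tree, m)
  edge <- postorder_tree(tree)$edge
  nnode <- max(edge)
  total <- 0L
  for (j in seq_len(ncol(m$cells))) {
    mask <- masks[, j]
    k <- max(1L, 1L + floor(log2(max(mask))))
    cost <- matrix(Inf, nnode, k)
    for (i in seq_len(ntip)) {
      allowed <- bitwAnd(bitwShiftR(mask[i], 0:(k - 1)), 1L) == 1L
      cost[i, allowed] <- 0
    }
    for (r in seq_len(nrow(edge))) {
      par <- edge[r, 1]; ch <- edge[r, 2]
      if (all(!is.finite(cost[par, ]))) cost[par, ] <- 0
      inc <- vapply(seq_len(k), function(s) min(cost[ch, s], min(cost[ch, ]) + 1), 0)
      cost[par, ] <- cost[par, ] + inc
    }
    root <- edge[nrow(edge), 1]
    total <- total + as.integer(min(cost[root, ]))
  }
  total
}

#' Minimum conceivable steps of a character
#'
#' The number of distinct non-equivocal states observed minus one (floored
#' at zero): the steps the character requires on any tree.
#'
#' @param m A [character_matrix].
#' @param j Character index (1-based).
#' @return Integer.
#' @export
char_min_steps <- function(m, j) {
  stopifnot(inherits(m, "character_matrix"))
  max(0L, length(observed_codes(m$cells, j)) - 1L)
}

#' Maximum conceivable steps of a character
#'
#' The steps the character would require on a completely unresolved (star)
#' tree: the number of scored (non-equivocal) cells minus the frequency of
#' the most common state; zero if at most one cell is scored.
#'
#' @inheritParams char_min_steps
#' @return Integer.
#' @export
char_max_steps <- function(m, j) {
  stopifnot(inherits(m, "character_matrix"))
  v <- m$cells[, j]
  v <- v[!is_equivocal(v)]
  if (length(v) <= 1) return(0L)
  as.integer(length(v) - max(table(v)))
}

# informative = at least two states each present in >= 2 scored taxa
char_informative <- function(m, j) {
  v <- m$cells[, j]
  tab <- table(v[!is_equivocal(v)])
  sum(tab >= 2) >= 2
}

#' Ensemble consistency and retention indices
#'
#' For a tree containing all matrix taxa, computes per character the minimum
#' conceivable steps m, the observed Fitch steps s, and the maximum
#' conceivable steps g, and the ensemble indices
#' CI = sum(m)/sum(s) and RI = (sum(g) - sum(s)) / (sum(g) - sum(m)).
#' Parsimony-uninformative characters are included by default (the usual
#' "ensemble" convention); set `exclude_uninformative = TRUE` for the
#' alternative convention. Degenerate ratios are reported as `NA`.
#'
#' @inheritParams fitch_length
#' @param exclude_uninformative Drop parsimony-uninformative characters from
#'   the sums.
#' @return An object of class `ensemble_stats`: a list with `sum_min`,
#'   `sum_obs`, `sum_max`, `ci`, `ri`, and a per-character data frame
#'   `per_char` with columns `index`, `m`, `s`, `g`, `ci_i`, `ri_i`,
#'   `informative`.
#' @export
ensemble_indices <- function(tree, m, exclude_uninformative = FALSE) {
  check_phylo(tree)
  if (!setequal(tree$tip.label, m$taxa)) {
    stop("tree must contain every matrix taxon for ensemble indices")
  }
  k <- ncol(m$cells)
  s <- fitch_length(tree, m)$per_character
  mi <- vapply(seq_len(k), char_min_steps, 0L, m = m)
  gi <- vapply(seq_len(k), char_max_steps, 0L, m = m)
  inf <- vapply(seq_len(k), char_informative, TRUE, m = m)
  per <- data.frame(index = seq_len(k), m = mi, s = s, g = gi,
                    ci_i = ifelse(s > 0, mi / s, NA_real_),
                    ri_i = ifelse(gi > mi, (gi - s) / (gi - mi), NA_real_),
                    informative = inf)
  use <- if (exclude_uninformative) inf else rep(TRUE, k)
  sm <- sum(mi[use]); so <- sum(s[use]); sg <- sum(gi[use])
  structure(list(
    sum_min = sm, sum_obs = so, sum_max = sg,
    ci = if (so > 0) sm / so else NA_real_,
    ri = if (sg > sm) (sg - so) / (sg - sm) else NA_real_,
    per_char = per,
    exclude_uninformative = exclude_uninformative), class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("ensemble parsimony stats (%s characters):\n",
              if (x$exclude_uninformative) "informative" else "all"))
  cat(sprintf("  length %d steps; sum min %d; sum max %d\n", x$sum_obs, x$sum_min, x$sum_max))
  cat(sprintf("  CI = %.4f  RI = %.4f\n", x$ci, x$ri))
  invisible(x)
}

#' Write per-character parsimony diagnostics as TSV
#'
#' @param stats An `ensemble_stats` object from [ensemble_indices()].
#' @param file Output path.
#' @return Invisibly, the data frame written.
#' @export
write_char_diagnostics <- function(stats, file) {
  stopifnot(inherits(stats, "ensemble_stats"))
  write.table(stats$per_char, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(stats$per_char)
}

# Per-branch minimum and maximum number of changes over all most-parsimonious
# reconstructions (summed over characters). Used by the branch-collapse rules.
# Returns a data.frame with one row per tree edge: min_len, max_len.
branch_length_range <- function(tree, m) {
  check_phylo(tree)
  masks <- masks_for_tree(tree, m)
  ntip <- length(tree$tip.label)
  po <- postorder_tree(tree)
  edge <- po$edge
  nnode <- max(edge)
  ne <- nrow(edge)
  children <- split(seq_len(ne), edge[, 1])  # edge rows by parent
  root <- edge[ne, 1]
  minl <- integer(ne); maxl <- integer(ne)
  for (j in seq_len(ncol(m$cells))) {
    mask <- masks[, j]
    k <- max(1L, 1L + floor(log2(max(mask))))
    down <- matrix(Inf, nnode, k)
    for (i in seq_len(ntip)) {
      allowed <- bitwAnd(bitwShiftR(mask[i], 0:(k - 1)), 1L) == 1L
      down[i, allowed] <- 0
    }
    down[(ntip + 1):nnode, ] <- 0
    # edge contribution of child ch into parent state a
    contrib <- function(ch) vapply(seq_len(k), function(a)
      min(down[ch, a], min(down[ch, ]) + 1), 0)
    contr <- matrix(0, ne, k)
    for (r in seq_len(ne)) {
      contr[r, ] <- contrib(edge[r, 2])
      down[edge[r, 1], ] <- down[edge[r, 1], ] + contr[r, ]
    }
    L <- min(down[root, ])
    # up_excl[r, a]: cost of everything outside the subtree of edge r's child,
    # with the parent end fixed to state a
    upn <- matrix(NA_real_, nnode, k)  # up cost at node, node's state fixed
    upn[root, ] <- 0
    up_excl <- matrix(0, ne, k)
    for (r in rev(seq_len(ne))) {   # preorder
      par <- edge[r, 1]; ch <- edge[r, 2]
      up_excl[r, ] <- upn[par, ] + down[par, ] - contr[r, ]
      if (ch > ntip) {
        upn[ch, ] <- vapply(seq_len(k), function(s)
          min(up_excl[r, s], min(up_excl[r, ]) + 1), 0)
      }
    }
    for (r in seq_len(ne)) {
      tot0 <- min(up_excl[r, ] + down[edge[r, 2], ])                 # same state
      both <- outer(up_excl[r, ], rep(1, k)) + outer(rep(1, k), down[edge[r, 2], ]) + 1
      diag(both) <- Inf
      tot1 <- min(both)                                              # different states
      if (tot0 > L) minl[r] <- minl[r] + 1L
      if (tot1 > L) NULL else maxl[r] <- maxl[r] + 1L
    }
  }
  data.frame(parent = edge[, 1], child = edge[, 2], min_len = minl, max_len = maxl)
}
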