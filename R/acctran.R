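#' ACCTRAN ancestral-state reconstruction
#'
#' Computes, for every character, a minimum-length assignment of states to
#' all nodes of a rooted binary tree in which ambiguity is resolved by
#' accelerating transformations: among all minimum-length reconstructions,
#' the one whose changes lie as close to the root as possible (early gains
#' with later reversals are preferred over delayed parallel gains). This is
#' found exactly by a dynamic program that minimizes, lexicographically, the
#' number of changes and then the summed root-distance of the change
#' branches. Remaining ties at the root are resolved toward the state
#' observed in the matrix's outgroup taxa when that is unique, otherwise
#' toward the lowest state code; along branches, retaining the parental
#' state is preferred, then the lowest code.
#'
#' @param tree A rooted, strictly binary `phylo` (reconstruct on each binary
#'   most-parsimonious tree; polytomies are refused).
#' @param m A [character_matrix] covering all tips.
#' @return An object of class `acctran_reconstruction`: a list with `tree`,
#'   `states` (nodes x characters integer matrix of state codes; rows follow
#'   the phylo node numbering), `changes` (data frame with columns `branch`
#'   -- the child node of the branch --, `character`, `from`, `to`, `depth`)
#'   and `depths` (node depths, root = 0).
#' @export
acctran_reconstruct <- function(tree, m) {
  check_phylo(tree)
  stopifnot(inherits(m, "character_matrix"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted; see root_with_outgroup()")
  if (!ape::is.binary(tree)) {
    stop("tree contains polytomies; reconstruct on a binary most-parsimonious tree, not a consensus")
  }
  masks <- masks_for_tree(tree, m)
  ntip <- length(tree$tip.label)
  po <- postorder_tree(tree)
  edge <- po$edge
  ne <- nrow(edge)
  nnode <- max(edge)
  root <- edge[ne, 1]
  depth <- integer(nnode)
  for (r in rev(seq_len(ne))) depth[edge[r, 2]] <- depth[edge[r, 1]] + 1L
  W <- sum(depth) + 1  # weight base: one change always outweighs any depth sum
  og_idx <- match(m$outgroup, m$taxa)
  nchar_ <- ncol(m$cells)
  states <- matrix(NA_integer_, nnode, nchar_)
  changes <- vector("list", nchar_)
  for (j in seq_len(nchar_)) {
    mask <- masks[, j]
    k <- max(1L, 1L + floor(log2(max(mask))))
    D <- matrix(Inf, nnode, k)
    for (i in seq_len(ntip)) {
      allowed <- bitwAnd(bitwShiftR(mask[i], 0:(k - 1)), 1L) == 1L
      D[i, allowed] <- 0
    }
    D[(ntip + 1):nnode, ] <- 0
    for (r in seq_len(ne)) {
      par <- edge[r, 1]; ch <- edge[r, 2]
      pen <- W + depth[ch]
      inc <- vapply(seq_len(k), function(s) min(D[ch, s], min(D[ch, ]) + pen), 0)
      D[par, ] <- D[par, ] + inc
    }
    cand <- which(D[root, ] == min(D[root, ]))
    pick <- cand[1]
    if (length(cand) > 1 && length(og_idx)) {
      ogv <- m$cells[og_idx, j]
      ogv <- unique(as.integer(ogv[!is_equivocal(ogv)]))
      if (length(ogv) == 1 && (ogv + 1L) %in% cand) pick <- ogv + 1L
    }
    st <- integer(nnode)
    st[root] <- pick
    for (r in rev(seq_len(ne))) {  # preorder
      par <- edge[r, 1]; ch <- edge[r, 2]
      a <- st[par]
      pen <- W + depth[ch]
      tot <- D[ch, ] + ifelse(seq_len(k) == a, 0, pen)
      best <- which(tot == min(tot))
      st[ch] <- if (a %in% best) a else best[1]
    }
    states[, j] <- st - 1L
    chg <- which(st[edge[, 2]] != st[edge[, 1]])
    if (length(chg)) {
      changes[[j]] <- data.frame(
        branch = edge[chg, 2], character = j,
        from = st[edge[chg, 1]] - 1L, to = st[edge[chg, 2]] - 1L,
        depth = depth[edge[chg, 2]])
    }
  }
  changes <- if (any(!vapply(changes, is.null, TRUE))) {
    do.call(rbind, changes[!vapply(changes, is.null, TRUE)])
  } else {
    data.frame(branch = integer(0), character = integer(0),
               from = integer(0), to = integer(0), depth = integer(0))
  }
  rownames(changes) <- NULL
  structure(list(tree = tree, states = states, changes = changes, depths = depth),
            class = "acctran_reconstruction")
}

#' @export
print.acctran_reconstruction <- function(x, ...) {
  cat("ACCTRAN reconstruction:", ncol(x$states), "characters,",
      nrow(x$changes), "changes\n")
  invisible(x)
}

#' Classify homoplasy of reconstructed character-state changes
#'
#' For every (character, derived state) pair appearing in the change list,
#' counts the independent origins (changes into that state on distinct
#' branches) and the reversals (changes whose derived state already occurs
#' at an ancestor of the branch), and classifies the pair:
#' `"non-homoplastic"` (exactly one origin, no reversal), `"convergent"`
#' (multiple origins, no reversal), `"reversal"` (single origin that is a
#' reversal), or `"both"`.
#'
#' @param recon An [acctran_reconstruct()] result.
#' @return A data frame of class `homoplasy_report` with columns
#'   `character`, `state`, `origins`, `reversals`, `class`.
#' @export
classify_homoplasy <- function(recon) {
  stopifnot(inherits(recon, "acctran_reconstruction"))
  ch <- flag_reversals(recon)
  if (!nrow(ch)) {
    out <- data.frame(character = integer(0), state = integer(0),
                      origins = integer(0), reversals = integer(0),
                      class = character(0))
    class(out) <- c("homoplasy_report", "data.frame")
    return(out)
  }
  agg <- aggregate(cbind(origins = rep(1L, nrow(ch)), reversals = ch$reversal),
                   by = list(character = ch$character, state = ch$to), FUN = sum)
  agg$class <- ifelse(agg$origins == 1 & agg$reversals == 0, "non-homoplastic",
               ifelse(agg$reversals == 0, "convergent",
               ifelse(agg$origins == 1, "reversal", "both")))
  agg <- agg[order(agg$character, agg$state), c("character", "state", "origins",
                                                "reversals", "class")]
  rownames(agg) <- NULL
  class(agg) <- c("homoplasy_report", "data.frame")
  agg
}

# change list with a logical `reversal` column: the derived state occurs at
# an ancestor of the branch's parent end (for the same character)
flag_reversals <- function(recon) {
  ch <- recon$changes
  if (!nrow(ch)) {
    ch$reversal <- logical(0)
    return(ch)
  }
  edge <- recon$tree$edge
  nnode <- max(edge)
  parent <- integer(nnode)
  for (r in seq_len(nrow(edge))) parent[edge[r, 2]] <- edge[r, 1]
  root <- setdiff(edge[, 1], edge[, 2])
  ch$reversal <- vapply(seq_len(nrow(ch)), function(i) {
    s <- ch$to[i]
    u <- parent[ch$branch[i]]  # parent end of the change branch
    repeat {
      if (recon$states[u, ch$character[i]] == s) return(TRUE)
      if (u == root) return(FALSE)
      u <- parent[u]
    }
  }, TRUE)
  ch
}

#' Count independent origins of a derived state
#'
#' @param recon An [acctran_reconstruct()] result.
#' @param char_index Character index (1-based).
#' @param state Derived state code.
#' @return Integer: the number of branches with a change into that state.
#' @export
count_origins <- function(recon, char_index, state) {
  stopifnot(inherits(recon, "acctran_reconstruction"))
  sum(recon$changes$character == char_index & recon$changes$to == state)
}

#' Per-branch change annotations
#'
#' Maps every reconstructed change to its branch, flagging reversals and
#' homoplastic character states, as drawn on published cladograms (each
#' internode labelled with its character-state gains; unique-origin states
#' distinguished from homoplastic ones and from reversals).
#'
#' @param tree The tree of the reconstruction (must be the same tree).
#' @param recon An [acctran_reconstruct()] result on `tree`.
#' @return A data frame with columns `branch` (child node of the branch),
#'   `character`, `from`, `to`, `reversal`, `class` (the
#'   [classify_homoplasy()] class of the character-state pair).
#' @export
annotate_internodes <- function(tree, recon) {
  stopifnot(inherits(recon, "acctran_reconstruction"))
  if (!identical(unclass(tree)$edge, unclass(recon$tree)$edge) ||
      !identical(tree$tip.label, recon$tree$tip.label)) {
    stop("'tree' is not the tree of this reconstruction")
  }
  ch <- flag_reversals(recon)
  rep <- classify_homoplasy(recon)
  key <- paste(rep$character, rep$state)
  ch$class <- rep$class[match(paste(ch$character, ch$to), key)]
  ch <- ch[order(ch$branch, ch$character), c("branch", "character", "from", "to",
                                             "reversal", "class")]
  rownames(ch) <- NULL
  ch
}
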