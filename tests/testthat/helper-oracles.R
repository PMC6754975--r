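# Independent oracles and small fixture builders used across the test files.
# These deliberately avoid the package's C++ code paths: the brute-force
# scorers enumerate ancestral assignments directly, and the TBR oracle works
# from the definition using ape primitives and full topology enumeration.

# canonical form of a split (the side not containing the alphabetically
# first label), matching maxpars:::unrooted_splits
canon_split <- function(side, labs) {
  if (sort(labs)[1] %in% side) side <- setdiff(labs, side)
  paste(sort(side), collapse = "|")
}

has_split <- function(tree, side) {
  canon_split(side, tree$tip.label) %in% maxpars:::unrooted_splits(tree)
}

# build a character_matrix from a list of per-character named state vectors
make_matrix <- function(..., outgroup = character()) {
  chars <- list(...)
  taxa <- names(chars[[1]])
  cells <- do.call(cbind, lapply(chars, function(x) as.character(x[taxa])))
  character_matrix(cells, taxa = taxa, outgroup = outgroup)
}

# random test instance: uniform random unrooted topology + simulated matrix
random_instance <- function(n_taxa, n_chars, k = 3, change_prob = 0.3, seed = 1,
                            missing_frac = 0, inapplicable_frac = 0) {
  tr <- random_topology(n_taxa, seed = seed)
  cfg <- sim_config(n_taxa, n_chars, k, change_prob = change_prob,
                    missing_frac = missing_frac,
                    inapplicable_frac = inapplicable_frac, seed = seed + 7919)
  list(tree = tr, matrix = simulate_matrix(tr, cfg))
}

# allowed state codes per cell (observed-state expansion of equivocal cells)
allowed_states <- function(m, j) {
  v <- m$cells[, j]
  eq <- v %in% c("?", "-")
  obs <- sort(unique(as.integer(v[!eq])))
  if (!length(obs)) obs <- 0L
  lapply(seq_along(v), function(i) if (eq[i]) obs else as.integer(v[i]))
}

# minimum changes over every ancestral assignment, by direct enumeration
brute_min_steps <- function(tree, m) {
  edge <- tree$edge
  ntip <- length(tree$tip.label)
  internals <- sort(unique(edge[edge > ntip]))
  tot <- 0L
  idx <- match(tree$tip.label, m$taxa)
  for (j in seq_len(ncol(m$cells))) {
    allow <- allowed_states(m, j)[idx]
    obs <- sort(unique(unlist(allow)))
    k <- length(obs)
    A <- as.matrix(expand.grid(rep(list(obs), length(internals))))
    cost <- numeric(nrow(A))
    for (r in seq_len(nrow(edge))) {
      p <- match(edge[r, 1], internals)
      ch <- edge[r, 2]
      if (ch > ntip) {
        cost <- cost + (A[, p] != A[, match(ch, internals)])
      } else {
        cost <- cost + vapply(A[, p], function(s) as.integer(!(s %in% allow[[ch]])), 0L)
      }
    }
    tot <- tot + min(cost)
  }
  tot
}

# every minimum-change assignment of one character on a rooted binary tree,
# returned with its change count and summed root-distance of change branches
enumerate_min_reconstructions <- function(tree, m, j) {
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  ntip <- length(tree$tip.label)
  nnode <- max(edge)
  root <- edge[nrow(edge), 1]
  depth <- integer(nnode)
  for (r in rev(seq_len(nrow(edge)))) depth[edge[r, 2]] <- depth[edge[r, 1]] + 1L
  idx <- match(tree$tip.label, m$taxa)
  allow <- allowed_states(m, j)[idx]
  obs <- sort(unique(unlist(allow)))
  nodes_free <- c(seq_len(ntip)[lengths(allow) > 1], (ntip + 1):nnode)
  fixed <- setdiff(seq_len(ntip), nodes_free)
  grids <- c(lapply(seq_len(ntip)[lengths(allow) > 1], function(i) allow[[i]]),
             rep(list(obs), nnode - ntip))
  A <- as.matrix(expand.grid(grids))
  full <- matrix(NA_integer_, nrow(A), nnode)
  full[, nodes_free] <- A
  for (i in fixed) full[, i] <- allow[[i]]
  chg <- matrix(FALSE, nrow(A), nrow(edge))
  for (r in seq_len(nrow(edge))) chg[, r] <- full[, edge[r, 1]] != full[, edge[r, 2]]
  steps <- rowSums(chg)
  wdepth <- as.vector(chg %*% depth[edge[, 2]])
  keep <- steps == min(steps)
  list(states = full[keep, , drop = FALSE], steps = min(steps),
       depth_sums = wdepth[keep])
}

# TBR neighborhood from the definition: all topologies T' (full enumeration)
# such that, for some branch-induced bipartition (S1, S2) of T, T' contains
# that bipartition and restricts to the same subtree topology on each side.
tbr_neighbors_naive <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  all_trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = labs)
  sides <- list()
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- n
  below <- vector("list", max(po$edge))
  for (i in seq_len(ntip)) below[[i]] <- labs[i]
  for (r in seq_len(nrow(po$edge))) {
    below[[po$edge[r, 1]]] <- c(below[[po$edge[r, 1]]], below[[po$edge[r, 2]]])
  }
  for (r in seq_len(nrow(po$edge))) {
    s1 <- sort(below[[po$edge[r, 2]]])
    if (length(s1) >= 1 && length(s1) <= n - 1) sides[[length(sides) + 1]] <- s1
  }
  sides <- unique(sides)
  restr <- function(t, s) {
    if (length(s) <= 3) return("star")
    topology_key(ape::keep.tip(t, s))
  }
  has_split <- function(t, s) {
    if (length(s) %in% c(1, n - 1)) return(TRUE)
    us <- maxpars:::unrooted_splits(t)
    anchor <- sort(labs)[1]
    key <- if (anchor %in% s) paste(sort(setdiff(labs, s)), collapse = "|")
           else paste(sort(s), collapse = "|")
    key %in% us
  }
  self_key <- topology_key(tree)
  out <- character(0)
  for (ti in seq_along(all_trees)) {
    tp <- all_trees[[ti]]
    k <- topology_key(tp)
    if (k == self_key) next
    for (s in sides) {
      s2 <- setdiff(labs, s)
      if (has_split(tp, s) &&
          identical(restr(tp, s), restr(tree, s)) &&
          identical(restr(tp, s2), restr(tree, s2))) {
        out <- c(out, k)
        break
      }
    }
  }
  unique(out)
}
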