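#' Simulation configuration for Mk-style morphological matrices
#'
#' @param n_taxa Number of taxa (>= 4).
#' @param n_chars Number of characters (>= 1).
#' @param states_per_char Number of states per character: a single integer
#'   (2..5) or a vector of length `n_chars`.
#' @param change_prob Per-branch probability that a character jumps to a
#'   uniformly chosen different state.
#' @param missing_frac Fraction of cells replaced by the missing token.
#' @param inapplicable_frac Fraction of cells replaced by the inapplicable
#'   token.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 38, n_chars = 48, states_per_char = 2,
                       change_prob = 0.1, missing_frac = 0,
                       inapplicable_frac = 0, seed = 1) {
  stopifnot(n_taxa >= 4, n_chars >= 1,
            all(states_per_char >= 2), all(states_per_char <= 5),
            change_prob >= 0, change_prob <= 1,
            missing_frac >= 0, missing_frac <= 1,
            inapplicable_frac >= 0, inapplicable_frac <= 1,
            missing_frac + inapplicable_frac <= 1)
  if (length(states_per_char) == 1) states_per_char <- rep(states_per_char, n_chars)
  if (length(states_per_char) != n_chars) {
    stop("states_per_char must have length 1 or n_chars")
  }
  structure(list(n_taxa = as.integer(n_taxa), n_chars = as.integer(n_chars),
                 states_per_char = as.integer(states_per_char),
                 change_prob = change_prob, missing_frac = missing_frac,
                 inapplicable_frac = inapplicable_frac, seed = seed),
            class = "sim_config")
}

#' Uniformly random unrooted binary topology
#'
#' Generated by sequential random edge insertion: starting from the unique
#' three-leaf tree, each further leaf is attached to a branch chosen
#' uniformly at random, which yields every unrooted binary topology with
#' equal probability.
#'
#' @param n_taxa Number of leaves (>= 3); labels are `t1..tn`.
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @return An unrooted `phylo`.
#' @export
random_topology <- function(n_taxa, seed = NULL) {
  stopifnot(n_taxa >= 3)
  with_seed(seed, {
    # nodes: 1..n tips, n+1.. internals; edge list grown by subdivision
    n <- n_taxa
    edges <- rbind(c(n + 1, 1), c(n + 1, 2), c(n + 1, 3))
    nextint <- n + 2
    for (tip in seq_len(n)[-(1:3)]) {
      r <- sample.int(nrow(edges), 1)
      w <- nextint; nextint <- nextint + 1
      e <- edges[r, ]
      edges <- rbind(edges[-r, , drop = FALSE], c(e[1], w), c(w, e[2]), c(w, tip))
    }
    edges_to_phylo(edges, n, paste0("t", seq_len(n)))
  })
}

# orient an arbitrary tree edge list (node ids: 1..ntip tips) into a phylo
# rooted at the internal node adjacent to tip 1
edges_to_phylo <- function(edges, ntip, tip_labels) {
  nb <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  root <- nb[[as.character(1)]][1]
  if (ntip == 3) root <- edges[1, 1]
  # iterative preorder from root
  parent <- rep(NA_integer_, max(edges))
  ord <- integer(0)
  stack <- root
  parent[root] <- 0L
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, u)
    for (v in nb[[as.character(u)]]) {
      if (is.na(parent[v])) { parent[v] <- u; stack <- c(stack, v) }
    }
  }
  newid <- integer(max(edges))
  nexti <- ntip + 1L
  for (u in ord) {
    newid[u] <- if (u <= ntip) u else { i <- nexti; nexti <- nexti + 1L; i }
  }
  new_phylo(cbind(newid[parent[ord[-1]]], newid[ord[-1]]), tip_labels)
}

#' Simulate a discrete character matrix on a tree
#'
#' Each character evolves from a uniform-random root state; on every branch
#' it jumps, with probability `change_prob`, to a uniformly chosen different
#' state (an Mk-style, branch-homogeneous model without branch lengths).
#' Missing and inapplicable tokens are then injected independently per cell
#' at the configured fractions.
#'
#' @param tree A `phylo` with at least 4 tips.
#' @param config A [sim_config()]; `n_taxa` is taken from the tree.
#' @return A [character_matrix] whose taxa are the tree's tip labels.
#' @export
simulate_matrix <- function(tree, config) {
  check_phylo(tree)
  stopifnot(inherits(config, "sim_config"))
  ntip <- length(tree$tip.label)
  if (ntip < 4) stop("tree must have at least 4 tips")
  with_seed(config$seed, {
    po <- postorder_tree(tree)
    edge <- po$edge
    nnode <- max(edge)
    root <- edge[nrow(edge), 1]
    cells <- matrix(NA_character_, ntip, config$n_chars)
    for (j in seq_len(config$n_chars)) {
      k <- config$states_per_char[j]
      st <- integer(nnode)
      st[root] <- sample.int(k, 1) - 1L
      for (r in rev(seq_len(nrow(edge)))) {  # preorder
        par <- edge[r, 1]; ch <- edge[r, 2]
        st[ch] <- if (runif(1) < config$change_prob) {
          alt <- setdiff(0:(k - 1), st[par])
          alt[sample.int(length(alt), 1)]
        } else {
          st[par]
        }
      }
      cells[, j] <- as.character(st[seq_len(ntip)])
    }
    u <- matrix(runif(length(cells)), nrow(cells))
    cells[u < config$inapplicable_frac] <- INAPPLICABLE_TOKEN
    cells[u >= config$inapplicable_frac &
            u < config$inapplicable_frac + config$missing_frac] <- MISSING_TOKEN
    character_matrix(cells, taxa = tree$tip.label)
  })
}

#' A study-shaped synthetic instance with known truth
#'
#' Generates a random 38-taxon topology and simulates a 48-character matrix
#' whose per-character state counts are those of the bundled study matrix
#' and whose inapplicable-token frequency matches the study matrix's
#' (about 9% of cells). The per-branch change probability (0.065) was
#' calibrated once so that the generating tree's ensemble consistency index
#' averages about 0.33, the moderate homoplasy level of the study data.
#'
#' @param seed Integer seed.
#' @return A list with `tree` (the generating topology) and `matrix`
#'   (a [character_matrix]).
#' @export
study_like_matrix <- function(seed = 1) {
  ref <- load_study_matrix()
  tree <- random_topology(38, seed = seed)
  cfg <- sim_config(n_taxa = 38, n_chars = 48,
                    states_per_char = pmin(5L, pmax(2L, ref$chardefs$nstates)),
                    change_prob = 0.065,
                    missing_frac = mean(ref$cells == MISSING_TOKEN),
                    inapplicable_frac = mean(ref$cells == INAPPLICABLE_TOKEN),
                    seed = seed + 1L)
  m <- simulate_matrix(tree, cfg)
  list(tree = tree, matrix = m)
}
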