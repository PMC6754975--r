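test_that("strict consensus is the split intersection, idempotent and order-invariant", {
  t1 <- ape::read.tree(text = "((A,B),((C,D),E));")
  expect_equal(compare_trees(strict_consensus(list(t1)), t1), 0L)
  t2 <- ape::read.tree(text = "((A,C),((B,D),E));")
  cons <- strict_consensus(list(t1, t2))
  s1 <- maxpars:::unrooted_splits(t1)
  s2 <- maxpars:::unrooted_splits(t2)
  expect_setequal(maxpars:::unrooted_splits(cons), intersect(s1, s2))
  # a single differing clade collapses, shared structure is retained
  t3 <- ape::read.tree(text = "((A,B),((C,E),D));")
  cons13 <- strict_consensus(list(t1, t3))
  expect_true(has_split(cons13, c("A", "B")))
  expect_false(has_split(cons13, c("C", "D")))
  # order invariance over random MPT sets
  inst <- random_instance(7, 8, k = 3, seed = 5, change_prob = 0.4)
  ex <- exhaustive_search(inst$matrix)
  if (length(ex$trees) > 1) {
    a <- strict_consensus(ex$trees)
    b <- strict_consensus(rev(unclass(ex$trees)))
    expect_equal(compare_trees(a, b), 0L)
    for (t in ex$trees) {
      expect_true(all(maxpars:::unrooted_splits(a) %in% maxpars:::unrooted_splits(t)))
    }
  }
  expect_error(strict_consensus(list(t1, ape::read.tree(text = "((A,B),(C,X));"))),
               "leaf set")
})

test_that("outgroup rooting places the outgroup basally, flagging non-monophyly", {
  q <- ape::read.tree(text = "((A,B),(C,D));")
  r1 <- root_with_outgroup(q, "A")
  expect_true(ape::is.rooted(r1))
  expect_true(attr(r1, "outgroup_monophyletic"))
  r2 <- root_with_outgroup(q, c("A", "B"))
  kids <- r2$edge[r2$edge[, 1] == length(r2$tip.label) + 1L, 2]
  sides <- lapply(kids, function(k) ape::extract.clade(r2, k)$tip.label)
  expect_true(any(vapply(sides, function(s) setequal(s, c("A", "B")), TRUE)))
  # non-monophyletic outgroup: best-matching branch, with a warning
  expect_warning(r3 <- root_with_outgroup(q, c("A", "C")), "not monophyletic")
  expect_false(attr(r3, "outgroup_monophyletic"))
  expect_true(ape::is.rooted(r3))
  expect_error(root_with_outgroup(q, c("A", "B", "C", "D")), "every leaf")
  expect_error(root_with_outgroup(q, "Z"), "Z")
})

rooted_instance <- function(n, n_chars, seed, k = 3, change_prob = 0.35) {
  inst <- random_instance(n, n_chars, k = k, seed = seed, change_prob = change_prob)
  list(tree = root_with_outgroup(inst$tree, "t1"), matrix = inst$matrix)
}

test_that("ACCTRAN change counts equal Fitch steps per character", {
  for (s in 1:8) {
    ri <- rooted_instance(7, 6, seed = s + 90)
    rec <- acctran_reconstruct(ri$tree, ri$matrix)
    per <- fitch_length(ri$tree, ri$matrix)$per_character
    for (j in seq_along(per)) {
      expect_equal(sum(rec$changes$character == j), per[j])
    }
    expect_true(all(rec$changes$from != rec$changes$to))
    # leaf states agree with non-equivocal cells
    idx <- match(ri$tree$tip.label, ri$matrix$taxa)
    cells <- ri$matrix$cells[idx, , drop = FALSE]
    scored <- !(cells %in% c("?", "-"))
    dim(scored) <- dim(cells)
    leaf_states <- rec$states[seq_along(idx), , drop = FALSE]
    expect_equal(leaf_states[scored], as.integer(cells[scored]))
  }
})

test_that("ACCTRAN is minimal and root-ward maximal among enumerated reconstructions", {
  for (s in 1:10) {
    n <- sample(4:6, 1)
    ri <- rooted_instance(n, 4, seed = s + 700, k = 3, change_prob = 0.45)
    rec <- acctran_reconstruct(ri$tree, ri$matrix)
    for (j in seq_len(4)) {
      en <- enumerate_min_reconstructions(ri$tree, ri$matrix, j)
      expect_equal(sum(rec$changes$character == j), en$steps)
      got_depth <- sum(rec$changes$depth[rec$changes$character == j])
      expect_equal(got_depth, min(en$depth_sums))
    }
  }
})

test_that("a Fitch ambiguity resolves to the accelerated (early gain, later loss) mapping", {
  # 0 at the outgroup side, 1 twice among the ingroup: ACCTRAN prefers one
  # early gain followed by a reversal over two parallel gains
  m <- make_matrix(c(O = 0, A = 1, B = 1, C = 0, D = 1), outgroup = "O")
  tr <- root_with_outgroup(ape::read.tree(text = "(O,(A,(B,(C,D))));"), "O")
  rec <- acctran_reconstruct(tr, m)
  ch <- rec$changes[rec$changes$character == 1, ]
  expect_equal(nrow(ch), 2L)
  expect_setequal(paste(ch$from, ch$to), c("0 1", "1 0"))
  rep <- classify_homoplasy(rec)
  expect_equal(rep$class[rep$character == 1 & rep$state == 0], "reversal")
})

test_that("homoplasy classification distinguishes unique origins, convergence and reversal", {
  # character 1: single origin; character 2: derived state in two clades
  # separated by two ancestral-state taxa, forcing independent origins
  m <- make_matrix(c(O = 0, A = 0, B = 1, C = 1, D = 1),
                   c(O = 0, A = 1, B = 0, C = 0, D = 1),
                   outgroup = "O")
  tr <- root_with_outgroup(ape::read.tree(text = "(O,(A,(B,(C,D))));"), "O")
  rec <- acctran_reconstruct(tr, m)
  rep <- classify_homoplasy(rec)
  expect_equal(rep$class[rep$character == 1 & rep$state == 1], "non-homoplastic")
  expect_equal(count_origins(rec, 1, 1), 1L)
  r2 <- rep[rep$character == 2 & rep$state == 1, ]
  expect_true(r2$origins >= 2)
  expect_equal(count_origins(rec, 2, 1), r2$origins)
  expect_equal(count_origins(rec, 2, 4), 0L)
})

test_that("internode annotations conserve total length and label classes", {
  ri <- rooted_instance(8, 10, seed = 44, change_prob = 0.4)
  rec <- acctran_reconstruct(ri$tree, ri$matrix)
  ann <- annotate_internodes(ri$tree, rec)
  expect_equal(nrow(ann), fitch_length(ri$tree, ri$matrix)$total)
  expect_true(all(ann$class %in% c("non-homoplastic", "convergent", "reversal", "both")))
  # zero-change matrix: empty annotation
  cm <- character_matrix(matrix("0", 8, 3), taxa = ri$matrix$taxa)
  rec0 <- acctran_reconstruct(ri$tree, cm)
  expect_equal(nrow(annotate_internodes(ri$tree, rec0)), 0L)
  expect_error(annotate_internodes(random_topology(8, seed = 1), rec), "not the tree")
})

test_that("polytomies and unrooted trees are refused with guidance", {
  m <- make_matrix(c(A = 0, B = 1, C = 1, D = 0))
  star <- ape::read.tree(text = "((A,B),C,D);")
  expect_error(acctran_reconstruct(star, m), "rooted")
  poly <- ape::read.tree(text = "((A,B,C),D);")
  expect_error(acctran_reconstruct(poly, m), "polytom")
})
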