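test_that("stepwise addition starts from the 3-taxon star and ranks placements", {
  m3 <- make_matrix(c(A = 0, B = 1, C = 1))
  held <- stepwise_addition(m3, c("A", "B", "C"))
  expect_length(held, 1L)
  expect_equal(length(held[[1]]$tip.label), 3L)
  # characters favoring ((A,B),(C,D)): that topology must rank first
  m4 <- make_matrix(c(A = 0, B = 0, C = 1, D = 1),
                    c(A = 1, B = 1, C = 0, D = 0),
                    c(A = 0, B = 0, C = 1, D = 1))
  held4 <- stepwise_addition(m4, c("A", "B", "C", "D"), hold = 3)
  want <- topology_key(ape::read.tree(text = "((A,B),(C,D));"))
  expect_equal(topology_key(held4[[1]]), want)
  expect_equal(attr(held4, "lengths")[1], 3L)
  expect_error(stepwise_addition(m4, c("A", "B")), "permutation")
})

test_that("held stepwise trees never beat the exhaustive optimum", {
  for (s in 1:5) {
    inst <- random_instance(8, 10, k = 3, seed = s + 60, change_prob = 0.35)
    ex <- exhaustive_search(inst$matrix)
    set.seed(s)
    held <- stepwise_addition(inst$matrix, sample(inst$matrix$taxa), hold = 5)
    expect_true(all(attr(held, "lengths") >= ex$best_length))
  }
})

test_that("TBR neighborhood contains both alternative quartets and all NNI trees", {
  q <- ape::read.tree(text = "((A,B),(C,D));")
  nb <- tbr_neighbors(q)
  expect_length(nb, 2L)
  keys <- vapply(nb, topology_key, "")
  expect_setequal(keys, c(topology_key(ape::read.tree(text = "((A,C),(B,D));")),
                          topology_key(ape::read.tree(text = "((A,D),(B,C));"))))
  skip_if_not_installed("phangorn")
  t5 <- random_topology(6, seed = 8)
  nbk <- vapply(tbr_neighbors(t5), topology_key, "")
  nni <- phangorn::nni(t5)
  expect_true(all(vapply(nni, topology_key, "") %in% nbk))
})

test_that("TBR neighborhoods match the definitional oracle on random trees", {
  skip_if_not_installed("phangorn")
  for (s in c(2, 5)) {
    for (n in c(6, 7)) {
      tr <- random_topology(n, seed = s * 10 + n)
      mine <- sort(vapply(tbr_neighbors(tr), topology_key, ""))
      oracle <- sort(tbr_neighbors_naive(tr))
      expect_identical(mine, oracle)
    }
  }
})

test_that("exhaustive search enumerates (2n-5)!! topologies and refuses big n", {
  m4 <- make_matrix(c(A = 0, B = 0, C = 1, D = 1))
  ex4 <- exhaustive_search(m4)
  expect_equal(ex4$n_topologies, 3)
  inst <- random_instance(7, 5, seed = 1)
  expect_equal(exhaustive_search(inst$matrix)$n_topologies, 945)
  inst10 <- random_instance(10, 5, seed = 1)
  expect_error(exhaustive_search(inst10$matrix), "4 to 9")
})

test_that("heuristic search equals the exhaustive optimum on random matrices", {
  for (s in 1:8) {
    inst <- random_instance(8, 12, k = 3, seed = s + 500, change_prob = 0.3)
    ex <- exhaustive_search(inst$matrix)
    sr <- heuristic_search(inst$matrix, search_config(n_replicates = 10, seed = s))
    expect_equal(sr$best_length, ex$best_length)
    # anytime soundness: every reported tree re-scores to best_length (Sankoff)
    for (t in sr$trees) expect_equal(sankoff_length(t, inst$matrix), sr$best_length)
    # every heuristic tree is a true optimum
    expect_true(all(vapply(sr$trees, topology_key, "") %in%
                      vapply(ex$trees, topology_key, "")))
  }
})

test_that("perfect data recovers the generating topology at the additive minimum", {
  inst <- random_instance(6, 40, k = 2, seed = 31, change_prob = 0.07)
  m <- inst$matrix
  summin <- sum(vapply(seq_len(ncol(m$cells)), char_min_steps, 0L, m = m))
  if (fitch_length(inst$tree, m)$total == summin) {  # homoplasy-free draw
    sr <- heuristic_search(m, search_config(n_replicates = 5, seed = 2))
    expect_equal(sr$best_length, summin)
    expect_true(topology_key(inst$tree) %in% vapply(sr$trees, topology_key, ""))
  }
  succeed()
})

test_that("search is reproducible and its log is a prefix of longer runs", {
  inst <- random_instance(9, 10, k = 3, seed = 17, change_prob = 0.35)
  a <- heuristic_search(inst$matrix, search_config(n_replicates = 12, seed = 5))
  b <- heuristic_search(inst$matrix, search_config(n_replicates = 12, seed = 5))
  expect_identical(a$log, b$log)
  expect_identical(lapply(a$trees, topology_key), lapply(b$trees, topology_key))
  longer <- heuristic_search(inst$matrix, search_config(n_replicates = 20, seed = 5))
  expect_identical(longer$log[1:12], a$log)
})

test_that("collapse_and_dedupe merges rerootings and collapses unsupported branches", {
  inst <- random_instance(6, 8, k = 3, seed = 23)
  t1 <- inst$tree
  t2 <- ape::root(t1, outgroup = "t4", resolve.root = TRUE)
  out <- collapse_and_dedupe(list(t1, t2), inst$matrix, "none")
  expect_length(out, 1L)
  # a branch supported by no character collapses under both rules
  m <- make_matrix(c(A = 0, B = 0, C = 1, D = 1, E = 1))
  tr <- ape::read.tree(text = "((A,B),(C,(D,E)));")  # D-E branch unsupported
  for (rule in c("min_length_zero", "max_length_zero")) {
    cc <- collapse_and_dedupe(list(tr), m, rule)[[1]]
    expect_lt(cc$Nnode, tr$Nnode)
    expect_false("D|E" %in% maxpars:::unrooted_splits(cc))
  }
})
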