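quartet <- function(newick = "((A,B),(C,D));") ape::read.tree(text = newick)

test_that("fitch_length counts single and double origins on quartets", {
  m <- make_matrix(c(A = 0, B = 0, C = 1, D = 1))
  expect_equal(fitch_length(quartet(), m)$total, 1L)
  expect_equal(fitch_length(quartet("((A,C),(B,D));"), m)$total, 2L)
  expect_error(fitch_length(quartet("((A,B),(C,X));"), m), "X")
})

test_that("equivocal cells are free and per-character steps sum to the total", {
  m <- make_matrix(c(A = 0, B = "?", C = 1, D = "-"),
                   c(A = 0, B = 1, C = 0, D = 1))
  fl <- fitch_length(quartet(), m)
  expect_equal(fl$per_character, c(1L, 2L))
  expect_equal(fl$total, sum(fl$per_character))
})

test_that("fitch equals sankoff, brute-force enumeration and phangorn on random instances", {
  skip_if_not_installed("phangorn")
  for (s in 1:25) {
    n <- sample(4:7, 1)
    inst <- random_instance(n, 6, k = 3, seed = s, missing_frac = 0.05,
                            inapplicable_frac = 0.05)
    f <- fitch_length(inst$tree, inst$matrix)$total
    expect_equal(f, sankoff_length(inst$tree, inst$matrix))
    expect_equal(f, brute_min_steps(inst$tree, inst$matrix))
    pd <- phangorn::phyDat(inst$matrix$cells, type = "USER",
                           levels = as.character(0:4), ambiguity = c("?", "-"))
    expect_equal(f, phangorn::fitch(inst$tree, pd))
  }
})

test_that("length is invariant under rerooting and exact on polytomies", {
  inst <- random_instance(7, 8, k = 3, seed = 2)
  f0 <- fitch_length(inst$tree, inst$matrix)$total
  for (tip in c("t2", "t5", "t7")) {
    rr <- ape::root(inst$tree, outgroup = tip, resolve.root = TRUE)
    expect_equal(fitch_length(rr, inst$matrix)$total, f0)
  }
  # a star tree scores the Sankoff value too
  star <- ape::read.tree(text = paste0("(", paste(inst$tree$tip.label, collapse = ","), ");"))
  expect_equal(fitch_length(star, inst$matrix)$total,
               sankoff_length(star, inst$matrix))
})

test_that("char_min_steps and char_max_steps follow their closed forms", {
  m <- make_matrix(c(A = 0, B = 1, C = 2, D = 0, E = 1),  # three states
                   c(A = "?", B = "-", C = "?", D = "-", E = "?"),  # all equivocal
                   c(A = 0, B = "?", C = 0, D = 0, E = "-"),  # single state
                   c(A = 0, B = 0, C = 0, D = 1, E = 1),
                   c(A = 0, B = 0, C = 1, D = 1, E = 2))
  expect_equal(sapply(1:5, char_min_steps, m = m), c(2L, 0L, 0L, 1L, 2L))
  expect_equal(sapply(1:5, char_max_steps, m = m), c(3L, 0L, 0L, 2L, 3L))
  m6 <- make_matrix(c(A = 0, B = 0, C = 1, D = 1, E = 2, F = 2))
  expect_equal(char_max_steps(m6, 1), 4L)
})

test_that("bounds min <= observed <= max hold for every character and tree", {
  for (s in 1:10) {
    inst <- random_instance(8, 10, k = 4, seed = s + 40, change_prob = 0.4,
                            missing_frac = 0.1)
    st <- ensemble_indices(inst$tree, inst$matrix)
    expect_true(all(st$per_char$m <= st$per_char$s))
    expect_true(all(st$per_char$s <= st$per_char$g))
  }
})

test_that("ensemble CI and RI follow their definitions and degenerate safely", {
  # arithmetic case: sum_min 3, sum_obs 5, sum_max 8 -> CI 0.6, RI 0.6
  m <- make_matrix(c(A = 0, B = 1, C = 0, D = 1, E = 1, F = 0),
                   c(A = 0, B = 0, C = 1, D = 1, E = 2, F = 2),
                   c(A = 0, B = 1, C = 1, D = 0, E = 0, F = 1))
  tr <- ape::read.tree(text = "((A,B),(C,D),(E,F));")
  st <- ensemble_indices(tr, m)
  expect_equal(st$ci, st$sum_min / st$sum_obs)
  expect_equal(st$ri, (st$sum_max - st$sum_obs) / (st$sum_max - st$sum_min))
  # homoplasy-free data (one clade indicator per character): CI = 1
  tr2 <- ape::read.tree(text = "((A,B),((C,D),(E,F)));")
  m2 <- make_matrix(c(A = 1, B = 1, C = 0, D = 0, E = 0, F = 0),
                    c(A = 0, B = 0, C = 1, D = 1, E = 0, F = 0),
                    c(A = 0, B = 0, C = 0, D = 0, E = 1, F = 1),
                    c(A = 0, B = 0, C = 1, D = 1, E = 1, F = 1))
  st2 <- ensemble_indices(tr2, m2)
  expect_equal(st2$sum_obs, st2$sum_min)
  expect_equal(st2$ci, 1)
  # constant matrix: degenerate denominators reported as NA
  cm <- make_matrix(c(A = 0, B = 0, C = 0, D = 0))
  st3 <- ensemble_indices(quartet(), cm)
  expect_true(is.na(st3$ci))
  expect_true(is.na(st3$ri))
})

test_that("CI is monotone: a longer tree never has higher CI", {
  inst <- random_instance(7, 12, k = 3, seed = 77, change_prob = 0.35)
  ex <- exhaustive_search(inst$matrix)
  best <- ensemble_indices(ex$trees[[1]], inst$matrix)
  worse <- ensemble_indices(random_topology(7, seed = 1234), inst$matrix)
  expect_true(best$sum_obs <= worse$sum_obs)
  expect_true(best$ci >= worse$ci)
})

test_that("ensemble indices agree with phangorn CI/RI on the study matrix", {
  skip_if_not_installed("phangorn")
  m <- load_study_matrix()
  tr <- random_topology(38, seed = 4)
  tr$tip.label <- m$taxa[as.integer(sub("t", "", tr$tip.label))]
  st <- ensemble_indices(tr, m)
  pd <- phangorn::phyDat(m$cells, type = "USER", levels = as.character(0:4),
                         ambiguity = c("?", "-"))
  expect_equal(st$ci, phangorn::CI(tr, pd), tolerance = 1e-10)
  expect_equal(st$ri, phangorn::RI(tr, pd), tolerance = 1e-10)
})

test_that("per-branch length ranges match enumeration over minimal reconstructions", {
  for (s in 1:6) {
    inst <- random_instance(6, 5, k = 3, seed = s + 300, change_prob = 0.35)
    tr <- ape::root(inst$tree, outgroup = "t1", resolve.root = TRUE)
    rng <- maxpars:::branch_length_range(tr, inst$matrix)
    ne <- nrow(rng)
    minexp <- integer(ne); maxexp <- integer(ne)
    po_edge <- ape::reorder.phylo(tr, "postorder")$edge
    for (j in seq_len(ncol(inst$matrix$cells))) {
      en <- enumerate_min_reconstructions(tr, inst$matrix, j)
      for (r in seq_len(ne)) {
        ch <- en$states[, po_edge[r, 1]] != en$states[, po_edge[r, 2]]
        minexp[r] <- minexp[r] + as.integer(all(ch))
        maxexp[r] <- maxexp[r] + as.integer(any(ch))
      }
    }
    expect_equal(rng$min_len, minexp)
    expect_equal(rng$max_len, maxexp)
  }
})

test_that("per-character diagnostics export as TSV", {
  inst <- random_instance(5, 6, seed = 3)
  st <- ensemble_indices(inst$tree, inst$matrix)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_char_diagnostics(st, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 6L)
  expect_named(back, c("index", "m", "s", "g", "ci_i", "ri_i", "informative"))
})
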