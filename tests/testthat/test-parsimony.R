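quartet <- ape::read.tree(text = "((A,B),(C,D));")

test_that("Fitch scoring counts minimum state changes", {
  m <- matrix(c(0, 0, 1, 1), 4, 1, dimnames = list(c("A", "B", "C", "D"),
                                                   "c1"))
  expect_equal(fitch_score(quartet, m), 1L)   # single synapomorphy
  const <- matrix(1, 4, 1, dimnames = list(c("A", "B", "C", "D"), "c1"))
  expect_equal(fitch_score(quartet, const), 0L)
  # a duplicated character doubles its contribution exactly
  m2 <- cbind(m, m)
  expect_equal(fitch_score(quartet, m2), 2L * fitch_score(quartet, m))
  # score is invariant to rooting
  expect_equal(fitch_score(ape::unroot(quartet), m), 1L)
})

test_that("Fitch equals brute-force ancestral-state enumeration", {
  set.seed(21)
  labels <- paste0("t", 1:6)
  for (rep in 1:5) {
    tr <- random_unrooted_tree(labels)
    m <- matrix(sample(0:1, 6 * 6, replace = TRUE), 6,
                dimnames = list(labels, NULL))
    oracle <- sum(vapply(seq_len(ncol(m)), function(j)
      oracle_min_changes(tr, m[, j]), 0))
    expect_equal(fitch_score(tr, m), oracle)
  }
})

test_that("three taxa give the single unrooted topology", {
  m <- matrix(sample(0:1, 6, replace = TRUE), 3,
              dimnames = list(c("A", "B", "C"), NULL))
  ts <- branch_and_bound(m)
  expect_equal(ts$count, 1)
  expect_equal(length(ts$trees), 1L)
  expect_setequal(ts$trees[[1]]$tip.label, c("A", "B", "C"))
})

test_that("branch and bound equals exhaustive enumeration (7 taxa)", {
  skip_if_not_installed("phangorn")
  labels <- paste0("t", 1:7)
  at <- phangorn::allTrees(7, rooted = FALSE, tip.label = labels)
  set.seed(31)
  for (rep in 1:3) {
    m <- matrix(sample(0:1, 7 * 8, replace = TRUE), 7,
                dimnames = list(labels, NULL))
    ts <- branch_and_bound(m)
    pd <- phangorn::phyDat(m, type = "USER", levels = c(0, 1))
    ps <- phangorn::parsimony(at, pd, method = "fitch")
    expect_equal(ts$score, min(ps))
    expect_equal(ts$count, sum(ps == min(ps)))
    key <- function(t) paste(sort(tree_splits(t)), collapse = ";")
    expect_setequal(vapply(ts$trees, key, ""),
                    vapply(at[ps == min(ps)], key, ""))
  }
})

test_that("strict consensus is the split-set intersection", {
  one <- ape::rtree(8)
  expect_true(setequal(tree_splits(strict_consensus(list(one))),
                       tree_splits(one)))
  # conflicting quartets collapse to a star
  t1 <- ape::unroot(ape::read.tree(text = "((A,B),(C,D));"))
  t2 <- ape::unroot(ape::read.tree(text = "((A,C),(B,D));"))
  star <- strict_consensus(list(t1, t2))
  expect_equal(length(tree_splits(star)), 0L)

  set.seed(41)
  for (rep in 1:5) {
    a <- ape::unroot(ape::rtree(8, tip.label = paste0("t", 1:8)))
    b <- ape::unroot(ape::rtree(8, tip.label = paste0("t", 1:8)))
    cons <- strict_consensus(list(a, b))
    expect_setequal(tree_splits(cons),
                    intersect(tree_splits(a), tree_splits(b)))
    # the consensus refines no split absent from either member
    expect_true(all(tree_splits(cons) %in% tree_splits(a)))
  }
})

test_that("consensus from a search agrees with ape::consensus", {
  set.seed(51)
  m <- matrix(sample(0:1, 7 * 6, replace = TRUE), 7,
              dimnames = list(paste0("t", 1:7), NULL))
  ts <- branch_and_bound(m)
  ours <- strict_consensus(ts)
  ref <- ape::consensus(ts$trees, p = 1)
  expect_setequal(tree_splits(ours), tree_splits(ref))
})

test_that("rooting between clades preserves splits and clade membership", {
  un <- ape::unroot(ape::read.tree(text = "((A,B),(C,D));"))
  rt <- root_between(un, c("A", "B"), c("C", "D"))
  expect_true("A|B" %in% tree_clades(rt) | "C|D" %in% tree_clades(rt))
  expect_setequal(tree_splits(rt), tree_splits(un))

  # an extra taxon outside both clades attaches to one side
  six <- ape::unroot(ape::read.tree(text = "(((A,B),X),((C,D),E));"))
  rt6 <- root_between(six, c("A", "B"), c("C", "D", "E"))
  expect_setequal(tree_splits(rt6), tree_splits(six))

  # clades incompatible with the tree -> error naming the problem
  expect_error(root_between(un, c("A", "C"), c("B", "D")),
               "no edge separates")
})
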