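test_that("generation is a pure function of the seed", {
  cfg <- two_clade_config(seed = 5)
  a <- generate_observations(cfg)
  b <- generate_observations(cfg)
  expect_identical(as.data.frame(a$table), as.data.frame(b$table))
  expect_identical(a$truth$strain_effects, b$truth$strain_effects)
  c2 <- generate_observations(two_clade_config(seed = 6))
  expect_false(identical(as.data.frame(a$table), as.data.frame(c2$table)))
})

test_that("truth records carry the latent-scale heritability", {
  chars <- sim_character_table(c("01", "02"), c("binomial", "poisson"),
                               baseline = c(0, log(10)),
                               sigma2_G = c(pi^2 / 3, 0.1))
  cfg <- generator_config(n_strains = 6L, n_individuals = 5L,
                          characters = chars, missing_rate = 0, seed = 1)
  g <- generate_observations(cfg)
  tr <- g$truth$characters
  # binomial with sigma2_G = pi^2/3 has true latent H2 exactly 0.5
  expect_equal(tr$H2_latent[1], 0.5, tolerance = 1e-12)
  lam <- exp(log(10) + 0.1 / 2)
  expect_equal(tr$H2_latent[2], 0.1 / (0.1 + log(1 + 1 / lam)),
               tolerance = 1e-12)
})

test_that("structure follows the design: sides, missingness, strains", {
  cfg <- generator_config(n_strains = 12L, n_individuals = c(8L, 12L),
                          missing_rate = 0.05, seed = 17)
  g <- generate_observations(cfg)
  tab <- g$table
  expect_equal(length(unique(tab$strain_id)), 12L)
  bilat <- g$specs$character_id[g$specs$bilateral]
  expect_setequal(unique(tab$side[tab$character_id %in% bilat]),
                  c("left", "right"))
  expect_true(all(tab$side[!tab$character_id %in% bilat] == "none"))
  ind_per_strain <- tapply(tab$individual_id, tab$strain_id,
                           function(i) length(unique(i)))
  expect_true(all(ind_per_strain >= 8 & ind_per_strain <= 12))
  expect_gt(mean(tab$missing), 0.02)
  expect_lt(mean(tab$missing), 0.09)
  # the full default design is analysable end to end
  expect_s3_class(character_tests(g$table, g$specs), "divergence_tests")
})

test_that("tree-based matrices evolve by per-edge state flips", {
  tr <- ape::rtree(8, tip.label = paste0("t", 1:8))
  # flip_prob 0: every character constant, score 0 on any tree
  g0 <- generate_matrix_on_tree(tr, 20, flip_prob = 0, seed = 2)
  expect_true(all(apply(g0$matrix, 2, function(s) length(unique(s))) == 1))
  expect_equal(fitch_score(ape::unroot(tr), g0$matrix), 0L)
  # determinism
  g1 <- generate_matrix_on_tree(tr, 20, flip_prob = 0.1, seed = 3)
  g2 <- generate_matrix_on_tree(tr, 20, flip_prob = 0.1, seed = 3)
  expect_identical(g1$matrix, g2$matrix)
  expect_error(generate_matrix_on_tree(tr, 5, flip_prob = 0.5, seed = 1),
               "flip_prob")
})

test_that("low flip rates keep the generating topology most parsimonious", {
  set.seed(99)
  among_mp <- compatible <- logical(10)
  for (s in 1:10) {
    tr <- ape::rtree(8, tip.label = paste0("t", 1:8))
    g <- generate_matrix_on_tree(tr, 100, flip_prob = 0.05, seed = 100 + s)
    ts <- branch_and_bound(g$matrix, max_trees = 1L)
    among_mp[s] <- fitch_score(ape::unroot(tr), g$matrix) == ts$score
    cons <- strict_consensus(ts)
    compatible[s] <- all(tree_splits(cons) %in%
                           tree_splits(ape::unroot(tr)))
  }
  # the generating tree attains the minimum length in most replicates and
  # the strict consensus rarely asserts a split absent from the truth
  expect_gte(mean(among_mp), 0.8)
  expect_gte(mean(compatible), 0.8)
})
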