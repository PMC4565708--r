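test_that("column standardization is exact and idempotent", {
  m <- matrix(c(1, 3), 2, 1, dimnames = list(c("X", "Y"), "01"))
  x <- suppressWarnings(
    scaled_mean_matrix(fake_profiles(m), fake_tests("01")))
  expect_equal(unname(x[, 1]), c(-1, 1) / sqrt(2), tolerance = 1e-12)

  set.seed(8)
  m2 <- matrix(rnorm(24), 6, 4,
               dimnames = list(paste0("S", 1:6), sprintf("%02d", 1:4)))
  x2 <- scaled_mean_matrix(fake_profiles(m2), fake_tests(colnames(m2)))
  expect_true(all(abs(colMeans(x2)) < 1e-12))
  expect_true(all(abs(apply(x2, 2, sd) - 1) < 1e-12))
  # idempotence
  x3 <- clonodiverge:::standardize_columns(x2)
  expect_equal(x2, x3, tolerance = 1e-12)
})

test_that("Euclidean distances match a direct double-loop computation", {
  expect_equal(euclidean_distances(rbind(a = c(0, 0), b = c(3, 4)))["a", "b"],
               5)
  set.seed(9)
  x <- matrix(rnorm(30), 6, 5, dimnames = list(paste0("s", 1:6), NULL))
  d <- euclidean_distances(x)
  for (i in 1:6) for (j in 1:6)
    expect_equal(d[i, j], sqrt(sum((x[i, ] - x[j, ])^2)), tolerance = 1e-12)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
})

test_that("UPGMA matches average-linkage hclust and is ultrametric-exact", {
  # two taxa merge at half their distance
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(unname(t2$edge.length), c(1.5, 1.5))

  set.seed(10)
  for (rep in 1:5) {
    x <- matrix(rnorm(8 * 5), 8, dimnames = list(paste0("t", 1:8), NULL))
    d <- euclidean_distances(x)
    ours <- upgma(d)
    hc <- hclust(as.dist(d), method = "average")
    co1 <- as.matrix(cophenetic(ours))
    co2 <- as.matrix(cophenetic(hc))
    expect_equal(co1[rownames(co2), colnames(co2)], co2, tolerance = 1e-10)
  }

  # ultrametric input is reproduced exactly
  tru <- ape::rcoal(7)
  du <- as.matrix(cophenetic(tru))
  back <- as.matrix(cophenetic(upgma(du)))
  expect_equal(back[rownames(du), colnames(du)], du, tolerance = 1e-10)
})

test_that("UPGMA heights never decrease towards the root", {
  set.seed(12)
  x <- matrix(rnorm(10 * 4), 10, dimnames = list(paste0("t", 1:10), NULL))
  core <- clonodiverge:::upgma_core(euclidean_distances(x))
  # average linkage is reducible: the merge height sequence is monotone
  expect_true(all(diff(core$height) >= -1e-12))
})

test_that("the AU model fit recovers exact (v, c) from noiseless input", {
  scales <- seq(0.5, 1.4, by = 0.1)
  psi <- 1.2 * sqrt(scales) + 0.3 / sqrt(scales)
  bp <- matrix(1 - pnorm(psi), 1)
  fit <- au_from_bp(bp, scales, n_boot = 1000)
  expect_equal(fit$v, 1.2, tolerance = 1e-8)
  expect_equal(fit$c, 0.3, tolerance = 1e-8)
  expect_equal(fit$au, 1 - pnorm(0.9), tolerance = 1e-8)
})

test_that("AU boundary cases: always / never recovered clusters", {
  scales <- seq(0.5, 1.4, by = 0.1)
  bp <- rbind(rep(1, 10), rep(0, 10), c(rep(0.5, 9), 1))
  fit <- au_from_bp(bp, scales, n_boot = 100)
  expect_equal(fit$au[1], 1)
  expect_equal(fit$au[2], 0)
  expect_false(is.na(fit$au[3]))
  # fewer than two informative scales -> undefined, flagged
  bp4 <- matrix(c(0.4, rep(1, 9)), 1)
  fit4 <- au_from_bp(bp4, scales, n_boot = 100)
  expect_true(is.na(fit4$au[1]))
  expect_equal(fit4$n_scales[1], 1L)
})

test_that("multiscale bootstrap is bit-reproducible under a fixed seed", {
  set.seed(13)
  x <- matrix(rnorm(6 * 8), 6, dimnames = list(paste0("s", 1:6), NULL))
  a <- multiscale_bootstrap(x, n_boot = 100, seed = 99)
  b <- multiscale_bootstrap(x, n_boot = 100, seed = 99)
  expect_identical(a$bp_table, b$bp_table)
  expect_identical(a$support, b$support)
  expect_true(all(a$support$bp >= 0 & a$support$bp <= 1))
  expect_true(all(a$support$au >= 0 & a$support$au <= 1, na.rm = TRUE))
  # a different seed gives a different resampling path
  c2 <- multiscale_bootstrap(x, n_boot = 100, seed = 100)
  expect_false(identical(a$bp_table, c2$bp_table))
})
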