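test_that("intercept-only GLM fits equal sample means exactly", {
  f <- fit_glm(c(2, 4, 6), matrix(1, 3, 1), "poisson")
  expect_equal(unname(f$coefficients), log(4), tolerance = 1e-12)
  expect_equal(unname(f$fitted[1]), 4, tolerance = 1e-12)
  f <- fit_glm(c(1, 1, 0, 0), matrix(1, 4, 1), "binomial")
  expect_equal(unname(f$coefficients), 0, tolerance = 1e-10)
  expect_equal(unname(f$fitted[1]), 0.5, tolerance = 1e-10)
  expect_true(f$converged)
})

test_that("factor-model fits match a numerical likelihood maximizer", {
  y <- c(1, 3, 10, 14)
  X <- cbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  f <- fit_glm(y, X, "poisson")
  expect_equal(sort(unique(round(f$fitted, 8))), c(2, 12))
  expect_equal(f$deviance, oracle_glm_deviance(y, X, "poisson"),
               tolerance = 1e-6)

  # random designs, both families, against BFGS on the exact likelihood
  set.seed(42)
  for (rep in 1:6) {
    n <- 30
    X <- cbind(1, matrix(rnorm(n * 2), n))
    for (family in c("binomial", "poisson")) {
      eta <- drop(X %*% c(0.2, 0.5, -0.3))
      y <- if (family == "binomial") rbinom(n, 1, plogis(eta))
           else rpois(n, exp(eta))
      f <- fit_glm(y, X, family)
      expect_equal(f$deviance, oracle_glm_deviance(y, X, family),
                   tolerance = 1e-6)
    }
  }
})

test_that("divergence test is a likelihood-ratio chi-square on strains - 1 df", {
  # three strains, binary states with closed-form per-strain likelihoods
  tab <- make_obs(rep(c("A", "B", "C"), each = 4),
                  c(1, 1, 1, 1, 0, 0, 0, 0, 1, 0, 1, 0))
  spec <- attr(tab, "specs")
  dt <- divergence_test(tab, make_spec_binomial())
  # oracle: 2 * (sum of per-strain max log-lik - pooled max log-lik)
  loglik_cell <- function(k, n) {
    p <- k / n
    if (p %in% c(0, 1)) 0 else k * log(p) + (n - k) * log(1 - p)
  }
  ll1 <- loglik_cell(4, 4) + loglik_cell(0, 4) + loglik_cell(2, 4)
  ll0 <- loglik_cell(6, 12)
  expect_equal(dt$chi_square, 2 * (ll1 - ll0), tolerance = 1e-6)
  expect_equal(dt$df, 2L)
  expect_equal(dt$p_value, pchisq(dt$chi_square, 2, lower.tail = FALSE))
})

test_that("degenerate and invariant responses are handled", {
  tab <- make_obs(rep(c("A", "B"), each = 3), rep(1, 6))
  dt <- divergence_test(tab, make_spec_binomial())
  expect_equal(dt$chi_square, 0)
  expect_equal(dt$p_value, 1)
  expect_false(dt$significant)

  one <- make_obs(rep("A", 4), c(1, 0, 1, 0))
  expect_error(divergence_test(one, make_spec_binomial()),
               "fewer than 2 strains")
})

test_that("the LR statistic is invariant to strain relabelling and side swaps", {
  set.seed(7)
  strains <- rep(c("A", "B", "C", "D"), each = 6)
  y <- rbinom(24, 1, rep(c(0.2, 0.5, 0.8, 0.4), each = 6))
  t1 <- divergence_test(make_obs(strains, y), make_spec_binomial())
  relabel <- c(A = "D2", B = "C2", C = "B2", D = "A2")
  t2 <- divergence_test(make_obs(unname(relabel[strains]), y),
                        make_spec_binomial())
  expect_equal(t1$chi_square, t2$chi_square, tolerance = 1e-8)
  # flipping the binary coding leaves the LR unchanged
  t3 <- divergence_test(make_obs(strains, 1 - y), make_spec_binomial())
  expect_equal(t1$chi_square, t3$chi_square, tolerance = 1e-8)
})

test_that("strain profiles report Wald intervals on the response scale", {
  tab <- make_obs(rep("A", 10), c(rep(1, 5), rep(0, 5)))
  pr <- strain_profile(tab, make_spec_binomial())
  expect_equal(pr$mean, 0.5)
  # symmetric on the logit scale around 0
  expect_equal(pr$ci_low, 1 - pr$ci_high, tolerance = 1e-10)

  tabp <- observation_table(
    data.frame(strain_id = "A", individual_id = paste0("A-", 1:4),
               character_id = "01", side = "none", value = c(3, 5, 4, 4)),
    poisson_spec())
  prp <- strain_profile(tabp, poisson_spec())
  expect_equal(prp$mean, 4)
  se <- sqrt(1 / 16)
  expect_equal(prp$ci_low, exp(log(4) - 1.96 * se), tolerance = 1e-10)
  expect_equal(prp$ci_high, exp(log(4) + 1.96 * se), tolerance = 1e-10)

  # boundary cell: exact mean, degenerate interval flag
  tab0 <- make_obs(rep("A", 8), rep(0, 8))
  pr0 <- strain_profile(tab0, make_spec_binomial())
  expect_equal(pr0$mean, 0)
  expect_true(pr0$degenerate)
})

test_that("test summaries count significant characters", {
  tests <- data.frame(character_id = c("01", "02", "03"),
                      family = "binomial", chi_square = c(9, 2, 12),
                      df = 2, p_value = c(0.01, 0.2, 0.003),
                      significant = c(TRUE, FALSE, TRUE))
  s <- summarize_tests(tests)
  expect_equal(s$n_significant, 2L)
  expect_equal(summarize_tests(tests[0, ])$n_significant, 0L)
})
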