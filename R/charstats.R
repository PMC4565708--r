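#' Per-character divergence test across strains
#'
#' Tests whether a character differs globally between strains with a
#' likelihood-ratio (analysis-of-deviance) chi-square: the deviance of the
#' intercept-only model minus the deviance of the model with strain as a
#' factor, referred to a chi-square distribution on (number of strains − 1)
#' degrees of freedom. Count characters with a binarization threshold in their
#' spec are binarized first, so the test is run on the same two-state variable
#' the paper-style analysis uses.
#'
#' @param table An [observation_table()].
#' @param spec One row of a [character_specs()] table (or the full table plus
#'   `character_id`).
#' @param character_id Character to test when `spec` has several rows.
#' @param alpha Significance level for the `significant` flag.
#' @return A one-row data frame: `character_id`, `family`, `chi_square`, `df`,
#'   `p_value`, `significant`.
#' @export
divergence_test <- function(table, spec, character_id = NULL, alpha = 0.05) {
  if (!is.null(character_id)) spec <- spec_for(spec, character_id)
  rows <- character_rows(table, spec)
  strains <- sort(unique(rows$strain_id))
  if (length(strains) < 2)
    stop("character ", spec$character_id,
         ": fewer than 2 strains with non-missing data")
  y <- rows$value
  if (length(unique(y)) == 1L) {
    chi <- 0
    df <- length(strains) - 1L
    return(data.frame(character_id = spec$character_id, family = spec$family,
                      chi_square = 0, df = df, p_value = 1,
                      significant = FALSE, stringsAsFactors = FALSE))
  }
  X0 <- matrix(1, length(y), 1L)
  X1 <- outer(rows$strain_id, strains, `==`) * 1
  fit0 <- fit_glm(y, X0, spec$family)
  fit1 <- fit_glm(y, X1, spec$family)
  chi <- max(fit0$deviance - fit1$deviance, 0)
  df <- length(strains) - 1L
  p <- pchisq(chi, df, lower.tail = FALSE)
  data.frame(character_id = spec$character_id, family = spec$family,
             chi_square = chi, df = df, p_value = p,
             significant = p < alpha, stringsAsFactors = FALSE)
}

#' Divergence tests for every character
#'
#' @inheritParams divergence_test
#' @param specs A [character_specs()] table; characters absent from `table`
#'   are skipped.
#' @return A `divergence_tests` data frame, one row per character.
#' @export
character_tests <- function(table, specs, alpha = 0.05) {
  ids <- intersect(specs$character_id, unique(table$character_id))
  out <- do.call(rbind, lapply(ids, function(id)
    divergence_test(table, specs, character_id = id, alpha = alpha)))
  class(out) <- c("divergence_tests", "data.frame")
  out
}

#' Summarize divergence tests
#'
#' @param tests A `divergence_tests` data frame.
#' @param alpha Significance level.
#' @return List with the test table, `n_characters`, and `n_significant` (the
#'   count of characters with between-strain variation at `alpha`).
#' @export
summarize_tests <- function(tests, alpha = 0.05) {
  if (is.null(tests) || nrow(tests) == 0L)
    return(list(tests = tests, n_characters = 0L, n_significant = 0L))
  list(tests = tests,
       n_characters = nrow(tests),
       n_significant = sum(tests$p_value < alpha))
}

#' Per-strain character means with 95% confidence intervals
#'
#' Fits the strain-factor model without intercept, so each coefficient is the
#' strain's maximum-likelihood mean on the link scale; 95% Wald intervals
#' (±1.96 standard errors from the Fisher information) are back-transformed to
#' the response scale. Degenerate cells (all 0, or all 1 for binomial) report
#' the boundary mean exactly with a `degenerate` flag instead of an interval.
#'
#' @inheritParams divergence_test
#' @return A `strain_profile` data frame: `character_id`, `strain_id`,
#'   `n_obs`, `mean`, `ci_low`, `ci_high`, `degenerate`.
#' @export
strain_profile <- function(table, spec, character_id = NULL) {
  if (!is.null(character_id)) spec <- spec_for(spec, character_id)
  rows <- character_rows(table, spec)
  strains <- sort(unique(rows$strain_id))
  out <- lapply(strains, function(s) {
    y <- rows$value[rows$strain_id == s]
    n <- length(y)
    m <- mean(y)
    degen <- (spec$family == "binomial" && (m == 0 || m == 1)) ||
      (spec$family == "poisson" && m == 0)
    if (degen) {
      ci <- c(m, m)
    } else if (spec$family == "binomial") {
      # logit-scale SE from Fisher information n * p * (1 - p)
      se <- sqrt(1 / (n * m * (1 - m)))
      lo <- log(m / (1 - m)) + c(-1, 1) * 1.96 * se
      ci <- 1 / (1 + exp(-lo))
    } else {
      # log-scale SE: Var(log lambda_hat) = 1 / (n * lambda_hat)
      se <- sqrt(1 / (n * m))
      ci <- exp(log(m) + c(-1, 1) * 1.96 * se)
    }
    data.frame(character_id = spec$character_id, strain_id = s, n_obs = n,
               mean = m, ci_low = ci[1], ci_high = ci[2], degenerate = degen,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("strain_profile", "data.frame")
  out
}

#' Strain profiles for every character
#'
#' @inheritParams character_tests
#' @return A `strain_profile` data frame across all characters present.
#' @export
strain_profiles <- function(table, specs) {
  ids <- intersect(specs$character_id, unique(table$character_id))
  out <- do.call(rbind, lapply(ids, function(id)
    strain_profile(table, specs, character_id = id)))
  class(out) <- c("strain_profile", "data.frame")
  out
}
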