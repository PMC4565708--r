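# Broad-sense heritability by variance partitioning: a random-intercept
# generalized linear mixed model with strain as the random factor, fitted by
# penalized quasi-likelihood (IRLS-linearized working response + REML
# variance components on the working linear mixed model), iterated until the
# between-strain variance stabilizes. H^2 is the latent-scale intraclass
# correlation: the residual variance is pi^2/3 on the logit scale (binomial)
# and log(1 + 1/lambda_bar) on the log scale (Poisson, lognormal
# approximation with lambda_bar the grand mean).

latent_residual_variance <- function(family, lambda_bar = NULL) {
  if (family == "binomial") pi^2 / 3
  else log(1 + 1 / lambda_bar)
}

# REML profile likelihood for the one-way random-intercept working model
# z_ij = beta0 + b_i + e_ij, Var(b) = gamma * phi, Var(e_ij) = phi / w_ij.
# Returns beta0, gamma, phi and the BLUPs for fixed weights and response.
reml_working_fit <- function(z, w, group) {
  sw <- tapply(w, group, sum)
  Sz <- tapply(w * z, group, sum)
  N <- length(z)

  prof <- function(gamma) {
    d <- 1 + gamma * sw
    beta0 <- sum(Sz / d) / sum(sw / d)
    # per-group weighted residual sums
    r <- z - beta0
    Swr2 <- tapply(w * r^2, group, sum)
    Swr <- tapply(w * r, group, sum)
    Q <- sum(Swr2) - gamma * sum(Swr^2 / d)
    Q <- max(Q, 1e-12)
    ll <- -0.5 * ((N - 1) * log(Q) + sum(log(d)) + log(sum(sw / d)))
    list(ll = ll, beta0 = beta0, Q = Q, Swr = Swr, d = d)
  }

  # optimize over log(gamma), compare against the gamma = 0 boundary
  f <- function(t) prof(exp(t))$ll
  opt <- optimize(f, interval = c(-15, 12), maximum = TRUE)
  gamma <- exp(opt$maximum)
  if (prof(0)$ll >= opt$objective) gamma <- 0
  fit <- prof(gamma)
  phi <- fit$Q / (N - 1)
  blup <- gamma * fit$Swr / fit$d
  list(beta0 = fit$beta0, gamma = gamma, phi = phi, blup = blup)
}

pql_fit <- function(y, group, family, tol = 1e-6, max_outer = 200L) {
  group <- factor(group)
  if (nlevels(group) < 3) stop("need at least 3 strains for a GLMM fit")
  if (length(unique(y)) == 1L)
    return(list(sigma2_G = 0, phi = NA_real_, beta0 = NA_real_,
                blup = setNames(rep(0, nlevels(group)), levels(group)),
                converged = TRUE, boundary = TRUE, iter = 0L))
  mu <- if (family == "binomial") (y + 0.5) / 2 else y + 0.1
  eta <- if (family == "binomial") log(mu / (1 - mu)) else log(mu)
  sigma2_G <- 0
  converged <- FALSE
  iter <- 0L
  fit <- NULL
  repeat {
    iter <- iter + 1L
    mu <- glm_mu(eta, family)
    w <- pmax(glm_variance(mu, family), 1e-10)
    z <- eta + (y - mu) / w
    fit <- reml_working_fit(z, w, group)
    sg_new <- fit$gamma * fit$phi
    eta <- fit$beta0 + fit$blup[as.integer(group)]
    eta <- pmin(pmax(eta, -15), 15)
    if (abs(sg_new - sigma2_G) < tol * max(1, sg_new)) {
      sigma2_G <- sg_new
      converged <- TRUE
      break
    }
    sigma2_G <- sg_new
    if (iter >= max_outer) break
  }
  list(sigma2_G = sigma2_G, phi = fit$phi, beta0 = fit$beta0,
       blup = setNames(as.numeric(fit$blup), levels(group)),
       converged = converged, boundary = sigma2_G <= 1e-10, iter = iter)
}

#' Variance components and broad-sense heritability for one character
#'
#' Partitions a character's variance into a between-strain (genetic)
#' component and a residual component with a strain random-intercept GLMM
#' fitted by penalized quasi-likelihood, and reports the broad-sense
#' heritability H² = σ²G / (σ²G + σ²E) on the latent (link) scale. For clonal
#' strains all individuals of a strain are genetically identical, so the
#' between-strain variance is the genetic variance. Count characters with a
#' binarization rule are binarized first, matching the divergence test.
#'
#' @inheritParams divergence_test
#' @return A `variance_components` list: `character_id`, `family`,
#'   `sigma2_G`, `sigma2_E`, `sigma2_T`, `H2`, `n_strains`, `n_obs`,
#'   `converged`, `boundary`.
#' @export
fit_glmm_pql <- function(table, spec, character_id = NULL) {
  if (!is.null(character_id)) spec <- spec_for(spec, character_id)
  rows <- character_rows(table, spec)
  if (length(unique(rows$strain_id)) < 3)
    stop("character ", spec$character_id, ": fewer than 3 strains")
  fit <- pql_fit(rows$value, rows$strain_id, spec$family)
  lambda_bar <- if (spec$family == "poisson") mean(rows$value) else NULL
  s2e <- latent_residual_variance(spec$family, lambda_bar)
  s2g <- fit$sigma2_G
  structure(list(character_id = spec$character_id, family = spec$family,
                 sigma2_G = s2g, sigma2_E = s2e, sigma2_T = s2g + s2e,
                 H2 = s2g / (s2g + s2e),
                 n_strains = length(unique(rows$strain_id)),
                 n_obs = nrow(rows),
                 converged = fit$converged, boundary = fit$boundary),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Character ", x$character_id, " (", x$family, "): H2 = ",
      sprintf("%.1f%%", 100 * x$H2), "  [sigma2_G = ",
      format(x$sigma2_G, digits = 4), ", sigma2_E = ",
      format(x$sigma2_E, digits = 4), "]",
      if (!x$converged) "  NOT CONVERGED", "\n", sep = "")
  invisible(x)
}

#' Heritability report for the significant characters
#'
#' Broad-sense heritability for every character with significant
#' between-strain variation (only those are heritable in a meaningful sense;
#' non-significant characters carry no detectable genetic variance).
#'
#' @inheritParams character_tests
#' @param tests A [character_tests()] result.
#' @param h2_threshold Threshold defining "high" heritability in the summary
#'   attributes.
#' @return A data frame with one row per significant character
#'   (`character_id`, `family`, `sigma2_G`, `sigma2_E`, `H2`, `converged`),
#'   with attributes `n_high` (count of characters with `H2 > h2_threshold`)
#'   and `max_H2`.
#' @export
heritability_table <- function(table, specs, tests, alpha = 0.05,
                               h2_threshold = 0.78) {
  keep <- tests$character_id[tests$p_value < alpha]
  rows <- lapply(keep, function(id) {
    vc <- fit_glmm_pql(table, specs, character_id = id)
    data.frame(character_id = id, family = vc$family,
               sigma2_G = vc$sigma2_G, sigma2_E = vc$sigma2_E, H2 = vc$H2,
               converged = vc$converged, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(character_id = character(0), family = character(0),
               sigma2_G = numeric(0), sigma2_E = numeric(0), H2 = numeric(0),
               converged = logical(0))
  attr(out, "n_high") <- sum(out$H2 > h2_threshold)
  attr(out, "max_H2") <- if (nrow(out)) max(out$H2) else NA_real_
  class(out) <- c("heritability_table", "data.frame")
  out
}
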