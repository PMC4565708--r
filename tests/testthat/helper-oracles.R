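# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: likelihoods are maximized numerically, parsimony
# scores come from exhaustive enumeration, average linkage from stats::hclust.

# exact log-likelihoods (up to data-only constants matching the deviance)
oracle_loglik <- function(beta, y, X, family) {
  eta <- drop(X %*% beta)
  if (family == "binomial") {
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    sum(y * log(mu) + (1 - y) * log(1 - mu))
  } else {
    sum(y * eta - exp(eta))
  }
}

# deviance at the numerically maximized likelihood
oracle_glm_deviance <- function(y, X, family) {
  p <- ncol(X)
  opt <- optim(rep(0, p), function(b) -oracle_loglik(b, y, X, family),
               method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  sat <- if (family == "binomial") 0 else
    sum(ifelse(y > 0, y * log(y) - y, 0))
  ll <- -opt$value
  if (family == "binomial") -2 * ll else 2 * (sat - ll)
}

# minimum changes of one binary character on a tree, by enumerating every
# ancestral state assignment (rooted representation of the unrooted tree)
oracle_min_changes <- function(tree, tip_states) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  internal <- seq(n + 1L, nn)
  states <- integer(nn)
  states[seq_len(n)] <- tip_states[tree$tip.label]
  best <- Inf
  for (a in 0:(2^length(internal) - 1)) {
    bits <- as.integer(intToBits(a))[seq_along(internal)]
    states[internal] <- bits
    ch <- sum(states[tree$edge[, 1]] != states[tree$edge[, 2]])
    best <- min(best, ch)
  }
  best
}

# random unrooted binary tree on the given labels
random_unrooted_tree <- function(labels) {
  ape::unroot(ape::rtree(length(labels), tip.label = sample(labels)))
}

# small long-format observation table for hand-built cases
make_obs <- function(strain, value, character_id = "01", side = "none",
                     specs = NULL) {
  df <- data.frame(strain_id = strain,
                   individual_id = paste0(strain, "-", seq_along(strain)),
                   character_id = character_id, side = side, value = value,
                   stringsAsFactors = FALSE)
  if (is.null(specs))
    specs <- character_specs(data.frame(
      character_id = unique(character_id), body_part = "head",
      family = "binomial", bilateral = any(side != "none"),
      cut = NA_integer_, low_includes_cut = NA,
      description = "test", stringsAsFactors = FALSE))
  observation_table(df, specs)
}

# strain-profile and test tables built directly from a means matrix
fake_profiles <- function(means) {
  do.call(rbind, lapply(colnames(means), function(ch)
    data.frame(character_id = ch, strain_id = rownames(means),
               n_obs = 10L, mean = means[, ch], ci_low = NA_real_,
               ci_high = NA_real_, degenerate = FALSE,
               stringsAsFactors = FALSE)))
}

fake_tests <- function(ids, p = 0.001) {
  data.frame(character_id = ids, family = "binomial", chi_square = 50,
             df = 11, p_value = p, significant = p < 0.05,
             stringsAsFactors = FALSE)
}

make_spec_binomial <- function() {
  character_specs(data.frame(
    character_id = "01", body_part = "head", family = "binomial",
    bilateral = FALSE, cut = NA_integer_, low_includes_cut = NA,
    description = "test", stringsAsFactors = FALSE))
}

poisson_spec <- function(character_id = "01") {
  character_specs(data.frame(
    character_id = character_id, body_part = "head", family = "poisson",
    bilateral = FALSE, cut = NA_integer_, low_includes_cut = NA,
    description = "test", stringsAsFactors = FALSE))
}
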