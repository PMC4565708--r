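#' Synthetic clonal-strain study designs
#'
#' `sim_character_table()` builds a character design table for the generator;
#' `default_sim_characters()` returns the built-in 18-character design that
#' emulates the chaetotaxy study system: pure binary presence/absence
#' characters, near-binary counts with rare single outliers, and wide-range
#' Poisson counts, with between-strain (genetic) latent variances spanning
#' non-heritable to highly heritable characters. `generator_config()`
#' validates a full simulation configuration.
#'
#' @param character_id,family,baseline,sigma2_G,bilateral,outlier_rate,base_count,clade_sign
#'   Per-character design columns: distribution family; baseline on the link
#'   scale; between-strain latent variance; whether the character is scored
#'   on both body sides; rate of rare outlier excursions (near-binary counts
#'   only); additive count offset giving near-binary characters their raw
#'   count range (raw value = base_count + state); and the sign (−1, 0, +1)
#'   with which the clade effect applies to the character.
#' @return A `sim_characters` data frame.
#' @export
sim_character_table <- function(character_id, family, baseline, sigma2_G,
                                bilateral = FALSE, outlier_rate = 0,
                                base_count = 0L, clade_sign = 0) {
  x <- data.frame(character_id = as.character(character_id),
                  family = family, baseline = baseline,
                  sigma2_G = sigma2_G, bilateral = bilateral,
                  outlier_rate = outlier_rate,
                  base_count = as.integer(base_count),
                  clade_sign = clade_sign, stringsAsFactors = FALSE)
  stopifnot(all(x$family %in% c("binomial", "poisson")),
            all(x$sigma2_G >= 0),
            all(x$outlier_rate >= 0 & x$outlier_rate <= 1))
  class(x) <- c("sim_characters", "data.frame")
  x
}

#' @rdname sim_character_table
#' @export
default_sim_characters <- function() {
  sim_character_table(
    character_id = sprintf("%02d", 1:18),
    family = c("binomial", "binomial", "poisson", "binomial", "binomial",
               "binomial", "poisson", "poisson", "poisson", "binomial",
               "binomial", "poisson", "poisson", "binomial", "binomial",
               "binomial", "binomial", "poisson"),
    baseline = c(0, 0, log(24), 0, 0,
                 0, log(8), log(6), log(10), 0,
                 0, log(30), log(6), 0, 0,
                 0, 0, log(18)),
    # latent variances implied by broad-sense heritabilities spanning
    # ~4% to 94% under the latent-scale residual convention
    sigma2_G = c(51.5, 11.7, 0.0019, 20.2, 51.5,
                 0.15, 0, 0, 0, 24.1,
                 11.7, 0.0024, 0.021, 13.2, 0.58,
                 51.5, 18.6, 0.0074),
    bilateral = c(FALSE, FALSE, FALSE, FALSE, TRUE,
                  FALSE, FALSE, FALSE, FALSE, FALSE,
                  FALSE, TRUE, TRUE, TRUE, TRUE,
                  FALSE, TRUE, TRUE),
    outlier_rate = c(0, 0.02, 0, 0.02, 0.02,
                     0.03, 0, 0, 0, 0,
                     0.02, 0, 0, 0.02, 0.02,
                     0.03, 0.02, 0),
    base_count = c(0L, 4L, 0L, 4L, 0L,
                   3L, 0L, 0L, 0L, 0L,
                   1L, 0L, 0L, 3L, 3L,
                   2L, 1L, 0L),
    # clade tendency (oligo- vs polychaetotic): logit-scale shifts for the
    # two-state characters, damped log-scale shifts for wide counts
    clade_sign = c(0, 1, 0.1, 0, 1,
                   0, 0, 0, 0, 0,
                   -1, 0, 0, 0, 0,
                   1, 0, 0.1)
  )
}

#' @rdname sim_character_table
#' @param n_strains Number of strains.
#' @param n_individuals Individuals per strain: a single number or a
#'   `c(min, max)` range sampled uniformly per strain.
#' @param characters A `sim_characters` design table.
#' @param clades Optional named character vector mapping strain labels to
#'   `"A"`/`"B"`.
#' @param clade_effect Link-scale shift between the clades (applied as
#'   ±`clade_effect`/2 times the character's `clade_sign`).
#' @param missing_rate Probability that any single observation is missing.
#' @param seed Mandatory RNG seed; all randomness flows from it.
#' @param strain_labels Optional strain labels (default `"S01"`, ...).
#' @export
generator_config <- function(n_strains = 12L, n_individuals = c(8L, 12L),
                             characters = default_sim_characters(),
                             clades = NULL, clade_effect = 0,
                             missing_rate = 0.03, seed,
                             strain_labels = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_strains >= 2, missing_rate >= 0, missing_rate <= 1,
            inherits(characters, "sim_characters"))
  if (length(n_individuals) == 1L) n_individuals <- rep(n_individuals, 2L)
  if (is.null(strain_labels))
    strain_labels <- sprintf("S%02d", seq_len(n_strains))
  stopifnot(length(strain_labels) == n_strains)
  if (!is.null(clades)) {
    stopifnot(all(names(clades) %in% strain_labels),
              all(clades %in% c("A", "B")))
  }
  structure(list(n_strains = as.integer(n_strains),
                 n_individuals = as.integer(n_individuals),
                 characters = characters, clades = clades,
                 clade_effect = clade_effect,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 strain_labels = strain_labels),
            class = "generator_config")
}

#' Generate a synthetic clonal-strain observation table
#'
#' Simulates per-individual character observations under the model the
#' analysis assumes: per character, strain latent effects are drawn from
#' Normal(0, σ²G) on the link scale, shifted by ±clade_effect/2 when a clade
#' structure is configured; each individual (and body side, for bilateral
#' characters — sides are independent draws) is a binomial draw through the
#' logit link or a Poisson draw through the log link. Near-binary count
#' characters report `base_count + state` with rare outlier excursions of
#' ±1–2 counts (outliers occur singly, mimicking rare variants); missing
#' flags are set at `missing_rate`. The truth record stores every latent
#' value and the implied true latent-scale H² per character
#' (σ²G / (σ²G + π²/3) for binomial; σ²G / (σ²G + log(1 + 1/λ̄)) with
#' λ̄ = exp(baseline + σ²G/2) for Poisson).
#'
#' @param config A [generator_config()].
#' @return List with `table` (an `obs_table`), `specs` (a matching
#'   [character_specs()] table) and `truth` (list: per-character data frame
#'   `characters` with `sigma2_G`, `sigma2_E_latent`, `H2_latent`; matrix
#'   `strain_effects`; the `clades` map; the `config`).
#' @export
generate_observations <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  ch <- config$characters
  strains <- config$strain_labels
  ns <- config$n_strains
  n_ind <- if (config$n_individuals[1] == config$n_individuals[2])
    rep(config$n_individuals[1], ns)
  else sample(seq(config$n_individuals[1], config$n_individuals[2]), ns,
              replace = TRUE)
  clade_shift <- rep(0, ns)
  if (!is.null(config$clades) && config$clade_effect != 0) {
    cl <- config$clades[strains]
    clade_shift <- ifelse(is.na(cl), 0,
                          ifelse(cl == "A", -0.5, 0.5)) * config$clade_effect
  }

  effects <- matrix(0, ns, nrow(ch), dimnames = list(strains,
                                                     ch$character_id))
  rows <- vector("list", nrow(ch))
  for (j in seq_len(nrow(ch))) {
    u <- rnorm(ns, 0, sqrt(ch$sigma2_G[j]))
    eta_strain <- ch$baseline[j] + u + ch$clade_sign[j] * clade_shift
    effects[, j] <- eta_strain
    per <- lapply(seq_len(ns), function(i) {
      k <- n_ind[i]
      sides <- if (ch$bilateral[j]) c("left", "right") else "none"
      eta <- eta_strain[i]
      nobs <- k * length(sides)
      state <- if (ch$family[j] == "binomial")
        rbinom(nobs, 1, 1 / (1 + exp(-eta)))
      else rpois(nobs, exp(eta))
      value <- state + ch$base_count[j]
      if (ch$outlier_rate[j] > 0) {
        out <- runif(nobs) < ch$outlier_rate[j]
        jump <- sample(c(-2L, -1L, 1L, 2L), sum(out), replace = TRUE)
        value[out] <- pmax(value[out] + jump, 0L)
      }
      miss <- runif(nobs) < config$missing_rate
      data.frame(strain_id = strains[i],
                 individual_id = paste0(strains[i], "-",
                                        rep(seq_len(k),
                                            each = length(sides))),
                 character_id = ch$character_id[j],
                 side = rep(sides, times = k),
                 value = ifelse(miss, NA_integer_, as.integer(value)),
                 missing = miss, stringsAsFactors = FALSE)
    })
    rows[[j]] <- do.call(rbind, per)
  }
  obs <- do.call(rbind, rows)

  specs <- character_specs(data.frame(
    character_id = ch$character_id,
    body_part = "head",
    family = ch$family,
    bilateral = ch$bilateral,
    cut = ifelse(ch$family == "binomial" &
                   (ch$base_count > 0 | ch$outlier_rate > 0),
                 ch$base_count, NA_integer_),
    low_includes_cut = ifelse(ch$family == "binomial" &
                                (ch$base_count > 0 | ch$outlier_rate > 0),
                              TRUE, NA),
    description = paste("synthetic character", ch$character_id),
    stringsAsFactors = FALSE))

  lambda_bar <- exp(ch$baseline + ch$sigma2_G / 2)
  s2e <- ifelse(ch$family == "binomial", pi^2 / 3,
                log(1 + 1 / lambda_bar))
  truth <- list(
    characters = data.frame(character_id = ch$character_id,
                            family = ch$family,
                            sigma2_G = ch$sigma2_G,
                            sigma2_E_latent = s2e,
                            H2_latent = ch$sigma2_G / (ch$sigma2_G + s2e),
                            stringsAsFactors = FALSE),
    strain_effects = effects,
    clades = config$clades,
    config = config)
  list(table = observation_table(obs, specs), specs = specs, truth = truth)
}

#' Simulate a binary character matrix on a known tree
#'
#' Binary states evolve from the root towards the leaves, flipping state on
#' each edge with probability `flip_prob`; the generating tree is returned
#' as the truth record. Direct test input for the parsimony machinery.
#'
#' @param tree A rooted `phylo`.
#' @param n_characters Number of characters to simulate.
#' @param flip_prob Per-edge state-flip probability, in \[0, 0.5).
#' @param seed Mandatory RNG seed.
#' @return List with `matrix` (taxa × characters 0/1 matrix) and `tree`.
#' @export
generate_matrix_on_tree <- function(tree, n_characters, flip_prob, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (flip_prob < 0 || flip_prob >= 0.5)
    stop("flip_prob must be in [0, 0.5)")
  set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")  # root-to-tip edge order
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  states <- matrix(NA_integer_, nn, n_characters)
  root <- n + 1L
  states[root, ] <- rbinom(n_characters, 1, 0.5)
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]
    ch <- tree$edge[k, 2]
    flip <- rbinom(n_characters, 1, flip_prob)
    states[ch, ] <- bitwXor(states[par, ], flip)
  }
  m <- states[seq_len(n), , drop = FALSE]
  rownames(m) <- tree$tip.label
  colnames(m) <- sprintf("c%02d", seq_len(n_characters))
  list(matrix = m, tree = tree)
}

#' Two-clade study configuration
#'
#' Convenience configuration emulating the study design used for end-to-end
#' clade-recovery checks: 12 strains in two clades of 5 ("A") and 7 ("B"),
#' 8–12 individuals each, and 8 informative binomial characters whose
#' between-clade shift (`clade_effect`, default 2.0 on the logit scale) is
#' large relative to the within-clade latent standard deviation
#' (σ²G = 0.25, i.e. clade effect = 4 × within-clade sd).
#'
#' @param seed Mandatory RNG seed.
#' @param n_characters Number of informative characters.
#' @param clade_effect Link-scale between-clade shift.
#' @param sigma2_G Within-clade between-strain latent variance.
#' @return A [generator_config()].
#' @export
two_clade_config <- function(seed, n_characters = 8L, clade_effect = 2,
                             sigma2_G = 0.25) {
  labels <- c("A1", "A2", "A3", "A4", "A5",
              "B1", "B2", "B3", "B4", "B5", "B6", "B7")
  clades <- setNames(c(rep("A", 5), rep("B", 7)), labels)
  chars <- sim_character_table(
    character_id = sprintf("%02d", seq_len(n_characters)),
    family = "binomial", baseline = 0, sigma2_G = sigma2_G,
    bilateral = FALSE, outlier_rate = 0, base_count = 0L, clade_sign = 1)
  generator_config(n_strains = 12L, n_individuals = c(8L, 12L),
                   characters = chars, clades = clades,
                   clade_effect = clade_effect, missing_rate = 0.02,
                   seed = seed, strain_labels = labels)
}
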