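#' Threshold rules for near-binary count characters
#'
#' Many count characters concentrate nearly all observations on two adjacent
#' values with rare outliers. Such characters are analysed as two-state
#' variables by grouping outliers and rare values with their nearest common
#' ones: every value on one side of an integer cut maps to state 0 and the
#' rest to state 1, so the rule is total and monotone on the non-negative
#' integers.
#'
#' @param character_id Character label the rule belongs to.
#' @param cut Integer threshold.
#' @param low_includes_cut If `TRUE` (default), values `<= cut` map to state 0
#'   and values `> cut` to state 1; if `FALSE`, values `< cut` map to 0.
#' @return A `threshold_rule` object.
#' @export
threshold_rule <- function(character_id, cut, low_includes_cut = TRUE) {
  cut <- as.integer(cut)
  if (is.na(cut)) stop("cut must be an integer")
  structure(list(character_id = as.character(character_id), cut = cut,
                 low_includes_cut = isTRUE(low_includes_cut)),
            class = "threshold_rule")
}

#' @rdname threshold_rule
#' @param values Non-negative integer vector of raw states.
#' @param rule A `threshold_rule`.
#' @return `binarize()` returns a 0/1 integer vector.
#' @examples
#' binarize(c(2, 3, 4, 5), threshold_rule("06", 3))  # 0 0 1 1
#' @export
binarize <- function(values, rule) {
  stopifnot(inherits(rule, "threshold_rule"))
  if (any(values < 0, na.rm = TRUE)) stop("values must be non-negative")
  if (rule$low_includes_cut) as.integer(values > rule$cut)
  else as.integer(values >= rule$cut)
}

#' Build the binary taxon matrix for cladistic analysis
#'
#' Restricts to the characters with significant between-strain variation,
#' centres each character's strain means by their unweighted average over
#' strains, scales by their sample standard deviation, and codes state 1 where
#' the scaled value is strictly greater than 0 (strains at or below the
#' average mean get state 0). Scaling never changes the sign, so the
#' parsimony input depends only on the centred means; columns that are
#' constant across strains are coded all-0 and flagged uninformative.
#'
#' @param profiles A [strain_profiles()] data frame covering every strain for
#'   every significant character.
#' @param tests A [character_tests()] data frame.
#' @param alpha Significance gate for character selection.
#' @return A `binary_taxon_matrix`: list with `taxa`, `characters`, `states`
#'   (taxa × characters 0/1 matrix), `source_means` (the strain-mean matrix it
#'   was derived from), `scaled` (centred/scaled means) and `uninformative`
#'   (character ids of constant columns).
#' @export
build_matrix <- function(profiles, tests, alpha = 0.05) {
  keep <- tests$character_id[tests$p_value < alpha]
  if (!length(keep)) stop("no significant characters to code")
  taxa <- sort(unique(profiles$strain_id))
  means <- matrix(NA_real_, length(taxa), length(keep),
                  dimnames = list(taxa, keep))
  for (ch in keep) {
    sub <- profiles[profiles$character_id == ch, ]
    i <- match(taxa, sub$strain_id)
    if (anyNA(i))
      stop("no strain mean for strain ", taxa[which(is.na(i))[1]],
           ", character ", ch)
    means[, ch] <- sub$mean[i]
  }
  ctr <- sweep(means, 2, colMeans(means))
  sds <- apply(means, 2, sd)
  scl <- sweep(ctr, 2, ifelse(sds > 0, sds, 1), "/")
  states <- (scl > 0) * 1L
  uninf <- keep[apply(states, 2, function(s) length(unique(s)) == 1L)]
  structure(list(taxa = taxa, characters = keep, states = states,
                 source_means = means, scaled = scl, uninformative = uninf),
            class = "binary_taxon_matrix")
}

#' @export
print.binary_taxon_matrix <- function(x, ...) {
  cat("Binary taxon matrix: ", length(x$taxa), " taxa x ",
      length(x$characters), " characters",
      if (length(x$uninformative))
        paste0(" (", length(x$uninformative), " uninformative)"),
      "\n", sep = "")
  print(x$states)
  invisible(x)
}

#' Export a binary taxon matrix as NEXUS or CSV
#'
#' Writes a `DATATYPE=STANDARD` NEXUS matrix (`SYMBOLS="01"`, `MISSING=?`)
#' readable by external parsimony programs, or a plain CSV of the 0/1 states.
#'
#' @param matrix A [build_matrix()] result.
#' @param path Output file path.
#' @export
write_nexus_matrix <- function(matrix, path) {
  states <- matrix$states
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(states), ncol(states)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
    "  MATRIX"), con)
  rows <- apply(states, 1, function(s)
    paste0(ifelse(is.na(s), "?", as.character(s)), collapse = ""))
  writeLines(sprintf("    %-12s %s", rownames(states), rows), con)
  writeLines(c("  ;", "END;"), con)
  invisible(path)
}

#' @rdname write_nexus_matrix
#' @export
write_matrix_csv <- function(matrix, path) {
  out <- data.frame(strain_id = matrix$taxa, matrix$states,
                    check.names = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
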