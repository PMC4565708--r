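#' Observation tables
#'
#' An observation table is the unit of all statistics in the package: one row
#' per scored character state, in long format, with columns
#' `strain_id`, `individual_id`, `character_id`, `side` (`"left"`, `"right"`
#' or `"none"`), `value` (non-negative integer, `NA` when the character could
#' not be seen) and `missing` (logical). Bilateral characters contribute one
#' row per body side per individual; statistics treat sides as independent
#' observations.
#'
#' @param x Data frame with the columns above (`missing` may be omitted and is
#'   then derived from `is.na(value)`).
#' @param specs A [character_specs()] table used to validate character ids and
#'   laterality.
#' @return An `obs_table` (a validated data frame).
#' @export
observation_table <- function(x, specs) {
  need <- c("strain_id", "individual_id", "character_id", "side", "value")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("observation table lacks columns: ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)
  x$strain_id <- as.character(x$strain_id)
  x$individual_id <- as.character(x$individual_id)
  x$character_id <- as.character(x$character_id)
  x$side <- as.character(x$side)
  x$side[is.na(x$side) | x$side == ""] <- "none"
  if (!all(x$side %in% c("left", "right", "none")))
    stop("side must be one of left, right, none")
  if (is.character(x$value)) x$value[x$value == ""] <- NA
  x$value <- suppressWarnings(as.integer(x$value))
  if (!"missing" %in% names(x)) x$missing <- is.na(x$value)
  x$missing <- as.logical(x$missing)
  if (any(x$missing != is.na(x$value)))
    stop("each observation must have a value XOR the missing flag set")
  if (any(x$value < 0, na.rm = TRUE))
    stop("character states must be non-negative integers")

  unknown <- setdiff(unique(x$character_id), specs$character_id)
  if (length(unknown))
    stop("unknown character id(s): ", paste(unknown, collapse = ", "))
  bilat <- specs$bilateral[match(x$character_id, specs$character_id)]
  bad <- x$side != "none" & !bilat
  if (any(bad))
    stop("side given for non-bilateral character(s): ",
         paste(unique(x$character_id[bad]), collapse = ", "),
         " (rows ", paste(head(which(bad)), collapse = ", "), ")")

  x <- x[c(need, "missing")]
  attr(x, "strains") <- unique(x$strain_id)
  attr(x, "characters") <- specs$character_id[specs$character_id %in%
                                                unique(x$character_id)]
  class(x) <- c("obs_table", "data.frame")
  x
}

#' Read / write observation tables
#'
#' The canonical on-disk format is a long-format CSV with header
#' `strain_id,individual_id,character_id,side,value`; an empty `value` field
#' marks an observation where the character was not visible.
#'
#' @param path CSV file path.
#' @param specs A [character_specs()] table.
#' @return `read_observations()` returns an `obs_table`;
#'   `write_observations()` returns `path` invisibly.
#' @export
read_observations <- function(path, specs) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = "character")
  tab <- tryCatch(observation_table(x, specs), error = function(e)
    stop("failed to parse ", path, ": ", conditionMessage(e), call. = FALSE))
  tab
}

#' @rdname read_observations
#' @param table An `obs_table`.
#' @export
write_observations <- function(table, path) {
  out <- as.data.frame(table)
  out$value <- ifelse(out$missing, "", as.character(out$value))
  out$missing <- NULL
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize observation counts per strain and character
#'
#' Counts non-missing and missing observations in every (strain, character)
#' cell, so that filtering steps can be audited.
#'
#' @param table An `obs_table`.
#' @return Data frame with columns `strain_id`, `character_id`, `n_obs`,
#'   `n_missing`.
#' @export
summarize_observations <- function(table) {
  key <- paste(table$strain_id, table$character_id, sep = "\r")
  n_obs <- tapply(!table$missing, key, sum)
  n_missing <- tapply(table$missing, key, sum)
  parts <- strsplit(names(n_obs), "\r", fixed = TRUE)
  out <- data.frame(
    strain_id = vapply(parts, `[`, "", 1L),
    character_id = vapply(parts, `[`, "", 2L),
    n_obs = as.integer(n_obs),
    n_missing = as.integer(n_missing),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$character_id, out$strain_id), ]
  rownames(out) <- NULL
  out
}

# non-missing rows of one character, optionally binarized via its spec
character_rows <- function(table, spec, binarize = TRUE) {
  rows <- table[table$character_id == spec$character_id & !table$missing, ,
                drop = FALSE]
  if (binarize && spec$family == "binomial" && !is.na(spec$cut)) {
    rule <- threshold_rule(spec$character_id, spec$cut,
                           isTRUE(spec$low_includes_cut))
    rows$value <- binarize(rows$value, rule)
  }
  rows
}
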