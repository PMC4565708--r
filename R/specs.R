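#' Character specification tables
#'
#' A character specification describes how each morphological character is
#' modelled: its distribution family (`binomial` or `poisson`), whether it is
#' scored on both body sides (`bilateral`), and, for count characters analysed
#' as two-state ("near-binary") variables, the integer threshold that groups
#' rare values with their nearest common ones.
#'
#' `character_specs()` validates a data frame of specifications;
#' `default_character_specs()` returns the built-in 18-character sheet for the
#' springtail chaetotaxy system the package was designed around (characters
#' "01"--"18" on head, thorax and abdomen).
#'
#' @param x A data frame with columns `character_id`, `body_part`, `family`,
#'   `bilateral`, `cut`, `low_includes_cut`, `description`. `cut` is `NA` for
#'   characters that are already binary or modelled as Poisson counts.
#' @return A validated `character_specs` data frame.
#' @export
character_specs <- function(x) {
  need <- c("character_id", "body_part", "family", "bilateral",
            "cut", "low_includes_cut", "description")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("character spec table lacks columns: ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)[need]
  x$character_id <- as.character(x$character_id)
  if (anyDuplicated(x$character_id))
    stop("duplicated character_id in specs")
  if (!all(x$family %in% c("binomial", "poisson")))
    stop("family must be 'binomial' or 'poisson'")
  if (!all(x$body_part %in% c("head", "thorax", "abdomen")))
    stop("body_part must be head, thorax or abdomen")
  x$bilateral <- as.logical(x$bilateral)
  x$cut <- as.integer(x$cut)
  x$low_includes_cut <- as.logical(x$low_includes_cut)
  # a threshold rule only makes sense for count characters analysed as binomial
  bad <- !is.na(x$cut) & x$family != "binomial"
  if (any(bad))
    stop("binarization cut given for non-binomial character(s): ",
         paste(x$character_id[bad], collapse = ", "))
  class(x) <- c("character_specs", "data.frame")
  x
}

#' @rdname character_specs
#' @export
default_character_specs <- function() {
  path <- system.file("extdata", "character_specs.csv",
                      package = "clonodiverge", mustWork = TRUE)
  read_character_specs(path)
}

#' @rdname character_specs
#' @param path Path to a CSV file with the columns listed above.
#' @export
read_character_specs <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(character_id = "character"))
  character_specs(x)
}

#' @rdname character_specs
#' @param specs A `character_specs` table.
#' @export
write_character_specs <- function(specs, path) {
  write.csv(as.data.frame(specs), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

spec_for <- function(specs, character_id) {
  i <- match(character_id, specs$character_id)
  if (is.na(i)) stop("unknown character: ", character_id)
  specs[i, , drop = FALSE]
}
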