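#' Run the full divergence-analysis pipeline
#'
#' End-to-end orchestration: per-character divergence tests → heritability of
#' the significant characters → binary character coding → exact parsimony
#' with strict consensus (optionally rooted between two named clades) → UPGMA
#' with multiscale-bootstrap AU support. Writes `tests.csv`, `h2.csv`,
#' `matrix.nex`, `matrix.csv`, `consensus.nwk`, `all-trees.nwk`,
#' `dendrogram.nwk`, `support.csv` and `manifest.json` into `out_dir` and
#' returns the result bundle invisibly. The pipeline is a pure function of
#' (inputs, config, seed): rerunning with the same inputs reproduces
#' identical file digests.
#'
#' @param table An [observation_table()] (or a CSV path readable by
#'   [read_observations()]).
#' @param specs A [character_specs()] table (or CSV path).
#' @param out_dir Output directory (created if needed).
#' @param clade_a,clade_b Optional taxon sets for rooting the consensus
#'   (e.g. clades known from prior molecular work); config data, not code.
#' @param alpha Character-selection significance gate.
#' @param n_boot,scales Multiscale-bootstrap settings.
#' @param seed Mandatory seed for the bootstrap.
#' @param h2_threshold "High heritability" threshold for the summary.
#' @return (Invisibly) list with `tests`, `h2`, `matrix`, `tree_set`,
#'   `consensus`, `consensus_rooted`, `dendrogram`, `manifest`.
#' @export
run_pipeline <- function(table, specs, out_dir, clade_a = NULL,
                         clade_b = NULL, alpha = 0.05, n_boot = 1000L,
                         scales = seq(0.5, 1.4, by = 0.1), seed,
                         h2_threshold = 0.78) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.character(specs)) specs <- read_character_specs(specs)
  if (is.character(table)) table <- read_observations(table, specs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    message(msg)
    warnings_log <<- c(warnings_log, msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] %.2fs", name, proc.time()[["elapsed"]] - t0))
    out
  }

  tests <- stage("test-characters", character_tests(table, specs,
                                                    alpha = alpha))
  write.csv(tests, file.path(out_dir, "tests.csv"), row.names = FALSE)

  h2 <- stage("heritability",
              heritability_table(table, specs, tests, alpha = alpha,
                                 h2_threshold = h2_threshold))
  write.csv(as.data.frame(h2), file.path(out_dir, "h2.csv"),
            row.names = FALSE)

  profiles <- stage("profiles", strain_profiles(table, specs))
  write.csv(profiles, file.path(out_dir, "profiles.csv"), row.names = FALSE)

  bm <- stage("code-matrix", build_matrix(profiles, tests, alpha = alpha))
  if (length(bm$uninformative))
    note("uninformative coded column(s): ",
         paste(bm$uninformative, collapse = ", "))
  write_nexus_matrix(bm, file.path(out_dir, "matrix.nex"))
  write_matrix_csv(bm, file.path(out_dir, "matrix.csv"))

  ts <- stage("parsimony", branch_and_bound(bm))
  cons <- strict_consensus(ts)
  ape::write.tree(ts$trees, file.path(out_dir, "all-trees.nwk"))
  cons_rooted <- NULL
  if (!is.null(clade_a) && !is.null(clade_b)) {
    cons_rooted <- tryCatch(root_between(cons, clade_a, clade_b),
                            error = function(e) {
                              note("rooting skipped: ", conditionMessage(e))
                              NULL
                            })
  }
  write_tree(if (is.null(cons_rooted)) cons else cons_rooted,
             file.path(out_dir, "consensus.nwk"))

  x <- stage("scale-means",
             suppressWarnings(scaled_mean_matrix(profiles, tests,
                                                 alpha = alpha)))
  dend <- stage("upgma-au",
                multiscale_bootstrap(x, n_boot = n_boot, scales = scales,
                                     seed = seed))
  write_tree(dend$tree, file.path(out_dir, "dendrogram.nwk"))
  write.csv(dend$support, file.path(out_dir, "support.csv"),
            row.names = FALSE)

  manifest <- pipeline_manifest(out_dir, seed = seed, alpha = alpha,
                                n_boot = n_boot, scales = scales,
                                warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(tests = tests, h2 = h2, profiles = profiles, matrix = bm,
                 tree_set = ts, consensus = cons,
                 consensus_rooted = cons_rooted, dendrogram = dend,
                 manifest = manifest))
}

pipeline_manifest <- function(out_dir, seed, alpha, n_boot, scales,
                              warnings) {
  files <- c("tests.csv", "h2.csv", "profiles.csv", "matrix.nex",
             "matrix.csv", "all-trees.nwk", "consensus.nwk",
             "dendrogram.nwk", "support.csv")
  paths <- file.path(out_dir, files)
  present <- file.exists(paths)
  digests <- rep(NA_character_, length(files))
  digests[present] <- unname(tools::md5sum(paths[present]))
  list(package = "clonodiverge",
       version = as.character(utils::packageVersion("clonodiverge")),
       seed = seed,
       config = list(alpha = alpha, n_boot = n_boot, scales = scales),
       files = setNames(as.list(digests), files),
       warnings = warnings)
}
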