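#' Scaled strain-mean matrix for distance analysis
#'
#' Strains × characters matrix of estimated strain means for the
#' significantly varying characters, each column centred to mean 0 and
#' scaled to unit standard deviation over strains. Constant columns carry no
#' distance information and are dropped with a warning.
#'
#' @inheritParams build_matrix
#' @return Numeric matrix (strains × characters), centred and standardized.
#' @export
scaled_mean_matrix <- function(profiles, tests, alpha = 0.05) {
  bm <- build_matrix(profiles, tests, alpha = alpha)
  x <- bm$scaled
  const <- colnames(x)[apply(bm$source_means, 2, sd) == 0]
  if (length(const)) {
    warning("dropping constant character column(s): ",
            paste(const, collapse = ", "))
    x <- x[, setdiff(colnames(x), const), drop = FALSE]
  }
  x
}

standardize_columns <- function(x) {
  ctr <- sweep(x, 2, colMeans(x))
  sds <- apply(x, 2, sd)
  sweep(ctr, 2, ifelse(sds > 0, sds, 1), "/")
}

#' Pairwise Euclidean distances between strains
#'
#' @param x Numeric matrix with strains as rows.
#' @return A symmetric `matrix` of Euclidean distances with zero diagonal.
#' @export
euclidean_distances <- function(x) {
  d <- as.matrix(stats::dist(x, method = "euclidean"))
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

# UPGMA merge engine shared by upgma() and the bootstrap (compiled; taxa are
# presented in sorted-label order so tie-breaks follow label order). Returns
# the hclust-style merge sequence, merge heights (= average distance / 2)
# and member label sets.
upgma_core <- function(d) {
  d <- as.matrix(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(d)))
  ord <- order(labels)
  d <- d[ord, ord, drop = FALSE]
  labels <- labels[ord]
  n <- nrow(d)
  if (n < 2) stop("UPGMA needs at least 2 taxa")
  res <- .upgma_cpp(unname(d))
  members <- merge_members(res$merge, labels)
  list(merge = res$merge, height = res$height, members = members,
       mask = res$mask, labels = labels)
}

merge_members <- function(merge, labels) {
  k <- nrow(merge)
  members <- vector("list", k)
  for (i in seq_len(k)) {
    get <- function(code) if (code < 0) labels[-code] else members[[code]]
    members[[i]] <- sort(c(get(merge[i, 1]), get(merge[i, 2])))
  }
  members
}

#' UPGMA dendrogram
#'
#' Average-linkage (unweighted pair-group) hierarchical clustering: the
#' closest pair of clusters is merged and distances to the merged cluster
#' are the size-weighted average of the members' distances. Merge height is
#' half the merge distance, so the tree is ultrametric and branch lengths
#' are height differences; on ultrametric input the cophenetic distances
#' reproduce the input exactly. Ties are broken deterministically in favour
#' of the lexicographically smallest pair of cluster labels.
#'
#' @param d A symmetric distance matrix (or `dist`) with taxon labels.
#' @return An ultrametric `phylo` with branch lengths; node heights are
#'   attached as attribute `heights` (one per internal node, root last).
#' @export
upgma <- function(d) {
  core <- upgma_core(d)
  n <- length(core$labels)
  if (n == 2) {
    tr <- ape::read.tree(text = paste0("(", core$labels[1], ":",
                                       core$height[1], ",", core$labels[2],
                                       ":", core$height[1], ");"))
    attr(tr, "heights") <- core$height
    return(tr)
  }
  # merge i -> phylo node id: root (last merge) must be n + 1
  node_id <- function(i) n + (n - i)
  edge <- matrix(0L, 2 * (n - 1), 2)
  elen <- numeric(2 * (n - 1))
  r <- 0L
  for (i in seq_len(n - 1)) {
    for (ch in core$merge[i, ]) {
      r <- r + 1L
      if (ch < 0) {
        edge[r, ] <- c(node_id(i), -ch)
        elen[r] <- core$height[i]
      } else {
        edge[r, ] <- c(node_id(i), node_id(ch))
        elen[r] <- core$height[i] - core$height[ch]
      }
    }
  }
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = core$labels, Nnode = n - 1L),
                  class = "phylo")
  tr <- ape::reorder.phylo(tr, "cladewise")
  attr(tr, "heights") <- core$height
  tr
}

dendro_cluster_keys <- function(members) {
  vapply(members, paste, "", collapse = "|")
}

#' Multiscale bootstrap support for UPGMA clusters
#'
#' Assesses how strongly the data support each cluster of the UPGMA
#' dendrogram by resampling characters (columns) with replacement at a range
#' of sample sizes. For each scale r the bootstrap probability BP_r of a
#' cluster is the fraction of `n_boot` resamples of round(r·m) columns whose
#' UPGMA dendrogram contains that cluster. The signed distance v and
#' curvature c are estimated by weighted least squares from the model
#' ψ_r = Φ⁻¹(1 − BP_r) = v√r + c/√r (binomial sampling weights), and the
#' approximately unbiased p-value is AU = 1 − Φ(v − c). Clusters recovered
#' in every resample get AU = 1, clusters never recovered get AU = 0.
#'
#' @param x Strains × characters numeric matrix (typically
#'   [scaled_mean_matrix()] output).
#' @param n_boot Resamples per scale.
#' @param scales Relative resample sizes r.
#' @param seed Mandatory RNG seed; with a fixed seed the result is
#'   bit-reproducible.
#' @param restandardize Re-standardize columns within each resample
#'   (consistent with clustering a scaled matrix).
#' @return A `supported_dendrogram`: list with `tree` (the observed UPGMA
#'   `phylo`), `support` (data frame: `cluster`, `members`, `bp`, `au`, `v`,
#'   `c`, `n_scales`), `bp_table` (clusters × scales BP matrix), `scales`,
#'   `n_boot`, `seed`.
#' @export
multiscale_bootstrap <- function(x, n_boot = 1000L,
                                 scales = seq(0.5, 1.4, by = 0.1),
                                 seed, restandardize = TRUE) {
  if (missing(seed)) stop("seed is mandatory")
  if (nrow(x) < 3) stop("need at least 3 strains")
  set.seed(seed)
  m <- ncol(x)
  ord <- order(rownames(x))
  x <- x[ord, , drop = FALSE]                  # taxa in sorted-label order
  xs <- if (restandardize) standardize_columns(x) else x
  obs_core <- upgma_core(euclidean_distances(xs))
  obs_tree <- upgma(euclidean_distances(xs))
  keys <- dendro_cluster_keys(obs_core$members)
  keep <- keys != keys[length(keys)]           # drop the all-taxa cluster
  keys <- keys[keep]
  obs_masks <- obs_core$mask[keep]

  res <- .boot_counts_cpp(x, scales, as.integer(n_boot), obs_masks,
                          restandardize)
  counts <- res$counts
  dimnames(counts) <- list(keys, as.character(scales))
  used <- res$usable > 0L
  if (any(!used))
    warning("all resamples degenerate at scale(s) ",
            paste(scales[!used], collapse = ", "), "; dropped from the fit")
  counts[, !used] <- NA_integer_
  denom <- ifelse(res$usable > 0L, res$usable, NA_integer_)
  bp <- sweep(counts, 2, denom, "/")
  fit <- au_from_bp(bp[, used, drop = FALSE], scales[used], n_boot)
  scale1 <- which.min(abs(scales - 1))
  support <- data.frame(cluster = keys,
                        members = keys,
                        bp = bp[, scale1],
                        au = fit$au, v = fit$v, c = fit$c,
                        n_scales = fit$n_scales,
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(tree = obs_tree, support = support, bp_table = bp,
                 scales = scales, n_boot = n_boot, seed = seed),
            class = "supported_dendrogram")
}

#' Fit the multiscale-bootstrap AU model to per-scale bootstrap probabilities
#'
#' Weighted least-squares fit of ψ_r = Φ⁻¹(1 − BP_r) = v√r + c/√r per
#' cluster, with binomial delta-method weights n_boot·φ(ψ_r)²/(BP_r(1−BP_r)).
#' Scales with BP exactly 0 or 1 carry no information about ψ and are
#' excluded from the fit; clusters observed in every usable resample get
#' AU = 1 and clusters never observed get AU = 0. Clusters with fewer than
#' two informative scales get `au = NA` (flagged by `n_scales`).
#'
#' @param bp Clusters × scales matrix of bootstrap probabilities.
#' @param scales Scale values r (matching the columns of `bp`).
#' @param n_boot Resamples per scale (for the weights).
#' @return List of vectors `au`, `v`, `c`, `n_scales` (one entry per row of
#'   `bp`).
#' @export
au_from_bp <- function(bp, scales, n_boot) {
  bp <- as.matrix(bp)
  k <- nrow(bp)
  au <- v <- cc <- rep(NA_real_, k)
  n_scales <- integer(k)
  for (i in seq_len(k)) {
    p <- bp[i, ]
    usable <- !is.na(p)
    info <- usable & p > 0 & p < 1
    n_scales[i] <- sum(info)
    if (all(p[usable] == 1)) { au[i] <- 1; next }
    if (all(p[usable] == 0)) { au[i] <- 0; next }
    if (sum(info) < 2) next                    # AU undefined, flagged
    r <- scales[info]
    psi <- qnorm(1 - p[info])
    wgt <- n_boot * dnorm(psi)^2 / (p[info] * (1 - p[info]))
    X <- cbind(sqrt(r), 1 / sqrt(r))
    XtW <- t(X * wgt)
    beta <- solve(XtW %*% X, XtW %*% psi)
    v[i] <- beta[1]
    cc[i] <- beta[2]
    au[i] <- 1 - pnorm(beta[1] - beta[2])
  }
  list(au = au, v = v, c = cc, n_scales = n_scales)
}

#' @export
print.supported_dendrogram <- function(x, ...) {
  cat("UPGMA dendrogram of", length(x$tree$tip.label), "strains;",
      nrow(x$support), "internal clusters\n")
  print(x$support[c("cluster", "bp", "au")], row.names = FALSE)
  invisible(x)
}
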