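#' Fitch parsimony score of a tree
#'
#' Minimum number of state changes needed by each character on the tree,
#' summed over characters, computed by the two-pass set-intersection
#' algorithm on an arbitrary rooting (the score does not depend on the
#' rooting). Characters are unordered, equally weighted and reversible;
#' `NA` states are treated as uncertain (either state).
#'
#' @param tree A `phylo` whose tip labels equal the matrix taxa.
#' @param matrix A [build_matrix()] result, or a 0/1 matrix with taxa as row
#'   names.
#' @return Integer parsimony length.
#' @export
fitch_score <- function(tree, matrix) {
  states <- if (inherits(matrix, "binary_taxon_matrix")) matrix$states
            else as.matrix(matrix)
  if (!setequal(tree$tip.label, rownames(states)))
    stop("tree tips and matrix taxa differ")
  states <- states[tree$tip.label, , drop = FALSE]
  m <- ncol(states)
  n <- length(tree$tip.label)
  # state sets coded 1 = {0}, 2 = {1}, 3 = {0,1}
  code <- matrix(3L, n + tree$Nnode, m)
  code[seq_len(n), ] <- ifelse(is.na(states), 3L, states + 1L)
  tree <- ape::reorder.phylo(tree, "postorder")
  first <- rep(TRUE, n + tree$Nnode)
  score <- 0L
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]
    ch <- tree$edge[k, 2]
    if (first[par]) {
      code[par, ] <- code[ch, ]
      first[par] <- FALSE
    } else {
      inter <- bitwAnd(code[par, ], code[ch, ])
      empty <- inter == 0L
      score <- score + sum(empty)
      inter[empty] <- bitwOr(code[par, empty], code[ch, empty])
      code[par, ] <- inter
    }
  }
  score
}

#' All most-parsimonious trees by exact branch and bound
#'
#' Stepwise taxon addition (in sorted-label order, so the search is
#' deterministic) with lower-bound pruning: a partial tree is abandoned when
#' its Fitch length plus one change for every state still absent from the
#' placed taxa exceeds the best complete length, initialized from a greedy
#' addition tree. The search provably visits every most-parsimonious
#' topology, so the returned set is identical to exhaustive enumeration.
#' Uninformative (constant or singleton-state) columns are retained in the
#' score but counted and reported.
#'
#' @param matrix A [build_matrix()] result or 0/1 matrix with taxa row names
#'   (3--64 taxa; intended for small matrices where exactness matters).
#' @param max_trees Cap on the number of stored topologies; the score, the
#'   total count and the strict-consensus splits are exact even when the cap
#'   is hit (`overflow = TRUE`).
#' @return A `tree_set`: list with `trees` (a `multiPhylo` of unrooted
#'   most-parsimonious trees), `score`, `count`, `consensus_splits`
#'   (canonical split keys shared by all most-parsimonious trees),
#'   `overflow`, `n_informative`.
#' @export
branch_and_bound <- function(matrix, max_trees = 500L) {
  states <- if (inherits(matrix, "binary_taxon_matrix")) matrix$states
            else as.matrix(matrix)
  taxa <- sort(rownames(states))
  if (length(taxa) < 3) stop("branch and bound requires at least 3 taxa")
  states <- states[taxa, , drop = FALSE]
  informative <- apply(states, 2, function(s) {
    tb <- table(factor(s, levels = c(0, 1)))
    sum(tb >= 2) == 2L
  })
  res <- .bab_cpp(unname(states), as.integer(max_trees))
  trees <- lapply(res$edges, edges_to_phylo, taxa = taxa)
  class(trees) <- "multiPhylo"
  splits <- vapply(res$consensus_splits,
                   function(i) canonical_split(taxa[i], taxa), "")
  structure(list(trees = trees, score = as.integer(res$score),
                 count = res$count, consensus_splits = unique(splits),
                 overflow = res$overflow,
                 n_informative = sum(informative)),
            class = "tree_set")
}

# undirected edge matrix (tips 1..n, internals n+1..) -> unrooted phylo
edges_to_phylo <- function(edges, taxa) {
  n <- length(taxa)
  nn <- max(edges)
  adj <- vector("list", nn)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  nwk <- function(v, from) {
    if (v <= n) return(taxa[v])
    kids <- setdiff(adj[[v]], from)
    paste0("(", paste(vapply(kids, nwk, "", from = v), collapse = ","), ")")
  }
  ape::read.tree(text = paste0(nwk(n + 1L, 0L), ";"))
}

#' @export
print.tree_set <- function(x, ...) {
  cat("Tree set: ", x$count, " most-parsimonious tree(s), length ",
      x$score, if (x$overflow) " [stored set truncated]", "\n", sep = "")
  invisible(x)
}

#' Strict consensus tree
#'
#' The unrooted tree containing exactly the nontrivial splits present in
#' every input tree, multifurcating where the trees disagree. For a
#' [branch_and_bound()] `tree_set` the split intersection recorded during the
#' search is used, so the consensus is exact even when the stored tree list
#' was truncated.
#'
#' @param trees A `tree_set`, a `multiPhylo`, or a list of `phylo` objects
#'   sharing one leaf set.
#' @return A `phylo` (unrooted, possibly multifurcating).
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "tree_set")) {
    taxa <- trees$trees[[1]]$tip.label
    return(tree_from_splits(trees$consensus_splits, taxa))
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) stop("empty tree set")
  taxa <- trees[[1]]$tip.label
  for (t in trees) if (!setequal(t$tip.label, taxa))
    stop("trees must share one leaf set")
  splits <- Reduce(intersect, lapply(trees, tree_splits))
  tree_from_splits(splits, taxa)
}

#' Root a tree between two named clades
#'
#' Roots an unrooted tree on the edge separating `clade_a` from `clade_b`
#' (e.g. two clades known from prior molecular work). Taxa outside both
#' clades are assigned to whichever root side they attach to in the unrooted
#' tree; when several edges separate the clades, the one placing the fewest
#' taxa on the `clade_a` side is chosen (deterministically). Re-rooting never
#' changes the unrooted split set.
#'
#' @param tree An unrooted `phylo`.
#' @param clade_a,clade_b Character vectors of tip labels (disjoint; their
#'   union need not cover all tips).
#' @return A rooted `phylo` in which both clades are monophyletic-compatible
#'   with the root split.
#' @export
root_between <- function(tree, clade_a, clade_b) {
  taxa <- tree$tip.label
  if (length(intersect(clade_a, clade_b)))
    stop("clades overlap")
  missing <- setdiff(c(clade_a, clade_b), taxa)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  n <- length(taxa)
  sets <- node_tip_sets(tree)
  # every edge bipartition: clade below each non-root node vs the rest
  cands <- list()
  for (v in seq_len(n + tree$Nnode)) {
    if (v == n + 1L) next
    side <- sets[[v]]
    if (length(side) == 0L || length(side) == n) next
    other <- setdiff(taxa, side)
    if (all(clade_a %in% side) && all(clade_b %in% other))
      cands <- c(cands, list(side))
    else if (all(clade_b %in% side) && all(clade_a %in% other))
      cands <- c(cands, list(other))
  }
  if (!length(cands))
    stop("no edge separates the two clades; candidate edges: none ",
         "(clades are incompatible with the tree)")
  keys <- vapply(cands, function(s) paste(sort(s), collapse = "|"), "")
  cands <- cands[!duplicated(keys)]
  sizes <- lengths(cands)
  pick <- cands[[order(sizes, vapply(cands, function(s)
    paste(sort(s), collapse = "|"), ""))[1]]]
  # rebuild the rooted tree from the split set: the root edge is pick|rest,
  # and every other split contributes the side nested within one root side
  comp <- setdiff(taxa, pick)
  clusters <- list(sort(pick), sort(comp))
  for (key in tree_splits(tree)) {
    side <- strsplit(key, "|", fixed = TRUE)[[1]]
    other <- setdiff(taxa, side)
    if (all(side %in% pick) || all(side %in% comp))
      clusters <- c(clusters, list(sort(side)))
    else if (all(other %in% pick) || all(other %in% comp))
      clusters <- c(clusters, list(sort(other)))
  }
  clusters <- clusters[!duplicated(vapply(clusters, paste, "",
                                          collapse = "|"))]
  clusters <- clusters[order(-lengths(clusters))]
  nwk <- paste0(nest_clusters(sort(taxa), clusters), ";")
  ape::read.tree(text = nwk)
}
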