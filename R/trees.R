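# Tree plumbing: Newick I/O (via ape), split (bipartition) extraction and
# tree reconstruction from a compatible split set. Unrooted trees are
# compared by their nontrivial split sets, rooted trees by clade sets.

#' Read and write trees in Newick format
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] so that
#' every tree produced by the package round-trips with an identical split
#' set; UPGMA dendrogram heights are encoded as branch lengths (the
#' leaf-to-ancestor length equals the height difference).
#'
#' @param tree An object of class `phylo`.
#' @param path File path.
#' @return `read_tree()` returns a `phylo`; `write_tree()` returns `path`
#'   invisibly.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  ape::read.tree(path)
}

# tip label sets below every internal node (arbitrary rooting)
node_tip_sets <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(n)) sets[[i]] <- tree$tip.label[i]
  for (k in seq_len(nrow(tree$edge))) {
    par <- tree$edge[k, 1]
    ch <- tree$edge[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[ch]])
  }
  sets
}

canonical_split <- function(side, taxa) {
  ref <- sort(taxa)[1]
  side <- sort(side)
  if (ref %in% side) side <- sort(setdiff(taxa, side))
  paste(side, collapse = "|")
}

#' Nontrivial splits of an unrooted tree
#'
#' Returns the set of nontrivial bipartitions of the leaf set, each
#' canonicalized as the sorted side not containing the alphabetically first
#' taxon, serialized as a `|`-joined key. Rooting does not change the result.
#'
#' @param tree A `phylo`.
#' @return Character vector of split keys.
#' @export
tree_splits <- function(tree) {
  taxa <- tree$tip.label
  n <- length(taxa)
  sets <- node_tip_sets(tree)
  root <- n + 1L
  out <- character(0)
  for (v in seq(n + 1L, n + tree$Nnode)) {
    if (v == root) next
    side <- sets[[v]]
    if (length(side) < 2L || length(side) > n - 2L) next
    out <- c(out, canonical_split(side, taxa))
  }
  unique(out)
}

#' Rooted clade sets of a tree
#'
#' @param tree A rooted `phylo`.
#' @return Character vector of clade keys (sorted tip labels, `|`-joined).
#' @export
tree_clades <- function(tree) {
  n <- length(tree$tip.label)
  sets <- node_tip_sets(tree)
  keys <- vapply(seq(n + 1L, n + tree$Nnode),
                 function(v) paste(sort(sets[[v]]), collapse = "|"), "")
  unique(keys)
}

# Recursively nest a laminar cluster family into a Newick string.
nest_clusters <- function(members, clusters) {
  parts <- list()
  used <- character(0)
  for (cl in clusters) {
    if (length(cl) == length(members)) next
    if (!all(cl %in% members) || any(cl %in% used)) next
    inner <- Filter(function(x) length(x) < length(cl) && all(x %in% cl),
                    clusters)
    parts <- c(parts, nest_clusters(cl, inner))
    used <- c(used, cl)
  }
  singles <- setdiff(members, used)
  kids <- c(parts, as.list(singles))
  if (length(kids) == 1L) return(kids[[1L]])
  paste0("(", paste(unlist(kids), collapse = ","), ")")
}

# Build the (possibly multifurcating) unrooted tree displaying exactly the
# given compatible splits. Splits are canonical keys as from tree_splits().
tree_from_splits <- function(splits, taxa) {
  taxa <- sort(taxa)
  clusters <- lapply(splits, function(s) strsplit(s, "|", fixed = TRUE)[[1]])
  if (length(clusters) > 1L)
    clusters <- clusters[order(-lengths(clusters))]
  nwk <- paste0(nest_clusters(taxa, clusters), ";")
  ape::read.tree(text = nwk)
}

# do two trees display the same unrooted topology?
same_topology <- function(a, b) {
  setequal(a$tip.label, b$tip.label) &&
    setequal(tree_splits(a), tree_splits(b))
}
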