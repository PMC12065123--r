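# Shared tree helpers: canonical forms for unrooted-topology equality,
# bipartition extraction, and adjacency structures used by search moves.

#' Canonicalize an unrooted tree topology
#'
#' Drops edge lengths and internal labels, unroots, and collapses degree-2
#' nodes, so that topologically identical trees compare equal via
#' [canonical_key()].
#'
#' @param tr a `phylo`.
#' @return an unrooted `phylo`.
#' @export
canonical_tree <- function(tr) {
  tr$edge.length <- NULL
  tr$node.label <- NULL
  tr <- ape::collapse.singles(tr)
  if (ape::is.rooted(tr)) tr <- ape::unroot(tr)
  tr
}

#' Canonical string key of an unrooted topology
#'
#' Two trees get the same key iff they are isomorphic as unrooted
#' (leaf-labelled) topologies; used for tree deduplication.
#'
#' @param tr a `phylo`.
#' @return character scalar.
#' @export
canonical_key <- function(tr) {
  tr <- canonical_tree(tr)
  adj <- tree_adjacency(tr)
  anchor <- which(tr$tip.label == min(tr$tip.label))
  nb <- adj[[anchor]]
  key <- function(node, parent) {
    kids <- setdiff(adj[[node]], parent)
    if (!length(kids)) return(tr$tip.label[node])
    paste0("(", paste(sort(vapply(kids, key, "", parent = node)),
                      collapse = ","), ")")
  }
  paste0(tr$tip.label[anchor], "|", key(nb, anchor))
}

# adjacency list over node ids of a phylo (tips 1..n, internals n+1..)
tree_adjacency <- function(tr) {
  nn <- max(tr$edge)
  adj <- vector("list", nn)
  for (i in seq_len(nrow(tr$edge))) {
    a <- tr$edge[i, 1]; b <- tr$edge[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Non-trivial bipartitions of a tree
#'
#' Each internal edge splits the leaf set in two; the side not containing
#' the alphabetically smallest label is returned as a sorted,
#' `"|"`-joined label string. Works for multifurcating trees.
#'
#' @param tr a `phylo`.
#' @return character vector of split keys (possibly empty).
#' @export
tree_bipartitions <- function(tr) {
  tr <- canonical_tree(tr)
  n <- length(tr$tip.label)
  ref <- min(tr$tip.label)
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  out <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2L && length(side) <= n - 2L) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  sort(unique(out))
}

# deduplicate a list of trees under unrooted isomorphism; returns the list
# with a "keys" attribute
dedup_trees <- function(trees) {
  keys <- vapply(trees, canonical_key, "")
  keep <- !duplicated(keys)
  out <- trees[keep]
  attr(out, "keys") <- keys[keep]
  out
}

# parse one newick string (tests/fixture convenience)
tree_from_newick <- function(txt) {
  canonical_tree(ape::read.tree(text = txt))
}
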