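# Independent oracles used across the suite: exhaustive enumeration of
# ancestral assignments, all unrooted topologies, and bipartition sets
# computed from first principles.

# minimum total cost over ALL internal-node state assignments, by brute
# force; leaf_sets: named list taxon -> allowed state indices (1-based
# into the cost matrix)
brute_min_cost <- function(tree, cost, leaf_sets) {
  tr <- ape::unroot(ape::collapse.singles(tree))
  rt <- ape::reorder.phylo(
    ape::root(tr, outgroup = tr$tip.label[1], resolve.root = TRUE),
    "postorder")
  ntip <- length(rt$tip.label)
  internals <- sort(unique(rt$edge[, 1]))
  ns <- nrow(cost)
  # leaves with ambiguity: include them in the enumeration too
  amb <- which(vapply(rt$tip.label,
                      function(l) length(leaf_sets[[l]]) > 1L, TRUE))
  vars <- c(internals, amb)
  choices <- c(rep(list(seq_len(ns)), length(internals)),
               lapply(amb, function(i) leaf_sets[[rt$tip.label[i]]]))
  fixed <- integer(ntip)
  for (i in seq_len(ntip)) {
    if (!(i %in% amb)) fixed[i] <- leaf_sets[[rt$tip.label[i]]][1]
  }
  n_comb <- prod(vapply(choices, length, 1L))
  if (n_comb > 2e6) {
    stop("brute-force oracle asked to enumerate ", n_comb,
         " assignments; use a smaller state space in this test")
  }
  best <- Inf
  grid <- do.call(expand.grid, choices)
  for (r in seq_len(nrow(grid))) {
    assign_all <- integer(max(rt$edge))
    assign_all[seq_len(ntip)] <- fixed
    for (k in seq_along(vars)) assign_all[vars[k]] <- grid[r, k]
    tot <- 0
    for (e in seq_len(nrow(rt$edge))) {
      tot <- tot + cost[assign_all[rt$edge[e, 1]],
                        assign_all[rt$edge[e, 2]]]
    }
    best <- min(best, tot)
  }
  best
}

# brute-force Fitch: unit-cost unordered character given cell tokens
brute_fitch <- function(tree, cells, states) {
  ns <- length(states)
  cost <- 1 - diag(ns)
  leaf_sets <- lapply(cells, function(tok) {
    st <- if (tok %in% c("?", "-")) states else
      as.integer(strsplit(tok, "")[[1]])
    match(st, states)
  })
  brute_min_cost(tree, cost, leaf_sets)
}

all_topologies <- function(labels) {
  trs <- phangorn::allTrees(length(labels), rooted = FALSE,
                            tip.label = labels)
  lapply(trs, canonical_tree)
}

# bipartition set computed independently of the package helper: for each
# internal edge, the tip set below it (via ape::prop.part on a rooted
# copy), keyed against the side without the smallest label
oracle_bipartitions <- function(tr) {
  tr <- ape::unroot(tr)
  n <- length(tr$tip.label)
  pp <- ape::prop.part(tr)
  labs <- attr(pp, "labels")
  ref <- min(labs)
  out <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2 && length(side) <= n - 2) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  sort(unique(out))
}

# a quick random binary tree on given labels, seeded
rand_tree <- function(labels, seed) {
  set.seed(seed)
  canonical_tree(ape::rtree(length(labels), rooted = FALSE,
                            tip.label = sample(labels)))
}
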