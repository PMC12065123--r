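# Heuristic search for minimum-score trees: random-addition starts,
# NNI/SPR/TBR swapping, ratchet and drift perturbation, a hits-based
# multi-start driver, bootstrap resampling, strict consensus, and the
# deduplicated tree-collection closure protocol.

.EPS <- 1e-9

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Search configuration
#'
#' @param replicates number of random-addition starts.
#' @param hits_required stop early once the best score has been reached
#'   independently this many times.
#' @param ratchet_iterations ratchet iterations appended to each
#'   replicate (0 disables).
#' @param drift_iterations drift iterations appended to each replicate
#'   (0 disables).
#' @param swap_mode branch-swapping neighbourhood (`"NNI"`, `"SPR"`,
#'   `"TBR"`).
#' @param rng_seed integer seed controlling the whole search.
#' @param collapse_rule `"min-length-zero"` collapses branches whose
#'   minimum length over most-parsimonious reconstructions is zero
#'   before deduplication; `"none"` keeps trees binary.
#' @return object of class `search_config`.
#' @export
search_config <- function(replicates = 5L, hits_required = 2L,
                          ratchet_iterations = 0L, drift_iterations = 0L,
                          swap_mode = c("TBR", "SPR", "NNI"),
                          rng_seed = 1L,
                          collapse_rule = c("min-length-zero", "none")) {
  stopifnot(replicates >= 1L, hits_required >= 1L,
            ratchet_iterations >= 0L, drift_iterations >= 0L)
  structure(list(replicates = as.integer(replicates),
                 hits_required = as.integer(hits_required),
                 ratchet_iterations = as.integer(ratchet_iterations),
                 drift_iterations = as.integer(drift_iterations),
                 swap_mode = match.arg(swap_mode),
                 rng_seed = as.integer(rng_seed),
                 collapse_rule = match.arg(collapse_rule)),
            class = "search_config")
}

#' Random-addition-sequence starting tree
#'
#' Taxa are inserted in a seeded-random order, each at the edge where the
#' resulting tree scores best (ties resolved in deterministic edge
#' order); deterministic given the seed.
#'
#' @param m a [char_matrix()] (supplies the taxon set).
#' @param scorer a `tree_scorer` from [make_scorer()].
#' @param seed integer seed.
#' @return an unrooted binary `phylo`.
#' @export
random_addition_tree <- function(m, scorer, seed = 1L) {
  taxa <- m$taxa
  if (length(taxa) < 4L) stop("random addition needs at least 4 taxa")
  with_seed(seed, {
    ord <- sample(taxa)
    ut <- utree_new(ord[1:3])
    for (lab in ord[-(1:3)]) {
      cand <- lapply(utree_edges(ut), function(e) {
        ut_insert_tip(ut, e[1], e[2], lab)
      })
      sc <- vapply(cand, scorer$total, 1)
      ut <- cand[[which.min(sc)]]
    }
    utree_to_phylo(ut)
  })
}

#' Branch swapping to a local optimum
#'
#' Repeatedly moves to the best improving rearrangement in the chosen
#' neighbourhood; at convergence all equally-best neighbours at the
#' final score are retained alongside the optimum.
#'
#' @param tree starting tree.
#' @param scorer a `tree_scorer`.
#' @param mode neighbourhood: `"NNI"`, `"SPR"` or `"TBR"`.
#' @return list with `trees` (deduplicated list at the final score) and
#'   `score`.
#' @export
swap_to_local_optimum <- function(tree, scorer,
                                  mode = c("TBR", "SPR", "NNI")) {
  mode <- match.arg(mode)
  ut <- utree_from_phylo(canonical_tree(tree))
  cur <- scorer$total(ut)
  repeat {
    nb <- ut_neighbours(ut, mode)
    if (!length(nb)) {
      return(list(trees = list(utree_to_phylo(ut)), score = cur))
    }
    sc <- vapply(nb, scorer$total, 1)
    if (min(sc) < cur - .EPS) {
      ut <- nb[[which.min(sc)]]
      cur <- min(sc)
    } else {
      ties <- lapply(nb[sc <= cur + .EPS], utree_to_phylo)
      return(list(trees = dedup_trees(c(list(utree_to_phylo(ut)), ties)),
                  score = cur))
    }
  }
}

#' Parsimony ratchet
#'
#' Per iteration a seeded-random subset of characters (default 25%) is
#' temporarily upweighted (default factor 2), the tree is swapped under
#' the perturbed weights, weights are restored and the tree swapped
#' again; all distinct trees at the best score seen are returned.
#'
#' @param tree starting tree.
#' @param m,g,scheme,use_composites scoring context (see
#'   [make_scorer()]).
#' @param iterations ratchet iterations (0 returns the input unchanged).
#' @param seed integer seed.
#' @param frac fraction of characters reweighted.
#' @param factor temporary weight multiplier.
#' @param mode swap neighbourhood.
#' @return list with `trees` and `score`.
#' @export
ratchet <- function(tree, m, g = NULL, scheme = weighting_scheme("EW"),
                    use_composites = FALSE, iterations = 10L, seed = 1L,
                    frac = 0.25, factor = 2, mode = "TBR") {
  scorer <- make_scorer(m, g, scheme, use_composites)
  if (iterations == 0L) {
    return(list(trees = list(canonical_tree(tree)),
                score = scorer$total(tree)))
  }
  cur <- swap_to_local_optimum(tree, scorer, mode)
  best <- cur$score
  pool <- cur$trees
  tree <- cur$trees[[1]]
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      sel <- sample(n_characters(m), max(1L, round(frac * n_characters(m))))
      m2 <- m
      m2$characters$weight[sel] <- m2$characters$weight[sel] * factor
      pscorer <- make_scorer(m2, g, scheme, use_composites)
      ptree <- swap_to_local_optimum(tree, pscorer, mode)$trees[[1]]
      res <- swap_to_local_optimum(ptree, scorer, mode)
      if (res$score < best - .EPS) {
        best <- res$score
        pool <- res$trees
        tree <- res$trees[[1]]
      } else if (res$score <= best + .EPS) {
        pool <- dedup_trees(c(pool, res$trees))
        tree <- res$trees[[1]]
      }
    }
  })
  list(trees = dedup_trees(pool), score = best)
}

#' Drift perturbation
#'
#' A bounded random walk that may accept slightly worse rearrangements
#' (relative tolerance `tol`), followed by a final swap to a local
#' optimum; a simplified seeded analogue of TNT's drift.
#'
#' @inheritParams swap_to_local_optimum
#' @param iterations number of random SPR moves attempted.
#' @param seed integer seed.
#' @param tol relative score tolerance for accepting a worse tree.
#' @param mode final swap neighbourhood.
#' @return list with `trees` and `score`.
#' @export
drift_perturb <- function(tree, scorer, iterations = 10L, seed = 1L,
                          tol = 0.02, mode = "TBR") {
  ut <- utree_from_phylo(canonical_tree(tree))
  cur <- scorer$total(ut)
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      nb <- ut_neighbours(ut, "SPR")
      cand <- nb[[sample.int(length(nb), 1L)]]
      sc <- scorer$total(cand)
      if (sc <= cur * (1 + tol) + .EPS) {
        ut <- cand
        cur <- sc
      }
    }
  })
  swap_to_local_optimum(utree_to_phylo(ut), scorer, mode)
}

#' Multi-start heuristic tree search
#'
#' Runs seeded random-addition replicates, each followed by branch
#' swapping and optional ratchet/drift rounds, stopping early once the
#' best score has been hit independently `hits_required` times. All
#' distinct best trees are returned after applying the configured
#' collapse rule.
#'
#' @param m a [char_matrix()].
#' @param g optional `dep_graph`.
#' @param scheme a [weighting_scheme()].
#' @param config a [search_config()].
#' @param use_composites score dependency complexes as composites.
#' @param scorer optional prebuilt `tree_scorer` (built from the other
#'   arguments when `NULL`); note the ratchet always rebuilds scorers
#'   from `m` and is skipped when a custom scorer is supplied.
#' @return list with `trees` (most parsimonious trees, deduplicated),
#'   `score`, and `hits`.
#' @export
multistart_search <- function(m, g = NULL, scheme = weighting_scheme("EW"),
                              config = search_config(),
                              use_composites = FALSE, scorer = NULL) {
  custom_scorer <- !is.null(scorer)
  if (!custom_scorer) scorer <- make_scorer(m, g, scheme, use_composites)
  best <- Inf
  pool <- list()
  hits <- 0L
  for (rep_i in seq_len(config$replicates)) {
    rseed <- config$rng_seed + 1000L * rep_i
    start <- random_addition_tree(m, scorer, seed = rseed)
    res <- swap_to_local_optimum(start, scorer, config$swap_mode)
    if (config$ratchet_iterations > 0L && !custom_scorer) {
      res <- ratchet(res$trees[[1]], m, g, scheme, use_composites,
                     iterations = config$ratchet_iterations,
                     seed = rseed + 1L, mode = config$swap_mode)
    }
    if (config$drift_iterations > 0L) {
      dr <- drift_perturb(res$trees[[1]], scorer,
                          iterations = config$drift_iterations,
                          seed = rseed + 2L, mode = config$swap_mode)
      if (dr$score < res$score - .EPS) res <- dr
      else if (dr$score <= res$score + .EPS) {
        res$trees <- dedup_trees(c(res$trees, dr$trees))
      }
    }
    if (res$score < best - .EPS) {
      best <- res$score
      pool <- res$trees
      hits <- 1L
    } else if (res$score <= best + .EPS) {
      pool <- dedup_trees(c(pool, res$trees))
      hits <- hits + 1L
    }
    if (hits >= config$hits_required) break
  }
  trees <- if (config$collapse_rule == "min-length-zero") {
    dedup_by_collapse(pool, scorer)
  } else dedup_trees(pool)
  list(trees = trees, score = best, hits = hits)
}

# deduplicate binary trees under the identity of their zero-length-
# collapsed topologies; binary representatives are kept (so every stored
# tree rescores to the reported optimum), the collapsed form only
# decides which trees count as the same MPT
dedup_by_collapse <- function(trees, scorer) {
  keys <- vapply(trees, function(tr) {
    canonical_key(collapse_zero_length(tr, scorer))
  }, "")
  out <- trees[!duplicated(keys)]
  attr(out, "keys") <- keys[!duplicated(keys)]
  out
}

#' Collapse branches of minimum length zero
#'
#' An internal branch is collapsed when, for every scoring unit
#' (character or composite), some most-parsimonious reconstruction
#' assigns its two endpoints the same state — i.e. the branch's minimum
#' length over per-unit optimal reconstructions is zero.
#'
#' @param tree unrooted binary `phylo`.
#' @param scorer a `tree_scorer`.
#' @return a (possibly multifurcating) `phylo`.
#' @export
collapse_zero_length <- function(tree, scorer) {
  tree <- canonical_tree(tree)
  zero <- rep(TRUE, 0)
  keys <- character(0)
  for (unit in scorer$units) {
    z <- unit_zero_edges(tree, unit)
    if (!length(keys)) {
      keys <- names(z)
      zero <- z
    } else {
      zero <- zero & z[keys]
    }
  }
  drop <- names(zero)[zero]
  if (!length(drop)) return(tree)
  collapse_edges_by_key(tree, drop)
}

# per internal edge (named by bipartition key): can this unit be
# optimized with zero change across the edge?
unit_zero_edges <- function(tree, unit) {
  rt <- rooted_binary(tree)
  cost <- unit$cost
  ns <- nrow(cost)
  ntip <- length(rt$tip.label)
  nnode <- ntip + rt$Nnode
  edge <- rt$edge
  root <- edge[nrow(edge), 1]
  down <- matrix(Inf, nnode, ns)
  for (i in seq_len(ntip)) {
    down[i, unit$leaf_sets[[rt$tip.label[i]]]] <- 0
  }
  down[(ntip + 1L):nnode, ] <- 0
  contrib <- matrix(NA_real_, nrow(edge), ns)  # child->parent message
  for (e in seq_len(nrow(edge))) {
    contrib[e, ] <- sankoff_message(cost, down[edge[e, 2], ])
    down[edge[e, 1], ] <- down[edge[e, 1], ] + contrib[e, ]
  }
  total <- min(down[root, ])
  # up[v][s]: cost of the rest of the tree given v = s
  up <- matrix(Inf, nnode, ns)
  up[root, ] <- 0
  upx_list <- vector("list", nrow(edge))
  for (e in rev(seq_len(nrow(edge)))) {  # preorder
    p <- edge[e, 1]; v <- edge[e, 2]
    upx <- up[p, ] + down[p, ] - contrib[e, ]  # parent minus this child
    up[v, ] <- sankoff_message(cost, upx)  # cost[s_p, s_v]: symmetric
    upx_list[[e]] <- upx
  }
  clade <- clade_tips(rt)
  labs <- sort(rt$tip.label)
  out <- logical(0)
  for (e in seq_len(nrow(edge))) {
    v <- edge[e, 2]
    if (v <= ntip || edge[e, 1] == root) next  # terminal or root edge
    side <- sort(clade[[v]])
    if (length(side) > length(labs) - 2L) next
    key <- paste(side, collapse = "|")
    upx <- upx_list[[e]]
    out[key] <- any(abs(down[v, ] + upx - total) < .EPS)
  }
  out
}

clade_tips <- function(rt) {
  ntip <- length(rt$tip.label)
  nnode <- ntip + rt$Nnode
  out <- vector("list", nnode)
  for (i in seq_len(ntip)) out[[i]] <- rt$tip.label[i]
  for (e in seq_len(nrow(rt$edge))) {   # postorder
    p <- rt$edge[e, 1]; v <- rt$edge[e, 2]
    out[[p]] <- c(out[[p]], out[[v]])
  }
  out
}

# contract the internal edges whose child-side tip sets match `keys`
collapse_edges_by_key <- function(tree, keys) {
  ut <- utree_from_phylo(tree)
  repeat {
    done <- TRUE
    for (e in utree_edges(ut)) {
      if (!is.na(ut$labels[e[1]]) || !is.na(ut$labels[e[2]])) next
      for (dir in 1:2) {
        side <- ut_component(ut, e[3 - dir], avoid = e[dir])
        lab <- sort(ut$labels[side[!is.na(ut$labels[side])]])
        key <- paste(lab, collapse = "|")
        if (key %in% keys) {
          # contract: attach child's other neighbours to parent
          p <- e[dir]; v <- e[3 - dir]
          for (w in setdiff(ut$adj[[v]], p)) {
            ut <- ut_disconnect(ut, v, w)
            ut <- ut_connect(ut, p, w)
          }
          ut <- ut_disconnect(ut, p, v)
          done <- FALSE
          break
        }
      }
      if (!done) break
    }
    if (done) break
  }
  utree_to_phylo(ut)
}

#' Strict consensus of a set of trees
#'
#' Contains exactly the bipartitions present in every input tree.
#'
#' @param trees list of `phylo` with identical leaf sets.
#' @return a (possibly multifurcating) `phylo`.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("need at least one tree")
  sets <- lapply(trees, function(tr) sort(tr$tip.label))
  if (length(unique(sets)) != 1L) stop("trees have mismatched leaf sets")
  if (length(trees) == 1L) return(canonical_tree(trees[[1]]))
  cns <- ape::consensus(trees, p = 1, rooted = FALSE)
  canonical_tree(cns)
}

#' Create an empty tree collection
#'
#' A deduplicated store of most parsimonious trees with per-tree
#' provenance labels, used by the closure protocol: analyses are looped,
#' each adding its trees and TBR-derived equal-or-better neighbours,
#' until a full pass adds nothing.
#'
#' @return object of class `tree_collection`.
#' @export
tree_collection <- function() {
  structure(list(trees = list(), keys = character(0),
                 provenance = list(), checked = list()),
            class = "tree_collection")
}

#' @export
print.tree_collection <- function(x, ...) {
  cat("tree_collection:", length(x$trees), "distinct trees\n")
  invisible(x)
}

collection_insert <- function(col, trees, label) {
  added <- 0L
  for (tr in trees) {
    tr <- canonical_tree(tr)
    key <- canonical_key(tr)
    at <- match(key, col$keys)
    if (is.na(at)) {
      col$trees[[length(col$trees) + 1L]] <- tr
      col$keys <- c(col$keys, key)
      col$provenance[[length(col$provenance) + 1L]] <- label
      added <- added + 1L
    } else {
      col$provenance[[at]] <- unique(c(col$provenance[[at]], label))
    }
  }
  list(collection = col, added = added)
}

#' Add trees to a collection and cross-check by TBR
#'
#' Inserts the non-duplicate trees, then runs one TBR round seeded from
#' every collection member under the supplied scorer, adding any
#' distinct tree scoring at least as well as the collection's current
#' best. The caller loops analyses until a full pass adds zero trees
#' (closure; guaranteed to terminate on the finite topology space).
#'
#' @param col a [tree_collection()].
#' @param trees list of trees to insert.
#' @param scorer the current analysis's `tree_scorer`.
#' @param label provenance label recorded for inserted trees.
#' @param cross_check run the TBR round (set `FALSE` to only insert).
#' @return list with `collection` and `added` (count of new trees).
#' @export
update_tree_collection <- function(col, trees, scorer, label = "analysis",
                                   cross_check = TRUE) {
  ins <- collection_insert(col, trees, label)
  col <- ins$collection
  added <- ins$added
  if (cross_check && length(col$trees)) {
    best <- min(vapply(col$trees, scorer$total, 1))
    seen <- col$checked[[label]] %||% character(0)
    for (ti in seq_along(col$trees)) {
      key <- col$keys[ti]
      if (key %in% seen) next  # TBR neighbourhood is deterministic
      seen <- c(seen, key)
      nb <- ut_neighbours(utree_from_phylo(col$trees[[ti]]), "TBR")
      if (!length(nb)) next
      sc <- vapply(nb, scorer$total, 1)
      good <- lapply(nb[sc <= best + .EPS], utree_to_phylo)
      if (length(good)) {
        ins <- collection_insert(col, good, paste0(label, ":tbr"))
        col <- ins$collection
        added <- added + ins$added
        best <- min(best, min(sc))
      }
    }
    col$checked[[label]] <- seen
  }
  list(collection = col, added = added)
}

#' Bootstrap support by unit resampling
#'
#' Resamples scoring units (independent characters, and whole dependency
#' complexes when composites are in use) with replacement, re-searches
#' each pseudo-replicate with a reduced configuration, and records how
#' often each bipartition appears in the replicate's strict consensus.
#'
#' @param m a [char_matrix()].
#' @param g optional `dep_graph`.
#' @param scheme a [weighting_scheme()].
#' @param pseudo_replicates number of bootstrap replicates.
#' @param config reduced [search_config()] used per replicate.
#' @param seed integer seed.
#' @param use_composites score dependency complexes as composites.
#' @return named numeric vector: bipartition key (sorted labels joined
#'   by `|`) to support percentage.
#' @export
bootstrap_support <- function(m, g = NULL, scheme = weighting_scheme("EW"),
                              pseudo_replicates = 100L,
                              config = search_config(replicates = 1L,
                                                     hits_required = 1L,
                                                     swap_mode = "SPR"),
                              seed = 1L, use_composites = FALSE) {
  stopifnot(pseudo_replicates >= 1L)
  base <- make_scorer(m, g, scheme, use_composites)
  nunit <- length(base$units)
  counts <- numeric(0)
  for (b in seq_len(pseudo_replicates)) {
    mult <- with_seed(seed + b, {
      tabulate(sample.int(nunit, nunit, replace = TRUE), nbins = nunit)
    })
    wscorer <- base
    wscorer$total <- function(tree) sum(mult * base$contribs(tree))
    # units replicated per multiplicity, so zero-length collapse sees
    # the resampled character set
    wscorer$units <- base$units[rep(seq_along(base$units), mult)]
    cfg <- config
    cfg$rng_seed <- seed + 7919L * b
    res <- multistart_search(m, g, scheme, cfg, use_composites,
                             scorer = wscorer)
    cons_trees <- lapply(res$trees, collapse_zero_length,
                         scorer = wscorer)
    for (key in tree_bipartitions(strict_consensus(cons_trees))) {
      counts[key] <- (if (is.na(counts[key])) 0 else counts[key]) + 1
    }
  }
  sort(100 * counts / pseudo_replicates, decreasing = TRUE)
}
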