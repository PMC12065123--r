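# Normalized Robinson-Foulds distances within and between analysis
# batches, distance-matrix assembly, and congruence-based selection of
# most parsimonious trees for a combined strict consensus.

#' Normalized Robinson-Foulds distance between two trees
#'
#' The Robinson-Foulds distance counts the bipartitions present in
#' exactly one of the two trees; it is normalized by `2 * (n - 3)`, the
#' largest value attainable by two fully binary trees on `n` leaves, so
#' that 0 means isomorphic and 1 means no shared internal bipartition.
#'
#' @param t1,t2 `phylo` trees over the same leaf set (`n >= 4`).
#' @return numeric in `[0, 1]`.
#' @export
nrf_distance <- function(t1, t2) {
  t1 <- canonical_tree(t1)
  t2 <- canonical_tree(t2)
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees have mismatched leaf sets")
  }
  n <- length(t1$tip.label)
  if (n < 4L) stop("nRF needs at least 4 leaves")
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  rf / (2 * (n - 3))
}

#' Pairwise nRF distance matrix over labelled tree batches
#'
#' Concatenates the batches, deduplicates topologies (merging labels of
#' duplicates), and fills the symmetric matrix of pairwise
#' [nrf_distance()] values. The per-batch "internal distance" (largest
#' pairwise nRF within a batch) is attached as an attribute.
#'
#' @param tree_batches named list; each element a list of `phylo` trees
#'   from one analysis.
#' @param rounding decimal places used by the `print` method (display
#'   only; stored values keep full precision).
#' @return object of class `nrf_dist`: list with `labels`, `values`
#'   (square numeric matrix), `rounding`, and attribute
#'   `internal_distance` (named per batch).
#' @export
distance_matrix <- function(tree_batches, rounding = 2L) {
  if (is.null(names(tree_batches)) || any(!nzchar(names(tree_batches)))) {
    stop("tree_batches must be a named list")
  }
  trees <- list()
  labels <- character(0)
  keys <- character(0)
  for (b in names(tree_batches)) {
    batch <- tree_batches[[b]]
    for (i in seq_along(batch)) {
      tr <- canonical_tree(batch[[i]])
      key <- canonical_key(tr)
      at <- match(key, keys)
      if (is.na(at)) {
        trees[[length(trees) + 1L]] <- tr
        keys <- c(keys, key)
        labels <- c(labels, sprintf("%s#%d", b, i))
      } else {
        labels[at] <- paste(labels[at], sprintf("%s#%d", b, i), sep = "+")
      }
    }
  }
  k <- length(trees)
  vals <- matrix(0, k, k, dimnames = list(labels, labels))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      vals[i, j] <- vals[j, i] <- nrf_distance(trees[[i]], trees[[j]])
    }
  }
  internal <- vapply(names(tree_batches), function(b) {
    batch <- tree_batches[[b]]
    if (length(batch) < 2L) return(0)
    mx <- 0
    for (i in seq_len(length(batch) - 1L)) for (j in (i + 1L):length(batch)) {
      mx <- max(mx, nrf_distance(batch[[i]], batch[[j]]))
    }
    mx
  }, 1)
  structure(list(labels = labels, values = vals, trees = trees,
                 rounding = as.integer(rounding)),
            class = "nrf_dist", internal_distance = internal)
}

# display rounding: half away from zero (0.125 -> 0.13), as tree
# distances are conventionally reported
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.nrf_dist <- function(x, ...) {
  cat("nrf_dist:", length(x$labels), "distinct trees\n")
  print(round_half_up(x$values, x$rounding))
  invisible(x)
}

#' Select the most congruent trees across analyses
#'
#' Keeps every tree of the anchor batches plus, from each non-anchor
#' batch, the tree(s) attaining the smallest nRF distance to any anchor
#' tree (ties all kept), and builds their strict consensus — a way of
#' combining the strengths of several weighting/dependency treatments
#' without accepting every tree of each.
#'
#' @param batches named list of tree lists (one per analysis).
#' @param anchor_labels names of the reference batches.
#' @return list with `selected` (named list of trees), `consensus`
#'   (strict consensus `phylo`), and `distances` (per selected
#'   non-anchor tree, its distance to the nearest anchor).
#' @export
select_congruent_mpts <- function(batches, anchor_labels) {
  if (length(batches) < 2L) stop("need at least two batches")
  if (any(vapply(batches, length, 1L) == 0L)) stop("empty batch")
  if (!all(anchor_labels %in% names(batches))) {
    stop("anchor label(s) not among batches: ",
         paste(setdiff(anchor_labels, names(batches)), collapse = ", "))
  }
  anchors <- unlist(lapply(batches[anchor_labels], function(b) b),
                    recursive = FALSE)
  selected <- list()
  for (b in anchor_labels) {
    for (i in seq_along(batches[[b]])) {
      selected[[sprintf("%s#%d", b, i)]] <- batches[[b]][[i]]
    }
  }
  dists <- numeric(0)
  for (b in setdiff(names(batches), anchor_labels)) {
    dd <- vapply(batches[[b]], function(tr) {
      min(vapply(anchors, nrf_distance, 1, t1 = tr))
    }, 1)
    best <- min(dd)
    for (i in which(dd <= best + 1e-12)) {
      nm <- sprintf("%s#%d", b, i)
      selected[[nm]] <- batches[[b]][[i]]
      dists[nm] <- dd[i]
    }
  }
  sel_dedup <- dedup_trees(selected)
  list(selected = selected,
       consensus = strict_consensus(sel_dedup),
       distances = dists)
}
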