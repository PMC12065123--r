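# Flattening dependency complexes into composite characters: tuple-state
# enumeration and generated step (cost) matrices that never charge changes
# of inapplicable constituents.

#' Partition characters into dependency complexes
#'
#' Connected components of the dependency relation (links plus shared
#' serial-block membership). Characters with no dependency remain
#' singletons.
#'
#' @param g a `dep_graph`.
#' @param n_characters total number of characters in the matrix.
#' @return list of sorted 1-based index vectors, ordered by smallest
#'   member; singletons have length 1.
#' @export
find_complexes <- function(g, n_characters) {
  edges <- integer(0)
  for (l in g$links) edges <- c(edges, l$controller, l$dependent)
  for (b in g$serial_blocks) {
    if (length(b$members) > 1L) {
      for (i in seq_len(length(b$members) - 1L)) {
        edges <- c(edges, b$members[i], b$members[i + 1L])
      }
    }
  }
  ig <- igraph::make_graph(edges, n = n_characters, directed = FALSE)
  comp <- igraph::components(ig)
  out <- split(seq_len(n_characters), comp$membership)
  out <- lapply(out, function(v) sort(as.integer(v)))
  names(out) <- NULL
  out[order(vapply(out, min, 1L))]
}

# links/blocks fully inside a member set
links_within <- function(g, members) {
  Filter(function(l) l$controller %in% members && l$dependent %in% members,
         g$links)
}

blocks_within <- function(g, members) {
  Filter(function(b) all(b$members %in% members), g$serial_blocks)
}

#' Enumerate the dependency-consistent tuple states of a complex
#'
#' A tuple assigns each member either a state code or `NA`
#' (inapplicable); an entry is `NA` iff some full-character controller
#' entry within the complex is non-enabling (or itself `NA`).
#' Single-state dependencies remove their listed dependent states while
#' the controller disables them. Streak-constrained serial blocks are
#' restricted to tuples whose non-baseline (non-zero) applicable members
#' form one contiguous run.
#'
#' @param members complex member indices (from [find_complexes()]).
#' @param m the [char_matrix()].
#' @param g the `dep_graph`.
#' @param cap maximum admissible number of tuples (default 4096); larger
#'   state spaces raise an error advising a complex split.
#' @return integer matrix, one row per tuple (lexicographic order, `NA`
#'   sorting first), columns named by member index.
#' @export
enumerate_states <- function(members, m, g, cap = 4096L) {
  members <- sort(as.integer(members))
  links <- links_within(g, members)
  codes <- m$characters$states[members]
  # topological order of members under full-character links
  full <- Filter(function(l) is.null(l$dependent_states), links)
  ord <- topo_order(members, full)
  tuples <- matrix(integer(0), nrow = 1, ncol = 0)
  for (mem in ord) {
    pos_new <- match(mem, members)
    ctl <- Filter(function(l) l$dependent == mem, full)
    sgl <- Filter(function(l) l$dependent == mem &&
                    !is.null(l$dependent_states), links)
    grown <- list()
    for (r in seq_len(nrow(tuples))) {
      row <- tuples[r, , drop = TRUE]
      disabled <- any(vapply(ctl, function(l) {
        v <- row[[as.character(l$controller)]]
        is.na(v) || !(v %in% l$enabling)
      }, TRUE))
      vals <- if (length(ctl) && disabled) NA_integer_ else {
        allowed <- codes[[pos_new]]
        for (l in sgl) {
          v <- row[[as.character(l$controller)]]
          if (is.na(v) || !(v %in% l$enabling)) {
            allowed <- setdiff(allowed, l$dependent_states)
          }
        }
        allowed
      }
      for (v in vals) {
        nr <- c(row, stats::setNames(v, as.character(mem)))
        grown[[length(grown) + 1L]] <- nr
      }
    }
    if (length(grown) > cap) {
      stop("composite state space exceeds cap (", cap,
           "); consider splitting the complex {",
           paste(members, collapse = ","), "}")
    }
    tuples <- do.call(rbind, grown)
  }
  colnames(tuples) <- as.character(ord)
  tuples <- tuples[, as.character(members), drop = FALSE]
  # streak restriction
  for (b in blocks_within(g, members)) {
    cols <- match(as.character(b$members), colnames(tuples))
    if (b$streak) {
      keep <- apply(tuples, 1, function(row) {
        on <- which(!is.na(row[cols]) & row[cols] != 0L)
        !length(on) || all(diff(on) == 1L)
      })
      tuples <- tuples[keep, , drop = FALSE]
    }
  }
  key <- apply(tuples, 1, function(row) {
    paste(sprintf("%03d", ifelse(is.na(row), -1L, row) + 1L),
          collapse = ".")
  })
  tuples <- tuples[order(key), , drop = FALSE]
  rownames(tuples) <- NULL
  tuples
}

topo_order <- function(members, full_links) {
  if (!length(full_links)) return(members)
  remaining <- members
  placed <- integer(0)
  while (length(remaining)) {
    free <- Filter(function(mm) {
      !any(vapply(full_links, function(l) {
        l$dependent == mm && l$controller %in% remaining
      }, TRUE))
    }, remaining)
    if (!length(free)) stop("cycle among complex members")
    nxt <- min(unlist(free))
    placed <- c(placed, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  placed
}

#' Build the step (cost) matrix of a composite character
#'
#' The direct cost between two tuples charges, for every member that is
#' applicable in both, its weight if the states differ; members
#' inapplicable on either side are free (the controller's own change
#' carries the cost of gaining or losing the whole dependent complex, so
#' instantiating a dependent state at gain costs nothing extra). Members
#' of one serial block changing concurrently are discounted:
#' `m` simultaneous changes cost `w * (1 + (m - 1) * discount)` rather
#' than `m * w`. A metric closure (all-pairs shortest path) is applied so
#' indirect routes are never beaten by direct overcharges.
#'
#' @param states tuple matrix from [enumerate_states()].
#' @param weights per-member weights (recycled if length 1).
#' @param blocks list of [serial_block()] fully inside the complex.
#' @return symmetric, zero-diagonal numeric cost matrix satisfying the
#'   triangle inequality.
#' @export
build_cost_matrix <- function(states, weights = 1, blocks = list()) {
  nmem <- ncol(states)
  ns <- nrow(states)
  if (any(weights <= 0)) stop("member weights must be positive")
  weights <- rep_len(weights, nmem)
  in_block <- rep(0L, nmem)
  for (bi in seq_along(blocks)) {
    in_block[match(as.character(blocks[[bi]]$members),
                   colnames(states))] <- bi
  }
  cost <- matrix(0, ns, ns)
  for (u in seq_len(ns)) for (v in seq_len(u - 1L)) {
    su <- states[u, ]; sv <- states[v, ]
    both <- !is.na(su) & !is.na(sv)
    diffm <- both & su != sv
    cc <- sum(weights[diffm & in_block == 0L])
    for (bi in seq_along(blocks)) {
      mb <- sum(diffm & in_block == bi)
      if (mb > 0L) {
        w <- weights[which(in_block == bi)[1]]
        cc <- cc + w * (1 + (mb - 1) * blocks[[bi]]$discount)
      }
    }
    cost[u, v] <- cost[v, u] <- cc
  }
  metric_closure(cost)
}

# vectorized Floyd-Warshall
metric_closure <- function(cost) {
  n <- nrow(cost)
  for (k in seq_len(n)) {
    cost <- pmin(cost, outer(cost[, k], cost[k, ], `+`))
  }
  cost
}

#' Assemble a composite character for a dependency complex
#'
#' Bundles the enumerated tuple states, the generated cost matrix and the
#' per-taxon compatible-state sets; a degenerate complex of one character
#' reproduces plain Fitch costs (`w * (1 - delta)`).
#'
#' @param members complex member indices.
#' @param m the [char_matrix()].
#' @param g the `dep_graph`.
#' @param cap state-space cap passed to [enumerate_states()].
#' @return object of class `composite_char` with fields `members`,
#'   `states`, `cost`, `taxon_state_sets` (list of integer state-row
#'   indices per taxon), `weights`, `n_members`.
#' @export
build_composite <- function(members, m, g, cap = 4096L) {
  members <- sort(as.integer(members))
  states <- enumerate_states(members, m, g, cap = cap)
  blocks <- blocks_within(g, members)
  weights <- m$characters$weight[members]
  cost <- build_cost_matrix(states, weights, blocks)
  tss <- lapply(seq_along(m$taxa), function(i) {
    compat <- rep(TRUE, nrow(states))
    for (pos in seq_along(members)) {
      tok <- m$cells[i, members[pos]]
      if (tok == "?") next
      col <- states[, pos]
      compat <- compat & if (tok == "-") is.na(col) else {
        !is.na(col) & col %in% token_states(tok)
      }
    }
    idx <- which(compat)
    if (!length(idx)) {
      stop("taxon '", m$taxa[i], "' has no dependency-consistent tuple ",
           "for complex {", paste(members, collapse = ","), "}")
    }
    idx
  })
  structure(list(members = members, states = states, cost = cost,
                 taxon_state_sets = tss, weights = weights,
                 n_members = length(members), taxa = m$taxa),
            class = "composite_char")
}

#' @export
print.composite_char <- function(x, ...) {
  cat("composite_char: members {", paste(x$members, collapse = ","),
      "},", nrow(x$states), "tuple states\n")
  invisible(x)
}

#' Build composites for every multi-character complex of a matrix
#'
#' @param m a [char_matrix()].
#' @param g a `dep_graph`.
#' @param cap state-space cap.
#' @return list with `composites` (list of `composite_char`) and
#'   `singletons` (indices of independent characters).
#' @export
build_composites <- function(m, g, cap = 4096L) {
  complexes <- find_complexes(g, n_characters(m))
  multi <- Filter(function(v) length(v) > 1L, complexes)
  single <- unlist(Filter(function(v) length(v) == 1L, complexes))
  list(composites = lapply(multi, build_composite, m = m, g = g, cap = cap),
       singletons = sort(as.integer(single)))
}

#' Serialize a composite character to a plain list (JSON-friendly)
#' @param comp a `composite_char`.
#' @return list of members, states (with `"-"` for inapplicable entries)
#'   and the cost matrix.
#' @export
composite_report <- function(comp) {
  list(members = comp$members,
       states = apply(comp$states, 1, function(row) {
         paste(ifelse(is.na(row), "-", row), collapse = "")
       }),
       cost = comp$cost)
}
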