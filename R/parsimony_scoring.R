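# Tree scoring: Fitch steps for independent characters, generalized
# (Sankoff) dynamic programming for composite characters, homoplasy,
# implied-weighting fits and the automatically derived concavity constant.

#' Weighting scheme for tree scoring
#'
#' @param mode `"EW"` (equal weights: total = sum of weighted steps) or
#'   `"IW"` (implied weighting: total = sum of concave homoplasy fits).
#' @param k concavity constant (IW only; must be positive).
#' @param ratio_N maximum admitted weight ratio between a homoplasy-free
#'   character and the most homoplastic one, used to derive `k`
#'   automatically (see [compute_sk()]); default 15.
#' @return object of class `weighting_scheme`.
#' @export
weighting_scheme <- function(mode = c("EW", "IW"), k = NULL, ratio_N = 15) {
  mode <- match.arg(mode)
  if (mode == "IW") {
    if (is.null(k) || !is.finite(k) || k <= 0) {
      stop("IW requires a positive concavity constant k")
    }
  }
  if (ratio_N <= 1) stop("ratio_N must exceed 1")
  structure(list(mode = mode, k = if (mode == "IW") k else NULL,
                 ratio_N = ratio_N),
            class = "weighting_scheme")
}

#' Fitch parsimony steps of one unordered character
#'
#' Minimum number of state changes on the tree under unordered parsimony.
#' Missing, inapplicable and polymorphic cells are ambiguity sets:
#' inapplicable expands to the full state set in this mode (the
#' traditional inapplicable-as-missing treatment).
#'
#' @param tree unrooted binary `phylo`.
#' @param cells named character vector of cell tokens (names = taxa);
#'   every leaf of `tree` must have a cell.
#' @param states integer vector of the character's state codes (defaults
#'   to the states observed in `cells`).
#' @return non-negative integer step count.
#' @export
fitch_steps <- function(tree, cells, states = NULL) {
  if (is.null(states)) {
    states <- observed_state_codes(cells)
    if (length(states) < 2L) states <- sort(unique(c(0L, 1L, states)))
  }
  miss <- setdiff(tree$tip.label, names(cells))
  if (length(miss)) stop("no cell for leaf '", miss[1], "'")
  masks <- vapply(cells[tree$tip.label], function(tok) {
    st <- cell_state_set(tok, states, inapplicable = "missing")
    sum(bitwShiftL(1L, match(st, states) - 1L))
  }, 1L)
  mm <- matrix(masks, ncol = 1, dimnames = list(tree$tip.label, NULL))
  fitch_count(tree, mm)[1]
}

# Sankoff message: out[s] = min_t (cost[t, s] + v[t]); row-wise pmin is
# much faster than apply() for the small state counts involved
sankoff_message <- function(cost, v) {
  out <- cost[1, ] + v[1]
  nr <- nrow(cost)
  if (nr > 1L) {
    for (t in 2:nr) {
      if (is.finite(v[t])) out <- pmin(out, cost[t, ] + v[t])
    }
  }
  out
}

# vectorized Fitch over a mask matrix (tips x chars, bitmasks over states,
# rows named by taxon)
fitch_count <- function(tree, leaf_masks) {
  rt <- rooted_binary(tree)
  ntip <- length(rt$tip.label)
  nnode <- ntip + rt$Nnode
  nchar_m <- ncol(leaf_masks)
  masks <- matrix(NA_integer_, nnode, nchar_m)
  masks[seq_len(ntip), ] <- leaf_masks[rt$tip.label, , drop = FALSE]
  steps <- rep(0L, nchar_m)
  edge <- rt$edge
  for (e in seq_len(nrow(edge))) {     # postorder: children final first
    p <- edge[e, 1]; child <- masks[edge[e, 2], ]
    acc <- masks[p, ]
    if (anyNA(acc)) {
      masks[p, ] <- child
    } else {
      inter <- bitwAnd(acc, child)
      hit <- inter == 0L
      steps <- steps + hit
      masks[p, ] <- ifelse(hit, bitwOr(acc, child), inter)
    }
  }
  steps
}

# root an unrooted binary topology on the edge leading to its first tip,
# returning a postorder-sorted binary rooted phylo
rooted_binary <- function(tree) {
  tr <- canonical_tree(tree)
  rt <- ape::root(tr, outgroup = tr$tip.label[1], resolve.root = TRUE)
  ape::reorder.phylo(rt, "postorder")
}

#' Generalized (Sankoff) parsimony cost of a composite character
#'
#' Minimum total cost over ancestral tuple assignments under the
#' composite's step matrix. Equals [fitch_steps()] when the composite is
#' degenerate (one unit-weight member).
#'
#' @param tree unrooted binary `phylo` over the composite's taxa.
#' @param comp a `composite_char` from [build_composite()].
#' @return non-negative numeric cost.
#' @export
sankoff_cost <- function(tree, comp) {
  rt <- rooted_binary(tree)
  ns <- nrow(comp$states)
  ntip <- length(rt$tip.label)
  nnode <- ntip + rt$Nnode
  tipidx <- match(rt$tip.label, comp$taxa)
  if (anyNA(tipidx)) {
    stop("leaf '", rt$tip.label[which(is.na(tipidx))[1]],
         "' not among the composite's taxa")
  }
  dp <- matrix(Inf, nnode, ns)
  for (i in seq_len(ntip)) {
    ok <- comp$taxon_state_sets[[tipidx[i]]]
    if (!length(ok)) stop("empty state set for leaf '", rt$tip.label[i], "'")
    dp[i, ok] <- 0
  }
  dp[(ntip + 1L):nnode, ] <- 0
  edge <- rt$edge
  for (e in seq_len(nrow(edge))) {     # postorder: children final first
    p <- edge[e, 1]; kid <- edge[e, 2]
    dp[p, ] <- dp[p, ] + sankoff_message(comp$cost, dp[kid, ])
  }
  min(dp[edge[nrow(edge), 1], ])
}

#' Tree-independent lower bound on a character's cost
#'
#' For an unordered character: `(number of states that must be observed -
#' 1) * w`, minimizing over the choices available to polymorphic cells.
#' For a composite: the exact Steiner minimal connection cost of the
#' definitely observed tuples under the step matrix
#' (Dreyfus-Wagner dynamic programming) when at most `steiner_cap`
#' terminals are involved, otherwise a minimum-spanning-tree value is
#' used and any negative homoplasy downstream is clamped at zero. The
#' bound never exceeds [sankoff_cost()] (or weighted [fitch_steps()]) on
#' any tree when computed exactly.
#'
#' @param x a `composite_char`, or a character vector of cell tokens for
#'   a plain character.
#' @param weight weight of a plain character (ignored for composites).
#' @param states state codes of a plain character.
#' @param steiner_cap largest terminal count for exact Steiner computation.
#' @return non-negative numeric lower-bound cost.
#' @export
min_possible_cost <- function(x, weight = 1, states = NULL,
                              steiner_cap = 10L) {
  if (inherits(x, "composite_char")) {
    return(composite_min_cost(x, steiner_cap))
  }
  cells <- x
  if (is.null(states)) states <- observed_state_codes(cells)
  sets <- Filter(length, lapply(cells, function(tok) {
    if (tok %in% c("?", "-")) integer(0) else token_states(tok)
  }))
  if (!length(sets)) return(0)
  singles <- unique(unlist(sets[vapply(sets, length, 1L) == 1L]))
  open <- Filter(function(s) !any(s %in% singles), sets)
  if (!length(open)) return(weight * max(0L, length(singles) - 1L))
  # polymorphic-only residue: choose extra states covering all open sets
  extra_pool <- sort(unique(unlist(open)))
  best <- length(extra_pool)
  for (sz in 0:length(extra_pool)) {
    if (sz >= best) break
    combs <- if (sz == 0L) list(integer(0)) else
      utils::combn(extra_pool, sz, simplify = FALSE)
    for (cmb in combs) {
      if (all(vapply(open, function(s) any(s %in% c(singles, cmb)), TRUE))) {
        best <- sz
        break
      }
    }
    if (best == sz) break
  }
  weight * max(0L, length(singles) + best - 1L)
}

composite_min_cost <- function(comp, steiner_cap = 10L) {
  terminals <- unique(unlist(Filter(
    function(s) length(s) == 1L, comp$taxon_state_sets)))
  if (length(terminals) <= 1L) return(0)
  d <- comp$cost
  if (length(terminals) <= steiner_cap) {
    steiner_cost(d, terminals)
  } else {
    mst_cost(d[terminals, terminals, drop = FALSE])
  }
}

# exact Steiner tree cost in a metric graph (Dreyfus-Wagner)
steiner_cost <- function(d, terminals) {
  nt <- length(terminals)
  if (nt == 2L) return(d[terminals[1], terminals[2]])
  n <- nrow(d)
  full <- bitwShiftL(1L, nt) - 1L
  # S[mask, v]: min cost of a tree spanning terminal subset `mask` plus v
  S <- matrix(Inf, full, n)
  for (t in seq_len(nt)) {
    S[bitwShiftL(1L, t - 1L), ] <- d[terminals[t], ]
  }
  masks <- seq_len(full)
  for (mask in masks[order(vapply(masks, bitcount, 1L))]) {
    if (bitcount(mask) < 2L) next
    sub <- mask
    best <- rep(Inf, n)
    s <- bitwAnd(mask - 1L, mask)
    while (s > 0L) {
      comp2 <- bitwAnd(mask, bitwNot(s))
      if (comp2 > 0L && s < comp2) {  # each split once
        best <- pmin(best, S[s, ] + S[comp2, ])
      }
      s <- bitwAnd(s - 1L, mask)
    }
    S[mask, ] <- pmin(S[mask, ], best)
    # relax through the metric
    for (v in seq_len(n)) {
      S[mask, ] <- pmin(S[mask, ], S[mask, v] + d[v, ])
    }
  }
  min(S[full, terminals])
}

bitcount <- function(x) sum(bitwAnd(bitwShiftR(x, 0:30), 1L))

mst_cost <- function(d) {
  n <- nrow(d)
  if (n <= 1L) return(0)
  intree <- c(TRUE, rep(FALSE, n - 1L))
  key <- d[1, ]
  tot <- 0
  for (step in seq_len(n - 1L)) {
    v <- which(!intree)[which.min(key[!intree])]
    tot <- tot + key[v]
    intree[v] <- TRUE
    key <- pmin(key, d[v, ])
  }
  tot
}

#' Implied-weighting fit contribution of a character
#'
#' For a plain character: `h / (h + k)`. For a composite of `n` members,
#' the single homoplasy score is the averaged member homoplasy times
#' their number: `n * hbar / (hbar + k)` with `hbar = h / n`.
#'
#' @param h total (member-summed) homoplasy, non-negative.
#' @param k concavity constant, positive.
#' @param n member count (1 for a plain character).
#' @return fit cost in `[0, n)`; 0 iff `h = 0`.
#' @export
iw_contribution <- function(h, k, n = 1) {
  if (any(k <= 0)) stop("concavity constant k must be positive")
  if (any(h < 0)) stop("homoplasy must be non-negative")
  hbar <- h / n
  n * hbar / (hbar + k)
}

#' Automatically derived concavity constant from a weight ratio
#'
#' Chooses `k` so that a homoplasy-free character weighs exactly `N`
#' times as much as the most homoplastic character in the dataset:
#' the implied weight ratio `f(0)/f(h_max) = (k + h_max)/k = N`, hence
#' `k = h_max / (N - 1)`. `h_max` is conventionally measured on the best
#' equal-weights tree(s) found in a preliminary search (see
#' [dataset_h_max()]).
#'
#' @param h_max maximum per-character homoplasy in the dataset (> 0).
#' @param N desired maximum weight ratio (> 1), default 15.
#' @return the concavity constant `k`.
#' @export
compute_sk <- function(h_max, N = 15) {
  if (N <= 1) stop("ratio N must exceed 1")
  if (!is.finite(h_max) || h_max < 0) stop("h_max must be non-negative")
  if (h_max == 0) stop("dataset is homoplasy-free; implied weighting is pointless")
  h_max / (N - 1)
}

#' Maximum per-character homoplasy over a set of trees
#'
#' @param trees list of trees (typically the best equal-weights trees).
#' @param m the [char_matrix()].
#' @param g optional `dep_graph` (required with composites).
#' @param use_composites score dependency complexes as composites.
#' @return the largest per-unit homoplasy `h` found.
#' @export
dataset_h_max <- function(trees, m, g = NULL, use_composites = FALSE) {
  scorer <- make_scorer(m, g, weighting_scheme("EW"),
                        use_composites = use_composites)
  max(vapply(trees, function(tr) max(scorer$report(tr)$h), 1))
}

#' Precompile a tree scorer for repeated evaluation
#'
#' Precomputes leaf bitmasks, composite structures, per-unit minimum
#' costs and weights once, returning closures used by the search
#' machinery: `total(tree)` (the quantity minimized under the scheme)
#' and `report(tree)` (the per-unit score table).
#'
#' @param m a [char_matrix()].
#' @param g a `dep_graph`, or `NULL` for no dependencies.
#' @param scheme a [weighting_scheme()].
#' @param use_composites score dependency complexes as composite
#'   characters (Sankoff); otherwise every character is scored by Fitch
#'   with inapplicables as missing.
#' @param cap composite state-space cap.
#' @return object of class `tree_scorer`: list with `total`, `report`,
#'   `ew_total` (equal-weights total, used for tie-breaking), `scheme`,
#'   `m`, and the compiled units.
#' @export
make_scorer <- function(m, g = NULL, scheme = weighting_scheme("EW"),
                        use_composites = FALSE, cap = 4096L) {
  if (use_composites && is.null(g)) {
    stop("composite scoring needs a dependency graph")
  }
  nch <- n_characters(m)
  if (use_composites) {
    built <- build_composites(m, g, cap = cap)
    composites <- built$composites
    singles <- built$singletons
  } else {
    composites <- list()
    singles <- seq_len(nch)
  }
  weights <- m$characters$weight
  # Fitch block over independent characters
  masks <- NULL
  single_min <- numeric(0)
  if (length(singles)) {
    masks <- vapply(singles, function(j) {
      codes <- m$characters$states[[j]]
      vapply(m$cells[, j], function(tok) {
        st <- cell_state_set(tok, codes, inapplicable = "missing")
        sum(bitwShiftL(1L, match(st, codes) - 1L))
      }, 1L)
    }, integer(length(m$taxa)))
    rownames(masks) <- m$taxa
    single_min <- vapply(singles, function(j) {
      min_possible_cost(m$cells[, j], weight = 1,
                        states = m$characters$states[[j]])
    }, 1)
  }
  comp_min <- vapply(composites, composite_min_cost, 1)
  comp_w <- vapply(composites, function(cc) cc$weights[1], 1)
  comp_n <- vapply(composites, `[[`, 1L, "n_members")
  # per-composite tip cost rows (0 allowed / Inf otherwise), by taxon
  comp_tipdp <- lapply(composites, function(cc) {
    out <- matrix(Inf, length(cc$taxa), nrow(cc$states),
                  dimnames = list(cc$taxa, NULL))
    for (i in seq_along(cc$taxa)) out[i, cc$taxon_state_sets[[i]]] <- 0
    out
  })

  # one shared postorder sweep over either a phylo or a utree: Fitch
  # masks for the independent block, per-composite Sankoff DP
  as_ut <- function(x) if (inherits(x, "utree")) x else utree_from_phylo(x)
  eval_units <- function(x) {
    ut <- as_ut(x)
    po <- ut_postorder(ut)
    nnode <- length(ut$adj)
    tipids <- which(!is.na(ut$labels))
    steps <- NULL
    if (length(singles)) {
      mk <- matrix(0L, nnode, length(singles))
      mk[tipids, ] <- masks[ut$labels[tipids], , drop = FALSE]
      steps <- fitch_masks_cpp(po, mk)
    }
    ccosts <- if (length(composites)) {
      labs <- ut$labels[tipids]
      vapply(seq_along(composites), function(ci) {
        cc <- composites[[ci]]
        dp <- matrix(0, nnode, nrow(cc$states))
        dp[tipids, ] <- comp_tipdp[[ci]][labs, , drop = FALSE]
        sankoff_total_cpp(po, cc$cost, dp)
      }, 1)
    } else numeric(0)
    list(steps = steps, ccosts = ccosts)
  }
  contribs <- function(x) {
    ev <- eval_units(x)
    out <- numeric(0)
    if (length(singles)) {
      out <- if (scheme$mode == "EW") ev$steps * weights[singles] else
        iw_contribution(pmax(0, ev$steps - single_min), scheme$k)
    }
    if (length(composites)) {
      cc <- if (scheme$mode == "EW") ev$ccosts else
        iw_contribution(pmax(0, (ev$ccosts - comp_min) / comp_w),
                        scheme$k, comp_n)
      out <- c(out, cc)
    }
    out
  }
  total <- function(x) sum(contribs(x))
  ew_total <- function(x) {
    ev <- eval_units(x)
    sum(ev$steps * weights[singles], ev$ccosts)
  }
  report <- function(tree) {
    ev <- eval_units(tree)
    rows <- list()
    if (length(singles)) {
      rows[[1]] <- data.frame(
        unit = paste0("char", singles),
        steps = ev$steps * weights[singles],
        min_steps = single_min * weights[singles],
        h = pmax(0, ev$steps - single_min), n_members = 1L)
    }
    if (length(composites)) {
      rows[[length(rows) + 1L]] <- data.frame(
        unit = vapply(composites, function(cc) {
          paste0("complex{", paste(cc$members, collapse = ","), "}")
        }, ""),
        steps = ev$ccosts,
        min_steps = comp_min,
        h = pmax(0, (ev$ccosts - comp_min) / comp_w),
        n_members = comp_n)
    }
    out <- do.call(rbind, rows)
    out$contribution <- if (scheme$mode == "EW") out$steps else {
      iw_contribution(out$h, scheme$k, out$n_members)
    }
    out
  }
  units <- c(
    lapply(seq_along(singles), function(si) {
      j <- singles[si]
      codes <- m$characters$states[[j]]
      ns <- length(codes)
      leaf_sets <- lapply(seq_along(m$taxa), function(i) {
        st <- cell_state_set(m$cells[i, j], codes, inapplicable = "missing")
        match(st, codes)
      })
      names(leaf_sets) <- m$taxa
      list(cost = weights[j] * (1 - diag(ns)), leaf_sets = leaf_sets)
    }),
    lapply(composites, function(cc) {
      leaf_sets <- cc$taxon_state_sets
      names(leaf_sets) <- cc$taxa
      list(cost = cc$cost, leaf_sets = leaf_sets)
    }))
  structure(list(total = total, contribs = contribs, report = report,
                 ew_total = ew_total, scheme = scheme, m = m,
                 composites = composites, singletons = singles,
                 units = units),
            class = "tree_scorer")
}

#' Score a tree and return the per-character report
#'
#' @param tree unrooted binary `phylo` over the matrix's taxa.
#' @param m a [char_matrix()].
#' @param g optional `dep_graph`.
#' @param scheme a [weighting_scheme()].
#' @param use_composites score dependency complexes as composites.
#' @return list with `per_character` (data frame: unit, steps, min_steps,
#'   homoplasy `h`, members, contribution) and `total_score`.
#' @export
score_tree <- function(tree, m, g = NULL, scheme = weighting_scheme("EW"),
                       use_composites = FALSE) {
  scorer <- make_scorer(m, g, scheme, use_composites)
  rp <- scorer$report(tree)
  list(per_character = rp, total_score = sum(rp$contribution))
}

#' Write a score report as TSV
#' @param report result of [score_tree()].
#' @param path output path.
#' @export
write_score_report <- function(report, path) {
  utils::write.table(report$per_character, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
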