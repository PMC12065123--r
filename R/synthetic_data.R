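# Synthetic fixtures with the statistical and ontological structure the
# analysis assumes: matrices evolved on known trees with dependency
# complexes, serial blocks and missing data; the canonical tail/colour
# fixture; and the uniramous-pleopod scoring demonstration.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a worked morphological
#' dataset: discrete unordered characters, hierarchical dependency
#' complexes (controller absent implies dependents inapplicable),
#' optional serial-homologue blocks over ordered positions, and a
#' missing-data fraction of about 12.85% of cells.
#'
#' @param n_taxa number of terminal taxa.
#' @param n_characters total number of characters.
#' @param dependency_fraction fraction of characters organized into
#'   dependency complexes.
#' @param complex_size_range integer interval of complex sizes
#'   (controller plus dependents).
#' @param serial_blocks list of `c(length, streak)` pairs; each becomes
#'   a serial block of binary presence characters appended to the
#'   matrix (`streak` as 0/1).
#' @param missing_fraction fraction of applicable cells rewritten to
#'   missing.
#' @param state_change_rate expected number of state changes per
#'   character on the true tree.
#' @param n_states_range state-count interval for transformational
#'   characters (controllers are always binary absent/present).
#' @param rng_seed integer seed; identical configurations and seeds give
#'   byte-identical output.
#' @param true_tree optional `phylo` to evolve on (random otherwise).
#' @param taxon_missing_skew optional named numeric: extra missing
#'   fraction applied to specific taxa (emulating unevenly known taxa).
#' @param weight common character weight (10 matches the ten-fold
#'   upweighting used alongside serial-block discounts).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 10L, n_characters = 60L,
                       dependency_fraction = 0.3,
                       complex_size_range = c(2L, 4L),
                       serial_blocks = list(),
                       missing_fraction = 0.1285,
                       state_change_rate = 1,
                       n_states_range = c(2L, 4L),
                       rng_seed = 1L, true_tree = NULL,
                       taxon_missing_skew = NULL,
                       weight = 1) {
  stopifnot(n_taxa >= 4L, n_characters >= 1L,
            dependency_fraction >= 0, dependency_fraction <= 1,
            missing_fraction >= 0, missing_fraction <= 1,
            state_change_rate >= 0, weight > 0)
  if (complex_size_range[1] < 2L) stop("complexes need at least 2 members")
  structure(list(n_taxa = as.integer(n_taxa),
                 n_characters = as.integer(n_characters),
                 dependency_fraction = dependency_fraction,
                 complex_size_range = as.integer(complex_size_range),
                 serial_blocks = serial_blocks,
                 missing_fraction = missing_fraction,
                 state_change_rate = state_change_rate,
                 n_states_range = as.integer(n_states_range),
                 rng_seed = as.integer(rng_seed),
                 true_tree = true_tree,
                 taxon_missing_skew = taxon_missing_skew,
                 weight = weight),
            class = "sim_config")
}

#' Simulate a character matrix on a known tree
#'
#' Characters evolve by a fixed-number-of-changes model: each character
#' draws a Poisson change count at the configured rate and places the
#' changes on random branches, so the truth ledger records exact change
#' counts. Dependent characters change only on branches whose both ends
#' have their controller present, and their cells are inapplicable
#' wherever the controller is absent, guaranteeing ontological
#' consistency before missing data are injected. Streak-flagged serial
#' blocks evolve as contiguous runs whose boundaries move by single
#' steps.
#'
#' @param config a [sim_config()].
#' @return list with `matrix` (a [char_matrix()] whose statements carry
#'   dependency annotations), `graph` (the corresponding `dep_graph`),
#'   and `ledger` (true tree, per-character true change counts, complex
#'   membership, serial blocks).
#' @export
simulate_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$rng_seed, simulate_matrix_impl(config))
}

# sample one element of a vector (safe for length-1 vectors, where
# sample() would read the value as a population size)
pick1 <- function(x) x[sample.int(length(x), 1L)]

simulate_matrix_impl <- function(cfg) {
  taxa <- sprintf("t%02d", seq_len(cfg$n_taxa))
  true <- if (is.null(cfg$true_tree)) {
    canonical_tree(ape::rtree(cfg$n_taxa, rooted = FALSE,
                              tip.label = sample(taxa)))
  } else canonical_tree(cfg$true_tree)
  if (!setequal(true$tip.label, taxa) &&
      !is.null(cfg$true_tree)) taxa <- sort(true$tip.label)
  rt <- rooted_binary(true)
  edge <- rt$edge
  nnode <- max(edge)
  ntip <- length(rt$tip.label)
  preorder <- rev(seq_len(nrow(edge)))

  n_serial <- sum(vapply(cfg$serial_blocks, function(b) b[1], 1))
  n_plain_total <- cfg$n_characters - n_serial
  if (n_plain_total < 1L) stop("serial blocks exceed n_characters")
  n_dep <- round(cfg$dependency_fraction * n_plain_total)
  # carve complexes (controller + dependents) out of the dependency budget
  complexes <- list()
  used <- 0L
  while (used < n_dep) {
    size <- pick1(seq(cfg$complex_size_range[1],
                      cfg$complex_size_range[2]))
    size <- min(size, n_dep - used)
    if (size < 2L) break
    complexes[[length(complexes) + 1L]] <- used + seq_len(size)
    used <- used + size
  }
  if (length(complexes) && max(unlist(complexes)) > n_plain_total) {
    stop("complex sizes exceed the number of characters")
  }

  cells <- matrix("?", cfg$n_taxa, cfg$n_characters,
                  dimnames = list(taxa, NULL))
  statements <- character(cfg$n_characters)
  states_list <- vector("list", cfg$n_characters)
  change_counts <- integer(cfg$n_characters)
  node_states <- matrix(NA_integer_, nnode, cfg$n_characters)

  evolve_char <- function(codes, allowed_edges = seq_len(nrow(edge)),
                          n_changes = NULL) {
    st <- integer(nnode)
    rootn <- edge[nrow(edge), 1]
    st[rootn] <- pick1(codes)
    if (is.null(n_changes)) {
      # fixed-number-of-changes model: exactly `rate` changes per
      # character (fractional remainder as a Bernoulli top-up), so the
      # truth ledger is exact
      r <- cfg$state_change_rate
      n_changes <- floor(r) + stats::rbinom(1L, 1L, r - floor(r))
    }
    hot <- if (length(allowed_edges) && n_changes > 0L) {
      sample(rep(allowed_edges, 2L),
             min(n_changes, 2L * length(allowed_edges)))
    } else integer(0)
    for (e in preorder) {
      p <- edge[e, 1]; v <- edge[e, 2]
      st[v] <- st[p]
      for (k in seq_len(sum(hot == e))) {
        st[v] <- pick1(setdiff(codes, st[v]))
      }
    }
    list(states = st, changes = length(hot))
  }

  ctrl_of <- integer(cfg$n_characters)  # 0 = independent
  for (cx in seq_along(complexes)) {
    idx <- complexes[[cx]]
    ctrl <- idx[1]
    states_list[[ctrl]] <- 0:1
    ev <- evolve_char(0:1)
    node_states[, ctrl] <- ev$states
    change_counts[ctrl] <- ev$changes
    statements[ctrl] <- sprintf(
      "Complex %d controller: (0) absent, (1) present", cx)
    cells[, ctrl] <- as.character(ev$states[seq_len(ntip)][
      match(taxa, rt$tip.label)])
    present_edges <- which(ev$states[edge[, 1]] == 1L &
                             ev$states[edge[, 2]] == 1L)
    for (dpos in idx[-1]) {
      ns <- pick1(seq(cfg$n_states_range[1], cfg$n_states_range[2]))
      codes <- seq_len(ns) - 1L
      states_list[[dpos]] <- codes
      ev2 <- evolve_char(codes, allowed_edges = present_edges)
      node_states[, dpos] <- ev2$states
      change_counts[dpos] <- ev2$changes
      ctrl_of[dpos] <- ctrl
      statements[dpos] <- sprintf(
        "[%d.1>this]Complex %d dependent %d: %s", ctrl, cx, dpos,
        paste(sprintf("(%d) state %d", codes, codes), collapse = ", "))
      leafst <- ev2$states[seq_len(ntip)][match(taxa, rt$tip.label)]
      ctrl_leaf <- node_states[seq_len(ntip), ctrl][match(taxa, rt$tip.label)]
      cells[, dpos] <- ifelse(ctrl_leaf == 1L, as.character(leafst), "-")
    }
  }
  # independent characters
  for (j in setdiff(seq_len(n_plain_total), unlist(complexes))) {
    ns <- pick1(seq(cfg$n_states_range[1], cfg$n_states_range[2]))
    codes <- seq_len(ns) - 1L
    states_list[[j]] <- codes
    ev <- evolve_char(codes)
    change_counts[j] <- ev$changes
    statements[j] <- sprintf("Independent character %d: %s", j,
                             paste(sprintf("(%d) state %d", codes, codes),
                                   collapse = ", "))
    cells[, j] <- as.character(ev$states[seq_len(ntip)][
      match(taxa, rt$tip.label)])
  }
  # serial blocks: contiguous-run (streak) or independent binary members
  blocks <- list()
  at <- n_plain_total
  for (bi in seq_along(cfg$serial_blocks)) {
    len <- cfg$serial_blocks[[bi]][1]
    streak <- isTRUE(cfg$serial_blocks[[bi]][2] == 1)
    members <- at + seq_len(len)
    at <- at + len
    blocks[[bi]] <- serial_block(members, streak = streak)
    for (j in members) {
      states_list[[j]] <- 0:1
      statements[j] <- sprintf("Serial block %d position %d: %s", bi,
                               j - members[1] + 1L,
                               "(0) absent, (1) present")
    }
    if (streak) {
      # interval-valued evolution: (lo, hi) with 0-length = empty
      iv <- matrix(NA_integer_, nnode, 2)
      rootn <- edge[nrow(edge), 1]
      lo <- pick1(seq_len(len))
      hi <- min(len, lo + pick1(0:(len - 1L)))
      iv[rootn, ] <- c(lo, hi)
      nch <- max(1L, round(cfg$state_change_rate * len / 2))
      hot <- sample(rep(seq_len(nrow(edge)), 2L),
                    min(nch, nrow(edge)))
      moves <- 0L
      for (e in preorder) {
        p <- edge[e, 1]; v <- edge[e, 2]
        iv[v, ] <- iv[p, ]
        for (k in seq_len(sum(hot == e))) {
          iv[v, ] <- streak_move(iv[v, ], len)
          moves <- moves + 1L
        }
      }
      for (j in members) {
        pos <- j - members[1] + 1L
        leafiv <- iv[seq_len(ntip), , drop = FALSE][
          match(taxa, rt$tip.label), , drop = FALSE]
        inrun <- !is.na(leafiv[, 1]) & leafiv[, 1] <= pos &
          pos <= leafiv[, 2]
        cells[, j] <- ifelse(inrun, "1", "0")
        change_counts[j] <- NA_integer_  # block-level, see ledger
      }
      blocks[[bi]]$true_moves <- moves
    } else {
      for (j in members) {
        ev <- evolve_char(0:1)
        change_counts[j] <- ev$changes
        cells[, j] <- as.character(ev$states[seq_len(ntip)][
          match(taxa, rt$tip.label)])
      }
    }
  }
  # missing-data injection (never touches inapplicable cells; never
  # creates violations since missing is neutral)
  applicable <- which(cells != "-")
  n_miss <- round(cfg$missing_fraction * length(applicable))
  if (n_miss > 0L) cells[sample(applicable, n_miss)] <- "?"
  if (!is.null(cfg$taxon_missing_skew)) {
    for (tx in names(cfg$taxon_missing_skew)) {
      row <- which(taxa == tx)
      appl <- which(cells[row, ] != "-")
      extra <- round(cfg$taxon_missing_skew[[tx]] * length(appl))
      if (extra > 0L) cells[row, sample(appl, min(extra, length(appl)))] <- "?"
    }
  }
  chars <- data.frame(row = seq_len(cfg$n_characters))
  chars$statement <- statements
  chars$states <- states_list
  chars$weight <- cfg$weight
  m <- char_matrix(taxa, cells, chars)
  g <- build_dependency_graph(m, serial_blocks = blocks)
  ledger <- list(true_tree = true, change_counts = change_counts,
                 complexes = complexes, serial_blocks = blocks,
                 participating = participating_characters(g),
                 config = cfg)
  list(matrix = m, graph = g, ledger = ledger)
}

# one random legal boundary move of a streak interval (NA,NA = empty)
streak_move <- function(iv, len) {
  empty <- is.na(iv[1]) || iv[1] > iv[2]
  if (empty) {
    p <- pick1(seq_len(len))
    return(c(p, p))
  }
  lo <- iv[1]; hi <- iv[2]
  opts <- list()
  if (lo > 1L) opts <- c(opts, list(c(lo - 1L, hi)))
  if (hi < len) opts <- c(opts, list(c(lo, hi + 1L)))
  if (lo < hi) opts <- c(opts, list(c(lo + 1L, hi), c(lo, hi - 1L)))
  if (lo == hi) opts <- c(opts, list(c(NA_integer_, NA_integer_)))
  opts[[sample.int(length(opts), 1L)]]
}

#' The tail/colour fixture
#'
#' Eight taxa; a controller "tail: absent/present" and a dependent
#' "tail colour: red/blue". Four taxa bear tails in two separate
#' regions: one clade of three with mixed colours and one lone tailed
#' taxon. The two candidate topologies differ only in the internal
#' arrangement of the mixed clade; both imply two independent origins of
#' the tail. Under composite scoring every colour assignment gives the
#' two topologies identical cost, whereas the inapplicable-as-missing
#' treatment scores them differently — driven solely by colour states
#' reconstructed for tailless ancestors.
#'
#' @return list with `matrix`, `graph` and `topologies` (list of the two
#'   candidate trees, `same_colour_adjacent` first).
#' @export
maddison_fixture <- function() {
  taxa <- LETTERS[1:8]
  #          tail  colour
  cells <- rbind(
    A = c("1", "0"), B = c("1", "0"), C = c("1", "1"), D = c("1", "1"),
    E = c("0", "-"), F = c("0", "-"), G = c("0", "-"), H = c("0", "-"))
  chars <- data.frame(row = 1:2)
  chars$statement <- c(
    "Tail: (0) absent, (1) present",
    "[1.1>this]Tail colour: (0) red, (1) blue")
  chars$char_type <- c("neomorphic", "transformational")
  chars$states <- list(0:1, 0:1)
  m <- char_matrix(taxa, cells, chars)
  g <- build_dependency_graph(m)
  t_a <- tree_from_newick("((((A,B),C),E),(F,(G,(D,H))));")
  t_b <- tree_from_newick("((((A,C),B),E),(F,(G,(D,H))));")
  list(matrix = m, graph = g, topologies = list(t_a, t_b))
}

#' The uniramous-pleopod scoring fixture
#'
#' A small matrix mirroring the ambiguous single pleopodal ramus case:
#' two hierarchically higher characters (endopod and exopod
#' absent/present) each controlling dependent characters, and one
#' uniramous taxon whose single ramus could be either. Three scoring
#' variants of that taxon are returned: `exopod_present` (the adopted
#' interpretation), `endopod_present`, and `both_missing` (all nine
#' cells missing), the latter admitting forbidden both-present or
#' both-absent optimizations.
#'
#' @return list with one [char_matrix()] per variant, the shared
#'   `graph`, the name of the `uniramous` taxon, and `chars` (indices of
#'   the endopod/exopod controllers).
#' @export
uniramy_fixture <- function() {
  taxa <- c("uniramous", "biramA", "biramB", "biramC", "endoOnly", "outgrp")
  # chars: 1 endopod HHC; 2-4 its dependents; 5 exopod HHC; 6-9 its
  # dependents; 10-12 ordinary characters giving tree structure
  base <- rbind(
    uniramous = c("0", "-", "-", "-", "1", "0", "1", "0", "1",
                  "0", "0", "0"),
    biramA    = c("1", "0", "1", "0", "1", "0", "1", "0", "1",
                  "0", "1", "0"),
    biramB    = c("1", "1", "0", "1", "1", "1", "0", "1", "0",
                  "1", "0", "1"),
    biramC    = c("1", "0", "0", "1", "1", "0", "1", "1", "0",
                  "1", "1", "0"),
    endoOnly  = c("1", "1", "1", "0", "0", "-", "-", "-", "-",
                  "0", "0", "1"),
    outgrp    = c("1", "0", "0", "0", "1", "0", "0", "0", "0",
                  "0", "0", "0"))
  chars <- data.frame(row = 1:12)
  chars$statement <- c(
    "Pleopods, endopods: (0) absent, (1) present",
    sprintf("[1.1>this]Endopod dependent %d: (0) state 0, (1) state 1", 1:3),
    "Pleopods, exopods: (0) absent, (1) present",
    sprintf("[5.1>this]Exopod dependent %d: (0) state 0, (1) state 1", 1:4),
    sprintf("Ordinary character %d: (0) state 0, (1) state 1", 1:3))
  chars$states <- rep(list(0:1), 12)
  adopted <- char_matrix(taxa, base, chars)
  endo <- adopted
  endo$cells["uniramous", 1:9] <- c("1", "0", "1", "0", "0",
                                    "-", "-", "-", "-")
  missing <- adopted
  missing$cells["uniramous", 1:9] <- "?"
  g <- build_dependency_graph(adopted)
  list(exopod_present = adopted, endopod_present = endo,
       both_missing = missing, graph = g,
       uniramous = "uniramous", chars = c(endopod = 1L, exopod = 5L))
}

#' Leaf tuples used by some optimal reconstruction
#'
#' For a given tree and composite character, returns which of a taxon's
#' compatible tuple states appear in at least one minimum-cost ancestral
#' reconstruction — the tool used to demonstrate which interpretations a
#' scoring variant admits.
#'
#' @param tree a `phylo` over the composite's taxa.
#' @param comp a `composite_char`.
#' @param taxon taxon label.
#' @return integer vector of state-row indices into `comp$states`.
#' @export
optimal_leaf_assignments <- function(tree, comp, taxon) {
  idx <- match(taxon, comp$taxa)
  if (is.na(idx)) stop("unknown taxon '", taxon, "'")
  cand <- comp$taxon_state_sets[[idx]]
  base <- sankoff_cost(tree, comp)
  keep <- integer(0)
  for (s in cand) {
    restricted <- comp
    restricted$taxon_state_sets[[idx]] <- s
    if (sankoff_cost(tree, restricted) <= base + 1e-9) keep <- c(keep, s)
  }
  keep
}
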