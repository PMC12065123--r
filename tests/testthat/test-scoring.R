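quartet <- tree_from_newick("((A,B),(C,D));")
cells4 <- function(...) stats::setNames(c(...), c("A", "B", "C", "D"))

test_that("Fitch steps on quartets match hand-counted values", {
  expect_equal(fitch_steps(quartet, cells4("0", "0", "1", "1")), 1L)
  expect_equal(fitch_steps(quartet, cells4("0", "1", "0", "1")), 2L)
  expect_equal(fitch_steps(quartet, cells4("0", "0", "1", "?")), 1L)
  expect_equal(fitch_steps(quartet, cells4("0", "0", "1", "-")), 1L)
  expect_equal(fitch_steps(quartet, cells4("01", "1", "0", "0")), 1L)
  expect_equal(fitch_steps(quartet, cells4("01", "0", "0", "0")), 0L)
  expect_error(fitch_steps(quartet, c(A = "0", B = "1", C = "0")), "D")
})

test_that("Sankoff scoring handles the tail/colour composite", {
  fx <- maddison_fixture()
  comp <- build_composite(1:2, fx$matrix, fx$graph)
  # one tail origin, one colour change: ((A,C),(E,F,G,H...)) with B apart
  tr <- tree_from_newick("((((A,C),B),E),(F,(G,(D,H))));")
  expect_equal(sankoff_cost(tr, comp), 3)
  # brute-force equivalence on the fixture trees
  leaf_sets <- stats::setNames(comp$taxon_state_sets, comp$taxa)
  for (tt in fx$topologies) {
    expect_equal(sankoff_cost(tt, comp),
                 brute_min_cost(tt, comp$cost, leaf_sets))
  }
  # all taxa sharing one tuple score zero
  m0 <- fx$matrix
  m0$cells[, 1] <- "1"
  m0$cells[, 2] <- "0"
  comp0 <- build_composite(1:2, m0, fx$graph)
  expect_equal(sankoff_cost(fx$topologies[[1]], comp0), 0)
})

test_that("minimum possible cost bounds are exact on small cases", {
  expect_equal(min_possible_cost(c("0", "1", "0")), 1)
  expect_equal(min_possible_cost(c("0", "1", "2")), 2)
  expect_equal(min_possible_cost(c("0", "1", "2"), weight = 10), 20)
  expect_equal(min_possible_cost(c("0", "?", "-")), 0)
  expect_equal(min_possible_cost(c("01", "01", "01")), 0)
  fx <- maddison_fixture()
  comp <- build_composite(1:2, fx$matrix, fx$graph)
  expect_equal(min_possible_cost(comp), 2)
  # never exceeds the tree cost, on any topology
  sub <- fx$matrix
  sub$cells <- sub$cells[LETTERS[1:5], , drop = FALSE]
  sub$taxa <- LETTERS[1:5]
  comp5 <- build_composite(1:2, sub, fx$graph)
  for (tr in all_topologies(LETTERS[1:5])) {
    expect_lte(min_possible_cost(comp5), sankoff_cost(tr, comp5))
  }
})

test_that("implied-weighting fits follow the concave formula", {
  expect_equal(iw_contribution(0, 3), 0)
  expect_equal(iw_contribution(3, 3), 0.5)
  expect_equal(iw_contribution(4, 2, n = 2), 1.0)  # hbar = 2: 2 * 2/4
  expect_error(iw_contribution(1, 0), "positive")
  expect_error(iw_contribution(-1, 1), "non-negative")
  h <- seq(0, 10, by = 0.5)
  f <- iw_contribution(h, 2)
  expect_true(all(diff(f) > 0))          # strictly increasing
  expect_true(all(diff(diff(f)) < 0))    # concave
})

test_that("the automatic concavity constant realizes the weight ratio", {
  expect_equal(compute_sk(14, 15), 1)
  expect_equal(compute_sk(28, 15), 2)
  k <- compute_sk(5.5, 15)
  expect_equal((k + 5.5) / k, 15)        # ratio is exactly N
  # inversion: the value implied by k = 5.443699 at N = 15
  expect_equal(5.443699 * (15 - 1), 76.211786)
  expect_error(compute_sk(0, 15), "homoplasy-free")
  expect_error(compute_sk(10, 1), "exceed")
})

test_that("tree scores aggregate per-character contributions", {
  taxa <- paste0("t", 1:6)
  cells <- matrix("0", 6, 4, dimnames = list(taxa, NULL))
  m0 <- char_matrix(taxa, cells)
  tr <- rand_tree(taxa, 1)
  expect_equal(score_tree(tr, m0)$total_score, 0)

  sim <- simulate_matrix(sim_config(n_taxa = 6, n_characters = 12,
                                    dependency_fraction = 0,
                                    state_change_rate = 2, rng_seed = 2))
  tr <- rand_tree(sim$matrix$taxa, 1)
  sc <- score_tree(tr, sim$matrix)
  oracle <- sum(vapply(seq_len(12), function(j) {
    brute_fitch(tr, sim$matrix$cells[, j], sim$matrix$characters$states[[j]])
  }, 1))
  expect_equal(sc$total_score, oracle)
  expect_true(all(sc$per_character$h >= 0))
})

test_that("Fitch and Sankoff equal exhaustive enumeration on small trees", {
  for (seed in 1:3) {
    sim <- simulate_matrix(sim_config(n_taxa = 6, n_characters = 10,
                                      dependency_fraction = 0.5,
                                      complex_size_range = c(2L, 3L),
                                      n_states_range = c(2L, 3L),
                                      state_change_rate = 2,
                                      rng_seed = seed + 10))
    tr <- rand_tree(sim$matrix$taxa, seed)
    built <- build_composites(sim$matrix, sim$graph)
    for (j in built$singletons) {
      cells <- stats::setNames(sim$matrix$cells[, j], sim$matrix$taxa)
      states <- sim$matrix$characters$states[[j]]
      expect_equal(fitch_steps(tr, cells, states),
                   brute_fitch(tr, cells, states))
      # independent library cross-check (phangorn's Fitch parsimony)
      tok <- ifelse(cells %in% c("?", "-"), "?", cells)
      poly <- nchar(tok) > 1
      if (!any(poly)) {
        pd <- phangorn::phyDat(matrix(tok, ncol = 1,
                                      dimnames = list(names(cells), NULL)),
                               type = "USER",
                               levels = as.character(states))
        expect_equal(fitch_steps(tr, cells, states),
                     as.integer(phangorn::parsimony(tr, pd)))
      }
    }
    for (comp in built$composites) {
      leaf_sets <- stats::setNames(comp$taxon_state_sets, comp$taxa)
      expect_equal(sankoff_cost(tr, comp),
                   brute_min_cost(tr, comp$cost, leaf_sets))
    }
  }
})

test_that("vector dominance and the equal-weights limit order trees consistently", {
  sim <- simulate_matrix(sim_config(n_taxa = 7, n_characters = 16,
                                    dependency_fraction = 0,
                                    state_change_rate = 2, rng_seed = 5))
  t1 <- sim$ledger$true_tree
  t2 <- rand_tree(sim$matrix$taxa, 99)
  ew <- make_scorer(sim$matrix)
  r1 <- ew$report(t1)
  r2 <- ew$report(t2)
  if (all(r1$h <= r2$h) && any(r1$h < r2$h)) {
    for (k in c(0.5, 2, 8, 32)) {
      iw <- make_scorer(sim$matrix, scheme = weighting_scheme("IW", k = k))
      expect_lt(iw$total(t1), iw$total(t2))
    }
  }
  # IW ranking converges to EW ranking as k grows
  trees <- c(list(t1, t2), lapply(1:4, function(s) {
    rand_tree(sim$matrix$taxa, 200 + s)
  }))
  ew_rank <- order(vapply(trees, ew$total, 1))
  iw_big <- make_scorer(sim$matrix,
                        scheme = weighting_scheme("IW", k = 1e9))
  iw_rank <- order(vapply(trees, iw_big$total, 1))
  expect_equal(vapply(trees, ew$total, 1)[iw_rank],
               vapply(trees, ew$total, 1)[ew_rank])
})
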