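test_that("simulated matrices are consistent, seeded and ledgered", {
  cfg <- sim_config(n_taxa = 9, n_characters = 36,
                    dependency_fraction = 0.4,
                    serial_blocks = list(c(4, 1)), rng_seed = 21)
  sim <- simulate_matrix(cfg)
  expect_equal(dim(sim$matrix$cells), c(9L, 36L))
  # dependency consistency before and after missing injection
  expect_equal(nrow(validate_and_autoscore(sim$matrix, sim$graph,
                                           "report")), 0L)
  # byte-identical under the same config and seed
  sim2 <- simulate_matrix(cfg)
  expect_identical(sim$matrix$cells, sim2$matrix$cells)
  expect_identical(canonical_key(sim$ledger$true_tree),
                   canonical_key(sim2$ledger$true_tree))
  # a different seed gives different data
  sim3 <- simulate_matrix(sim_config(n_taxa = 9, n_characters = 36,
                                     dependency_fraction = 0.4,
                                     serial_blocks = list(c(4, 1)),
                                     rng_seed = 22))
  expect_false(identical(sim$matrix$cells, sim3$matrix$cells))
  # missing fraction near the configured default
  expect_lt(abs(mean(sim$matrix$cells == "?") - 0.1285), 0.05)
})

test_that("parsimony steps never exceed the true change counts", {
  for (seed in 1:3) {
    sim <- simulate_matrix(sim_config(n_taxa = 8, n_characters = 30,
                                      dependency_fraction = 0.4,
                                      state_change_rate = 2,
                                      rng_seed = seed))
    sc <- make_scorer(sim$matrix, sim$graph, use_composites = TRUE)
    rp <- sc$report(sim$ledger$true_tree)
    # independent characters: Fitch steps <= exact change count
    singles <- setdiff(seq_len(30), unlist(sim$ledger$complexes))
    for (j in singles) {
      row <- match(paste0("char", j), rp$unit)
      if (!is.na(row)) {
        expect_lte(rp$steps[row], sim$ledger$change_counts[j])
      }
    }
    # composites: weighted cost <= weighted sum of member changes
    for (cx in sim$ledger$complexes) {
      row <- grep(paste0("complex\\{", cx[1], ","), rp$unit)
      expect_lte(rp$steps[row],
                 sum(sim$ledger$change_counts[cx]) *
                   sim$matrix$characters$weight[cx[1]])
    }
  }
})

test_that("zero rate and zero missing give an all-constant matrix", {
  sim <- simulate_matrix(sim_config(n_taxa = 6, n_characters = 8,
                                    dependency_fraction = 0,
                                    missing_fraction = 0,
                                    state_change_rate = 0, rng_seed = 1))
  expect_true(all(apply(sim$matrix$cells, 2,
                        function(col) length(unique(col)) == 1L)))
  expect_equal(make_scorer(sim$matrix)$total(sim$ledger$true_tree), 0)
})

test_that("per-taxon missing skew raises that taxon's missing share", {
  sim <- simulate_matrix(sim_config(
    n_taxa = 8, n_characters = 40, dependency_fraction = 0,
    missing_fraction = 0.1, taxon_missing_skew = c(t03 = 0.3),
    rng_seed = 6))
  frac <- rowMeans(sim$matrix$cells == "?")
  expect_gt(frac[["t03"]], max(frac[setdiff(names(frac), "t03")]))
})

test_that("the tail/colour fixture shows the inapplicable artifact", {
  fx <- maddison_fixture()
  comp <- build_composite(1:2, fx$matrix, fx$graph)
  ta <- fx$topologies[[1]]
  tb <- fx$topologies[[2]]
  # composite scoring ties the two candidate two-origin topologies
  expect_equal(sankoff_cost(ta, comp), sankoff_cost(tb, comp))
  # inapplicable-as-missing scoring separates them
  missing_mode <- make_scorer(fx$matrix)
  expect_false(missing_mode$total(ta) == missing_mode$total(tb))
  # both imply two independent origins of the tail
  tails <- stats::setNames(fx$matrix$cells[, 1], fx$matrix$taxa)
  expect_equal(fitch_steps(ta, tails), 2L)
  expect_equal(fitch_steps(tb, tails), 2L)
  # scoring is dependency-consistent
  expect_equal(nrow(validate_and_autoscore(fx$matrix, fx$graph,
                                           "report")), 0L)
  # neutrality: every colour assignment ties the topologies
  for (bits in 0:15) {
    cols <- as.character(bitwAnd(bitwShiftR(bits, 0:3), 1L))
    m2 <- fx$matrix
    m2$cells[c("A", "B", "C", "D"), 2] <- cols
    comp2 <- build_composite(1:2, m2, fx$graph)
    expect_equal(sankoff_cost(ta, comp2), sankoff_cost(tb, comp2))
  }
})

test_that("the uniramous-pleopod fixture exposes forbidden optimizations", {
  fx <- uniramy_fixture()
  for (v in c("exopod_present", "endopod_present", "both_missing")) {
    expect_equal(nrow(validate_and_autoscore(fx[[v]], fx$graph,
                                             "report")), 0L)
  }
  trees <- list(
    tree_from_newick(
      "(((uniramous,biramA),(biramB,biramC)),endoOnly,outgrp);"),
    tree_from_newick(
      "(((biramA,biramB),(biramC,uniramous)),endoOnly,outgrp);"))
  endo_of <- function(m, tr) {
    comp <- build_composite(1:4, m, fx$graph)
    idx <- optimal_leaf_assignments(tr, comp, fx$uniramous)
    comp$states[idx, 1]
  }
  exo_of <- function(m, tr) {
    comp <- build_composite(5:9, m, fx$graph)
    idx <- optimal_leaf_assignments(tr, comp, fx$uniramous)
    comp$states[idx, 1]
  }
  # both-missing admits an optimization with BOTH rami present
  flagged <- vapply(trees, function(tr) {
    any(endo_of(fx$both_missing, tr) == 1, na.rm = TRUE) &&
      any(exo_of(fx$both_missing, tr) == 1, na.rm = TRUE)
  }, TRUE)
  expect_true(any(flagged))
  # the adopted scoring never reconstructs an endopod for that taxon
  for (tr in trees) {
    expect_true(all(endo_of(fx$exopod_present, tr) == 0, na.rm = TRUE))
  }
})
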