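# clean matrix whose characters are exactly the bipartitions of a known
# tree (doubled): the unique optimum is that tree, at a known score
clean_case <- function(nwk = "(((A,B),(C,D)),(E,F),G);") {
  true <- tree_from_newick(nwk)
  taxa <- sort(true$tip.label)
  bips <- tree_bipartitions(true)
  cells <- vapply(bips, function(k) {
    side <- strsplit(k, "|", fixed = TRUE)[[1]]
    ifelse(taxa %in% side, "1", "0")
  }, character(length(taxa)))
  cells <- cbind(cells, cells)
  rownames(cells) <- taxa
  list(true = true, m = char_matrix(taxa, cells),
       min_total = 2 * length(bips))
}

test_that("random addition is seeded, deterministic and greedy", {
  cs <- clean_case()
  sc <- make_scorer(cs$m)
  t1 <- random_addition_tree(cs$m, sc, seed = 5)
  t2 <- random_addition_tree(cs$m, sc, seed = 5)
  expect_identical(canonical_key(t1), canonical_key(t2))
  t3 <- random_addition_tree(cs$m, sc, seed = 6)
  expect_setequal(t3$tip.label, cs$m$taxa)
  # on a clean matrix the greedy insertion already attains the optimum
  expect_equal(sc$total(t1), cs$min_total)
  small <- char_matrix(c("A", "B", "C"), matrix("0", 3, 2))
  expect_error(random_addition_tree(small, sc), "4 taxa")
})

test_that("branch swapping reaches the exhaustive optimum on 6 taxa", {
  sim <- simulate_matrix(sim_config(n_taxa = 6, n_characters = 14,
                                    dependency_fraction = 0,
                                    state_change_rate = 2, rng_seed = 8))
  sc <- make_scorer(sim$matrix)
  all105 <- all_topologies(sim$matrix$taxa)
  best_exhaustive <- min(vapply(all105, sc$total, 1))
  start <- rand_tree(sim$matrix$taxa, 3)
  res_tbr <- swap_to_local_optimum(start, sc, "TBR")
  expect_equal(res_tbr$score, best_exhaustive)
  # neighbourhood nesting: NNI local optima are never better than SPR/TBR
  res_nni <- swap_to_local_optimum(start, sc, "NNI")
  res_spr <- swap_to_local_optimum(start, sc, "SPR")
  expect_gte(res_nni$score, res_spr$score)
  expect_gte(res_spr$score, res_tbr$score)
  # already-optimal input is returned unchanged
  again <- swap_to_local_optimum(res_tbr$trees[[1]], sc, "TBR")
  expect_equal(again$score, best_exhaustive)
  expect_true(canonical_key(res_tbr$trees[[1]]) %in%
                vapply(again$trees, canonical_key, ""))
})

test_that("ratchet is reproducible and keeps the best score", {
  sim <- simulate_matrix(sim_config(n_taxa = 7, n_characters = 16,
                                    state_change_rate = 2, rng_seed = 9))
  sc <- make_scorer(sim$matrix)
  start <- rand_tree(sim$matrix$taxa, 4)
  r0 <- ratchet(start, sim$matrix, iterations = 0)
  expect_identical(canonical_key(r0$trees[[1]]),
                   canonical_key(canonical_tree(start)))
  r1 <- ratchet(start, sim$matrix, iterations = 3, seed = 2)
  r2 <- ratchet(start, sim$matrix, iterations = 3, seed = 2)
  expect_equal(r1$score, r2$score)
  expect_identical(sort(vapply(r1$trees, canonical_key, "")),
                   sort(vapply(r2$trees, canonical_key, "")))
  expect_lte(r1$score, sc$total(start))
})

test_that("multistart search returns all tied optima and stops on hits", {
  cs <- clean_case()
  res <- multistart_search(cs$m, config = search_config(
    replicates = 3, hits_required = 2, rng_seed = 1))
  expect_equal(res$score, cs$min_total)
  expect_length(res$trees, 1L)
  expect_identical(canonical_key(res$trees[[1]]), canonical_key(cs$true))

  # a deliberate two-island case: equal support for two conflicting
  # groupings of a quartet -> both topologies are optimal
  taxa <- c("A", "B", "C", "D", "E")
  cells <- rbind(A = c("1", "1"), B = c("1", "0"), C = c("0", "1"),
                 D = c("0", "0"), E = c("0", "0"))
  m2 <- char_matrix(taxa, cells)
  sc2 <- make_scorer(m2)
  all15 <- all_topologies(taxa)
  scores <- vapply(all15, sc2$total, 1)
  tied <- vapply(all15[scores == min(scores)], canonical_key, "")
  res2 <- multistart_search(m2, config = search_config(
    replicates = 6, hits_required = 6, rng_seed = 2,
    collapse_rule = "none"))
  expect_setequal(vapply(res2$trees, canonical_key, ""), tied)
  # search never returns a tree worse than the optimum it reports
  expect_true(all(vapply(res2$trees, sc2$total, 1) == res2$score))
})

test_that("search equals exhaustive enumeration on small synthetic cases", {
  for (seed in 1:3) {
    sim <- simulate_matrix(sim_config(n_taxa = 6, n_characters = 12,
                                      dependency_fraction = 0.4,
                                      state_change_rate = 1.5,
                                      rng_seed = 20 + seed))
    sc <- make_scorer(sim$matrix, sim$graph, use_composites = TRUE)
    best <- min(vapply(all_topologies(sim$matrix$taxa), sc$total, 1))
    res <- multistart_search(sim$matrix, sim$graph,
                             config = search_config(replicates = 2,
                                                    hits_required = 1,
                                                    rng_seed = seed),
                             use_composites = TRUE, scorer = sc)
    expect_equal(res$score, best)
  }
})

test_that("the tree collection deduplicates and reaches closure", {
  cs <- clean_case()
  sc <- make_scorer(cs$m)
  col <- tree_collection()
  trs <- list(cs$true, rand_tree(cs$m$taxa, 1), rand_tree(cs$m$taxa, 2))
  trs <- trs[!duplicated(vapply(trs, canonical_key, ""))]
  up <- update_tree_collection(col, trs, sc, "a", cross_check = FALSE)
  expect_equal(up$added, length(trs))
  up2 <- update_tree_collection(up$collection, trs, sc, "b",
                                cross_check = FALSE)
  expect_equal(up2$added, 0L)
  # closure: repeated cross-checked updates stop adding trees
  col2 <- up2$collection
  for (pass in 1:5) {
    out <- update_tree_collection(col2, list(), sc, "a")
    col2 <- out$collection
    if (out$added == 0L) break
  }
  expect_equal(out$added, 0L)
  expect_lte(pass, 5L)
})

test_that("strict consensus keeps exactly the shared bipartitions", {
  t1 <- tree_from_newick("(((A,B),C),(D,E),F);")
  expect_identical(canonical_key(strict_consensus(list(t1))),
                   canonical_key(t1))
  t2 <- tree_from_newick("((A,D),(B,E),(C,F));")
  expect_length(intersect(oracle_bipartitions(t1),
                          oracle_bipartitions(t2)), 0L)
  star <- strict_consensus(list(t1, t2))
  expect_length(tree_bipartitions(star), 0L)
  # planted shared subtree: consensus = intersection of bipartitions
  trees <- lapply(1:4, function(s) {
    set.seed(s)
    base <- ape::rtree(4, rooted = FALSE,
                       tip.label = sample(c("W", "X", "Y", "Z")))
    nw <- sub("W", "(A,(B,C))", ape::write.tree(base), fixed = TRUE)
    tree_from_newick(nw)
  })
  cons <- strict_consensus(trees)
  shared <- Reduce(intersect, lapply(trees, oracle_bipartitions))
  expect_setequal(tree_bipartitions(cons), shared)
  expect_error(strict_consensus(list(t1, tree_from_newick("((A,B),(C,D));"))),
               "mismatch")
})

test_that("bootstrap support reflects character agreement", {
  taxa <- c("A", "B", "C", "D", "E")
  cells <- matrix(rep(c("1", "1", "0", "0", "0"), 6), 5, 6,
                  dimnames = list(taxa, NULL))
  m <- char_matrix(taxa, cells)
  bs <- bootstrap_support(m, pseudo_replicates = 20, seed = 3)
  # the A,B grouping is keyed by the side without the smallest label
  expect_equal(unname(bs[["C|D|E"]]), 100)
  bs2 <- bootstrap_support(m, pseudo_replicates = 20, seed = 3)
  expect_identical(bs, bs2)
  m0 <- char_matrix(taxa, matrix("0", 5, 4))
  bs0 <- bootstrap_support(m0, pseudo_replicates = 5, seed = 1)
  expect_true(length(bs0) == 0 || all(names(bs0) == ""))
})

test_that("zero-minimum-length branches are collapsed before dedup", {
  # an edge with no character support collapses; a supported edge stays
  taxa <- c("A", "B", "C", "D", "E")
  cells <- matrix(c("1", "1", "0", "0", "0"), 5, 2,
                  dimnames = list(taxa, NULL))
  m <- char_matrix(taxa, cells)
  sc <- make_scorer(m)
  tr <- tree_from_newick("(((A,B),C),D,E);")  # the ABC|DE edge unsupported
  col <- collapse_zero_length(tr, sc)
  expect_equal(tree_bipartitions(col), "C|D|E")  # the A,B split survives
})
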