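mk_matrix <- function(n_chars, statements, states, cells, taxa = NULL) {
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(cells)))
  chars <- data.frame(row = seq_len(n_chars))
  chars$statement <- statements
  chars$states <- states
  char_matrix(taxa, cells, chars)
}

test_that("complexes are the connected components of the dependency relation", {
  m <- mk_matrix(5, c("A", "[1.1>this]B", "[1.1>this]C", "D", "E"),
                 rep(list(0:1), 5), matrix("0", 2, 5))
  g <- build_dependency_graph(m)
  cpx <- find_complexes(g, 5)
  expect_equal(cpx, list(c(1L, 2L, 3L), 4L, 5L))
  g0 <- build_dependency_graph(mk_matrix(3, c("A", "B", "C"),
                                         rep(list(0:1), 3),
                                         matrix("0", 2, 3)))
  expect_equal(find_complexes(g0, 3), list(1L, 2L, 3L))
})

test_that("tuple enumeration respects dependency consistency", {
  # tail/colour: absent blanks the colour -> 3 of 4 raw combinations
  fx <- maddison_fixture()
  st <- enumerate_states(1:2, fx$matrix, fx$graph)
  expect_equal(nrow(st), 3L)
  expect_equal(st[1, ], c("1" = 0L, "2" = NA_integer_))
  # shared controller blanking two binary dependents: 1 + 2*2 = 5 of 8
  m <- mk_matrix(3, c("Ctrl", "[1.1>this]X", "[1.1>this]Y"),
                 rep(list(0:1), 3), matrix("0", 2, 3))
  g <- build_dependency_graph(m)
  expect_equal(nrow(enumerate_states(1:3, m, g)), 5L)
  # brute-force cross-check: consistent = controller 0 implies both NA
  raw <- expand.grid(c(0:1), c(0:1, NA), c(0:1, NA))
  ok <- sum(apply(raw, 1, function(r) {
    if (r[1] == 0) is.na(r[2]) && is.na(r[3]) else
      !is.na(r[2]) && !is.na(r[3])
  }))
  expect_equal(nrow(enumerate_states(1:3, m, g)), ok)
})

test_that("streak-constrained serial block enumerates contiguous runs", {
  n <- 7L
  m <- mk_matrix(n, sprintf("Pos %d", 1:n), rep(list(0:1), n),
                 matrix("0", 2, n))
  g <- build_dependency_graph(
    m, serial_blocks = list(serial_block(1:n, streak = TRUE)))
  st <- enumerate_states(1:n, m, g)
  expect_equal(nrow(st), n * (n + 1) / 2 + 1)  # runs + empty = 29
  # and the state-space cap triggers with advice
  g2 <- build_dependency_graph(
    m, serial_blocks = list(serial_block(1:n, streak = FALSE)))
  expect_error(enumerate_states(1:n, m, g2, cap = 100L), "cap")
})

test_that("cost matrices follow the charging rules and stay metric", {
  fx <- maddison_fixture()
  comp <- build_composite(1:2, fx$matrix, fx$graph)
  # (absent,-) , (present,red), (present,blue): all transitions cost 1;
  # the dependent's state instantiation at gain is free
  expect_equal(comp$cost, matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))

  # serial block, weight 10, discount 1/10: empty -> full 7-streak
  n <- 7L
  cells <- rbind(a = rep("0", n), b = rep("1", n))
  chars <- data.frame(row = 1:n)
  chars$statement <- sprintf("Pos %d", 1:n)
  chars$states <- rep(list(0:1), n)
  chars$weight <- 10
  m <- char_matrix(c("a", "b"), cells, chars)
  blk <- serial_block(1:n, streak = TRUE)
  g <- build_dependency_graph(m, serial_blocks = list(blk))
  comp7 <- build_composite(1:n, m, g)
  i_empty <- which(apply(comp7$states, 1, function(r) all(r == 0L)))
  i_full <- which(apply(comp7$states, 1, function(r) all(r == 1L)))
  expect_equal(comp7$cost[i_empty, i_full], 10 * (1 + 6 / 10))  # 16
  # single-position change costs the full weight
  i_one <- which(apply(comp7$states, 1, function(r) {
    sum(r) == 1L && r[1] == 1L
  }))
  expect_equal(comp7$cost[i_empty, i_one], 10)
})

test_that("a degenerate one-character complex reproduces Fitch costs", {
  m <- mk_matrix(1, "Solo", list(0:2), matrix(c("0", "1", "2"), 3, 1))
  g <- build_dependency_graph(m)
  comp <- build_composite(1L, m, g)
  expect_equal(comp$cost, 1 - diag(3))
  tr <- tree_from_newick("((t1,t2),(t3,t1b));")
  m2 <- mk_matrix(1, "Solo", list(0:1),
                  matrix(c("0", "0", "1", "1"), 4, 1),
                  taxa = c("t1", "t2", "t3", "t1b"))
  comp2 <- build_composite(1L, m2, build_dependency_graph(m2))
  expect_equal(sankoff_cost(tr, comp2),
               fitch_steps(tr, stats::setNames(m2$cells[, 1], m2$taxa)))
})

test_that("generated cost matrices are symmetric, zero-diagonal, metric", {
  for (seed in 1:4) {
    sim <- simulate_matrix(sim_config(n_taxa = 6, n_characters = 15,
                                      dependency_fraction = 0.6,
                                      rng_seed = seed))
    built <- build_composites(sim$matrix, sim$graph)
    for (comp in built$composites) {
      cc <- comp$cost
      expect_equal(cc, t(cc))
      expect_true(all(diag(cc) == 0))
      for (i in seq_len(nrow(cc))) {   # triangle via every midpoint i
        expect_true(all(outer(cc[, i], cc[i, ], `+`) >= cc - 1e-9))
      }
    }
  }
})

test_that("streak restriction leaves scores unchanged when patterns are contiguous", {
  # observed patterns all contiguous; optima need no disrupted ancestors
  cells <- rbind(a = c("1", "1", "0", "0"), b = c("1", "1", "1", "0"),
                 c = c("0", "1", "1", "1"), d = c("0", "0", "1", "1"))
  chars <- data.frame(row = 1:4)
  chars$statement <- sprintf("Pos %d", 1:4)
  chars$states <- rep(list(0:1), 4)
  m <- char_matrix(rownames(cells), cells, chars)
  g_streak <- build_dependency_graph(
    m, serial_blocks = list(serial_block(1:4, streak = TRUE)))
  g_free <- build_dependency_graph(
    m, serial_blocks = list(serial_block(1:4, streak = FALSE)))
  c_streak <- build_composite(1:4, m, g_streak)
  c_free <- build_composite(1:4, m, g_free)
  for (tr in all_topologies(rownames(cells))) {
    expect_equal(sankoff_cost(tr, c_streak), sankoff_cost(tr, c_free))
  }
})
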