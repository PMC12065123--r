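test_that("annotation tokens parse to links and render back", {
  l <- parse_dependency_annotation(
    "[98.1>this]Pleopod ramus shape: (0) flat, (1) round",
    self_index = 99L, n_characters = 207L)
  expect_length(l, 1L)
  expect_equal(l[[1]]$controller, 98L)
  expect_equal(l[[1]]$enabling, 1L)
  expect_equal(l[[1]]$dependent, 99L)
  expect_null(l[[1]]$dependent_states)

  expect_length(parse_dependency_annotation(
    "Carapace: (0) absent, (1) present", 5L), 0L)
  expect_error(parse_dependency_annotation(
    "[999.1>this]x", 5L, n_characters = 207L), "999")
  expect_error(parse_dependency_annotation("[garbage]x", 5L), "garbage")

  # multiple tokens, multi-state enabling, single-state dependency
  l2 <- parse_dependency_annotation("[3.1,2>this][7.0>this.2]stmt", 9L)
  expect_length(l2, 2L)
  expect_equal(l2[[1]]$enabling, c(1L, 2L))
  expect_equal(l2[[2]]$dependent_states, 2L)
})

test_that("render-parse identity holds for generated link lists", {
  set.seed(7)
  for (i in 1:20) {
    links <- lapply(seq_len(sample(1:4, 1)), function(j) {
      dep_link(sample(setdiff(1:30, 9), 1), sample(0:3, sample(1:2, 1)),
               9L,
               if (runif(1) < 0.3) sample(0:3, 1) else NULL)
    })
    txt <- render_dependency_annotation(links)
    back <- parse_dependency_annotation(paste0(txt, "Statement"), 9L)
    expect_equal(back, links)
  }
})

test_that("graph building validates structure and counts participants", {
  cells <- matrix("0", 3, 5)
  cells[1, ] <- "1"
  chars <- data.frame(row = 1:5)
  chars$statement <- c("A: (0)/(1)", "[1.1>this]B", "[2.1>this]C",
                       "D", "E")
  chars$states <- rep(list(0:1), 5)
  m <- char_matrix(c("t1", "t2", "t3"), cells, chars)
  g <- build_dependency_graph(m)
  expect_length(g$links, 2L)
  expect_equal(participating_characters(g), 1:3)
  expect_equal(attr(g, "participating"), 3L)

  # a cycle is rejected with the offending characters named
  chars2 <- chars
  chars2$statement[1] <- "[3.1>this]A"
  m2 <- char_matrix(c("t1", "t2", "t3"), cells, chars2)
  expect_error(build_dependency_graph(m2), "cycle")

  # overlapping serial blocks with conflicting membership are rejected
  expect_error(build_dependency_graph(
    m, serial_blocks = list(serial_block(4:5), serial_block(c(5, 3)))),
    "overlap")
})

test_that("generated complexes match the generator's ledger", {
  sim <- simulate_matrix(sim_config(n_taxa = 8, n_characters = 30,
                                    dependency_fraction = 0.5,
                                    rng_seed = 4))
  expect_setequal(sim$ledger$participating,
                  sort(unique(unlist(sim$ledger$complexes))))
  expect_equal(attr(sim$graph, "participating"),
               length(sim$ledger$participating))
})

test_that("violations are detected and enforcement is idempotent", {
  cells <- rbind(t1 = c("0", "1"),   # controller absent, dependent scored
                 t2 = c("?", "1"),   # controller missing: undecidable
                 t3 = c("1", "-"),   # controller enabling, dependent inapp
                 t4 = c("1", "0"))
  chars <- data.frame(row = 1:2)
  chars$statement <- c("Ctrl: (0) absent, (1) present", "[1.1>this]Dep")
  chars$states <- rep(list(0:1), 2)
  m <- char_matrix(rownames(cells), cells, chars)
  g <- build_dependency_graph(m)
  rep0 <- validate_and_autoscore(m, g, "report")
  expect_equal(sort(rep0$kind),
               sort(c("state_under_disabled_controller",
                      "inapplicable_under_enabled_controllers")))
  expect_equal(rep0$taxon[rep0$kind == "state_under_disabled_controller"],
               "t1")
  fixed <- validate_and_autoscore(m, g, "enforce")
  expect_equal(unname(fixed$cells["t1", 2]), "-")
  expect_equal(unname(fixed$cells["t2", 2]), "1")  # missing ctrl untouched
  rep1 <- validate_and_autoscore(fixed, g, "report")
  expect_false("state_under_disabled_controller" %in% rep1$kind)
  # idempotence, and controllers/non-dependents never altered
  fixed2 <- validate_and_autoscore(fixed, g, "enforce")
  expect_identical(fixed2$cells, fixed$cells)
  expect_identical(fixed$cells[, 1], m$cells[, 1])
})

test_that("consistent synthetic matrices report no violations", {
  for (seed in 1:3) {
    sim <- simulate_matrix(sim_config(n_taxa = 8, n_characters = 24,
                                      dependency_fraction = 0.5,
                                      rng_seed = seed))
    expect_equal(nrow(validate_and_autoscore(sim$matrix, sim$graph,
                                             "report")), 0L)
  }
})

test_that("xlinks command emission groups links deterministically", {
  m <- char_matrix(c("a", "b"), matrix("0", 2, 6),
                   characters = data.frame(row = 1:6) |>
                     (\(d) {d$states <- rep(list(0:1), 6); d})())
  g <- build_dependency_graph(m, extra_links = list(
    dep_link(1, 1, 3), dep_link(1, 1, 2), dep_link(4, 0, 5, 1)),
    serial_blocks = list(serial_block(c(5, 6), streak = TRUE)))
  cmds <- emit_xlink_commands(g)
  expect_length(cmds, 3L)  # one grouped + one single-state + one serial
  expect_match(cmds[1], "^xlinks = 0\\.1 > 1 2$")   # 0-based default
  expect_match(cmds[2], "^xlinks = 3\\.0 > 4\\.1$")
  expect_match(cmds[3], "^xlinks \\* = 4 5 streak$")
  # 1-based rendering via template
  cmds1 <- emit_xlink_commands(g, template = list(numbering_base = 1L))
  expect_match(cmds1[1], "^xlinks = 1\\.1 > 2 3$")
  expect_identical(emit_xlink_commands(
    build_dependency_graph(m)), character(0))
})
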