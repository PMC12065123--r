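# The k-browsing pipeline: per dataset an equal-weights search, an
# implied-weighting search per requested k, and one at the automatically
# derived sk; a shared deduplicated tree collection with TBR cross-check
# looping until closure; and a final all-analysis nRF comparison with
# congruence-based selection.

#' Pipeline configuration
#'
#' @param datasets named list; each element either a TNT file path or a
#'   list with components `matrix` (a [char_matrix()]), optional `graph`
#'   (a `dep_graph`; built from statement annotations when absent) and
#'   `use_composites` (flag: score dependency complexes as composites).
#' @param k_values implied-weighting concavity constants to sweep
#'   (default 1..25).
#' @param ratio_N maximum weight ratio for the automatic sk (default 15).
#' @param search_traditional [search_config()] for analyses without
#'   composites.
#' @param search_composite [search_config()] for composite analyses
#'   (conventionally lighter, composites being costlier to score).
#' @param bootstrap_replicates named vector: pseudo-replicates for
#'   analyses without (`traditional`, default 1500) and with composites
#'   (`composite`, default 100).
#' @param run_bootstrap actually run the bootstrap per analysis (off by
#'   default: it dominates runtime; the replicate defaults above are
#'   used when on).
#' @param output_dir directory for MPT/consensus/distance files, or
#'   `NULL` to skip writing.
#' @param seed master seed; every stochastic stage derives from it.
#' @param max_closure_passes safety bound on the cross-check loop.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(datasets,
                            k_values = 1:25,
                            ratio_N = 15,
                            search_traditional =
                              search_config(replicates = 5L,
                                            hits_required = 2L),
                            search_composite =
                              search_config(replicates = 2L,
                                            hits_required = 1L),
                            bootstrap_replicates =
                              c(traditional = 1500L, composite = 100L),
                            run_bootstrap = FALSE,
                            output_dir = NULL,
                            seed = 1L,
                            max_closure_passes = 10L) {
  if (!length(datasets)) stop("datasets must be non-empty")
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    stop("datasets must be a named list")
  }
  if (any(k_values <= 0)) stop("k_values must be positive")
  structure(list(datasets = datasets, k_values = k_values,
                 ratio_N = ratio_N,
                 search_traditional = search_traditional,
                 search_composite = search_composite,
                 bootstrap_replicates = bootstrap_replicates,
                 run_bootstrap = isTRUE(run_bootstrap),
                 output_dir = output_dir, seed = as.integer(seed),
                 max_closure_passes = as.integer(max_closure_passes)),
            class = "pipeline_config")
}

#' Stable analysis label
#'
#' `"<dataset>:EW"`, `"<dataset>:IWk<k>"` or `"<dataset>:IWsk<k>"`, with
#' the realized automatic k embedded to six decimals.
#'
#' @param dataset dataset name.
#' @param scheme `"EW"`, `"IW"` or `"IWsk"`.
#' @param k concavity constant (IW only).
#' @return character scalar.
#' @export
analysis_label <- function(dataset, scheme, k = NULL) {
  switch(scheme,
         EW = paste0(dataset, ":EW"),
         IW = sprintf("%s:IWk%s", dataset, format(k, scientific = FALSE)),
         IWsk = sprintf("%s:IWsk%.6f", dataset, k),
         stop("unknown scheme '", scheme, "'"))
}

load_dataset <- function(ds) {
  if (is.character(ds)) {
    m <- read_tnt_matrix(ds)
    list(matrix = m, graph = build_dependency_graph(m),
         use_composites = TRUE)
  } else {
    if (is.null(ds$graph) && isTRUE(ds$use_composites)) {
      ds$graph <- build_dependency_graph(ds$matrix)
    }
    if (is.null(ds$use_composites)) ds$use_composites <- !is.null(ds$graph)
    ds
  }
}

#' Run the full k-browsing pipeline
#'
#' Per dataset: an equal-weights search, an implied-weighting search for
#' every requested k, and one at the automatically derived sk (measured
#' on the best equal-weights trees of that dataset). Every analysis
#' inserts its most parsimonious trees into a shared deduplicated tree
#' collection. After all analyses, TBR-only cross-check passes reseed
#' each analysis from the collection (re-scoring all stored trees under
#' its scheme) until a full pass adds no tree; analyses whose best score
#' improves, or whose tree set grows, are updated. Finally all distinct
#' MPTs enter a labelled nRF distance matrix and the congruence-based
#' selection anchored on the sk analyses.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest: list with `analyses` (data frame: label,
#'   dataset, scheme, k, score, n_mpt, seed, files), `mpts` (named list
#'   of tree lists), `collection`, `distance` (an `nrf_dist`),
#'   `congruent` (result of [select_congruent_mpts()], when at least two
#'   analyses exist), `closure_passes`, and `errors`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$output_dir
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    unlink(file.path(outdir, "run_log.jsonl"))
  }
  col <- tree_collection()
  analyses <- list()   # per label: list(scorer, result, meta)
  errors <- list()
  aseed <- config$seed

  for (ds_name in names(config$datasets)) {
    ds <- load_dataset(config$datasets[[ds_name]])
    cfg_search <- if (ds$use_composites) config$search_composite else
      config$search_traditional
    schemes <- c(list(list(scheme = "EW", k = NULL)),
                 lapply(config$k_values, function(k) {
                   list(scheme = "IW", k = k)
                 }),
                 list(list(scheme = "IWsk", k = NA)))
    ew_trees <- NULL
    for (sch in schemes) {
      aseed <- aseed + 1L
      k <- sch$k
      if (identical(sch$scheme, "IWsk")) {
        k <- tryCatch({
          h_max <- dataset_h_max(ew_trees, ds$matrix, ds$graph,
                                 ds$use_composites)
          compute_sk(h_max, config$ratio_N)
        }, error = function(e) NA_real_)
        if (is.na(k)) {
          errors[[analysis_label(ds_name, "IWsk", 0)]] <-
            "sk underivable (dataset homoplasy-free or no EW trees)"
          next
        }
      }
      label <- analysis_label(ds_name, sch$scheme, k)
      wscheme <- if (sch$scheme == "EW") weighting_scheme("EW") else
        weighting_scheme("IW", k = k, ratio_N = config$ratio_N)
      res <- tryCatch({
        cfg_i <- cfg_search
        cfg_i$rng_seed <- aseed
        scorer <- make_scorer(ds$matrix, ds$graph, wscheme,
                              ds$use_composites)
        out <- multistart_search(ds$matrix, ds$graph, wscheme, cfg_i,
                                 ds$use_composites, scorer = scorer)
        list(scorer = scorer, trees = out$trees, score = out$score)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        errors[[label]] <- conditionMessage(res)
        next
      }
      if (sch$scheme == "EW") ew_trees <- res$trees
      up <- update_tree_collection(col, res$trees, res$scorer, label)
      col <- up$collection
      if (!is.null(outdir)) {
        cat(jsonlite::toJSON(list(
          event = "analysis", label = label, score = res$score,
          n_mpt = length(res$trees), seed = aseed,
          collection_added = up$added), auto_unbox = TRUE),
          "\n", sep = "",
          file = file.path(outdir, "run_log.jsonl"), append = TRUE)
      }
      analyses[[label]] <- list(
        scorer = res$scorer, trees = res$trees, score = res$score,
        dataset = ds_name, scheme = sch$scheme, k = k, seed = aseed,
        use_composites = ds$use_composites,
        matrix = ds$matrix, graph = ds$graph)
    }
  }

  # closure loop: TBR-only cross-checks reseeding every analysis from
  # the shared collection until a full pass adds nothing
  passes <- 0L
  repeat {
    passes <- passes + 1L
    added <- 0L
    for (label in names(analyses)) {
      a <- analyses[[label]]
      sc <- vapply(col$trees, a$scorer$total, 1)
      best <- min(c(sc, a$score))
      pool <- col$trees[sc <= best + .EPS]
      if (best < a$score - .EPS || length(pool) > length(a$trees)) {
        analyses[[label]]$trees <- dedup_by_collapse(
          if (best < a$score - .EPS) pool else c(a$trees, pool),
          a$scorer)
        analyses[[label]]$score <- best
      }
      up <- update_tree_collection(col, analyses[[label]]$trees,
                                   a$scorer, paste0(label, ":x"))
      added <- added + up$added
      col <- up$collection
    }
    if (added == 0L || passes >= config$max_closure_passes) break
  }

  # outputs and manifest
  rows <- list()
  mpts <- list()
  for (label in names(analyses)) {
    a <- analyses[[label]]
    mpts[[label]] <- a$trees
    mpt_file <- cons_file <- NA_character_
    if (!is.null(outdir)) {
      safe <- gsub("[^A-Za-z0-9._-]", "_", label)
      mpt_file <- file.path(outdir, paste0(safe, ".mpts.nwk"))
      write_trees(a$trees, mpt_file)
      cons_file <- file.path(outdir, paste0(safe, ".consensus.nwk"))
      cons <- strict_consensus(a$trees)
      if (config$run_bootstrap) {
        reps <- if (a$use_composites) {
          config$bootstrap_replicates[["composite"]]
        } else config$bootstrap_replicates[["traditional"]]
        bs <- bootstrap_support(a$matrix, a$graph, a$scorer$scheme,
                                pseudo_replicates = reps,
                                seed = a$seed + 500000L,
                                use_composites = a$use_composites)
        cons <- annotate_support(cons, bs)
      }
      ape::write.tree(cons, cons_file)
    }
    rows[[label]] <- data.frame(
      label = label, dataset = a$dataset, scheme = a$scheme,
      k = if (is.null(a$k)) NA_real_ else a$k,
      score = a$score, n_mpt = length(a$trees), seed = a$seed,
      mpt_file = mpt_file, consensus_file = cons_file,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  dist <- if (length(mpts)) distance_matrix(mpts) else NULL
  congruent <- NULL
  sk_labels <- grep(":IWsk", names(mpts), value = TRUE)
  if (length(sk_labels) && length(mpts) > length(sk_labels)) {
    congruent <- tryCatch(select_congruent_mpts(mpts, sk_labels),
                          error = function(e) NULL)
  }
  if (!is.null(outdir) && !is.null(dist)) {
    write_table(dist, file.path(outdir, "nrf_distances.csv"), "csv")
    write_table(dist, file.path(outdir, "nrf_heatmap.svg"), "svg-heatmap")
    jsonlite::write_json(
      list(analyses = manifest, closure_passes = passes,
           errors = errors),
      file.path(outdir, "manifest.json"), auto_unbox = TRUE,
      dataframe = "rows", digits = NA)
  }
  list(analyses = manifest, mpts = mpts, collection = col,
       distance = dist, congruent = congruent,
       closure_passes = passes, errors = errors)
}

# write bootstrap percentages onto matching consensus nodes
annotate_support <- function(cons, support) {
  bips <- tree_bipartitions(cons)
  cons$node.label <- rep("", cons$Nnode)
  labs <- sort(cons$tip.label)
  ref <- min(labs)
  pp <- ape::prop.part(cons)
  pl <- attr(pp, "labels")
  for (i in seq_along(pp)) {
    side <- pl[pp[[i]]]
    if (ref %in% side) side <- setdiff(labs, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) {
      cons$node.label[i] <- sprintf("%.0f", support[[key]])
    }
  }
  cons
}
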