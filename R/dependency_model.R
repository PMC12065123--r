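# Ontological character dependencies: annotation parsing, graph building,
# scoring validation/enforcement, and emission of xlinks-style commands.

#' Default dependency-annotation grammar
#'
#' Annotations sit at the beginning of a character statement, one bracketed
#' token per controlling character:
#' `[12.1>this]` - this character is applicable only when character 12
#' (1-based) shows state 1; several enabling states are comma-separated
#' (`[12.1,2>this]`); a single-state dependency restricts only listed
#' states of this character (`[12.1>this.3]`: state 3 unavailable unless
#' character 12 shows state 1). The grammar is configurable so that a
#' matrix using different delimiters can be read without editing it.
#'
#' @return list of grammar components (`open`, `close`, `arrow`, `self`).
#' @export
default_dep_grammar <- function() {
  list(open = "[", close = "]", arrow = ">", self = "this")
}

#' Construct a dependency link
#'
#' @param controller 1-based index of the controlling character.
#' @param enabling integer vector of controller states under which the
#'   dependent is applicable.
#' @param dependent 1-based index of the dependent character.
#' @param dependent_states integer vector of dependent states covered by a
#'   single-state dependency, or `NULL` for the whole character.
#' @return object of class `dep_link`.
#' @export
dep_link <- function(controller, enabling, dependent,
                     dependent_states = NULL) {
  if (controller == dependent) {
    stop("character ", controller, " cannot control itself")
  }
  if (!length(enabling)) stop("enabling state set must be non-empty")
  structure(list(controller = as.integer(controller),
                 enabling = sort(unique(as.integer(enabling))),
                 dependent = as.integer(dependent),
                 dependent_states =
                   if (is.null(dependent_states)) NULL
                   else sort(unique(as.integer(dependent_states)))),
            class = "dep_link")
}

#' Construct a serial-homologue block
#'
#' @param members 1-based character indices, ordered along the body axis
#'   (anterior-most first).
#' @param streak restrict joint transformation to contiguous runs of
#'   non-baseline states (no disrupted distribution patterns).
#' @param discount cost charged per additional member changing in the same
#'   transformation, as a fraction of the full member weight (default
#'   1/10: m concurrent changes cost `w * (1 + (m - 1)/10)`).
#' @return object of class `serial_block`.
#' @export
serial_block <- function(members, streak = FALSE, discount = 1 / 10) {
  members <- as.integer(members)
  if (anyDuplicated(members)) stop("serial block members must be distinct")
  if (length(members) < 2L) stop("a serial block needs at least 2 members")
  if (discount <= 0 || discount > 1) stop("discount must be in (0, 1]")
  structure(list(members = members, streak = isTRUE(streak),
                 discount = discount),
            class = "serial_block")
}

#' Parse dependency annotations from a character statement
#'
#' @param statement character statement text, optionally prefixed by
#'   annotation tokens (see [default_dep_grammar()]).
#' @param self_index 1-based index of the character carrying the statement
#'   (becomes the `dependent` of each returned link).
#' @param grammar grammar configuration.
#' @param n_characters if given, controller indices are checked against it.
#' @return list of [dep_link()] objects (empty for a plain statement).
#' @export
parse_dependency_annotation <- function(statement, self_index = NA_integer_,
                                        grammar = default_dep_grammar(),
                                        n_characters = NULL) {
  esc <- function(s) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", s)
  pat <- sprintf("^\\s*%s([^%s%s]*)%s", esc(grammar$open),
                 esc(grammar$open), esc(grammar$close), esc(grammar$close))
  links <- list()
  rest <- statement
  repeat {
    m <- regexec(pat, rest, perl = TRUE)[[1]]
    if (m[1] < 0) break
    token <- regmatches(rest, list(m))[[1]][2]
    rest <- sub(pat, "", rest, perl = TRUE)
    body <- sprintf(
      "^(\\d+)\\.(\\d+(?:,\\d+)*)\\s*%s\\s*%s(?:\\.(\\d+(?:,\\d+)*))?$",
      gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", grammar$arrow),
      grammar$self)
    g <- regexec(body, trimws(token), perl = TRUE)[[1]]
    if (g[1] < 0) stop("malformed dependency annotation token '",
                       token, "'")
    parts <- regmatches(trimws(token), list(g))[[1]]
    ctrl <- as.integer(parts[2])
    if (!is.null(n_characters) && (ctrl < 1L || ctrl > n_characters)) {
      stop("annotation references nonexistent character ", ctrl)
    }
    enabling <- as.integer(strsplit(parts[3], ",")[[1]])
    dep_states <- if (is.na(parts[4]) || !nzchar(parts[4])) NULL else
      as.integer(strsplit(parts[4], ",")[[1]])
    links[[length(links) + 1L]] <-
      dep_link(ctrl, enabling, self_index, dep_states)
  }
  links
}

#' Render dependency links back to annotation text
#'
#' Inverse of [parse_dependency_annotation()]: `parse(render(links))`
#' yields the same links.
#'
#' @param links list of [dep_link()] with a common `dependent`.
#' @param grammar grammar configuration.
#' @return character scalar (annotation prefix, no trailing space).
#' @export
render_dependency_annotation <- function(links,
                                         grammar = default_dep_grammar()) {
  paste(vapply(links, function(l) {
    suffix <- if (is.null(l$dependent_states)) "" else
      paste0(".", paste(l$dependent_states, collapse = ","))
    paste0(grammar$open, l$controller, ".",
           paste(l$enabling, collapse = ","), grammar$arrow,
           grammar$self, suffix, grammar$close)
  }, ""), collapse = "")
}

#' Build a validated dependency graph for a matrix
#'
#' Parses annotations from every character statement, merges structured
#' extra links (the manually transcribed single-state dependencies) and
#' serial-homologue blocks, and checks that the controller-to-dependent
#' relation is acyclic. A character may have several controllers;
#' applicability then requires all of them to be enabling.
#'
#' @param m a [char_matrix()].
#' @param extra_links list of [dep_link()], or a data frame with columns
#'   `controller`, `enabling` (comma-separated states), `dependent` and
#'   optionally `dependent_states`.
#' @param serial_blocks list of [serial_block()].
#' @param grammar annotation grammar.
#' @return object of class `dep_graph` with fields `links`,
#'   `serial_blocks` and attribute `participating` (count of characters
#'   involved in any link or block).
#' @export
build_dependency_graph <- function(m, extra_links = list(),
                                   serial_blocks = list(),
                                   grammar = default_dep_grammar()) {
  nch <- n_characters(m)
  links <- list()
  for (j in seq_len(nch)) {
    links <- c(links, parse_dependency_annotation(
      m$characters$statement[j], self_index = j, grammar = grammar,
      n_characters = nch))
  }
  if (is.data.frame(extra_links)) {
    extra_links <- lapply(seq_len(nrow(extra_links)), function(i) {
      row <- extra_links[i, ]
      ds <- if ("dependent_states" %in% names(row) &&
                !is.na(row$dependent_states) &&
                nzchar(as.character(row$dependent_states))) {
        as.integer(strsplit(as.character(row$dependent_states), ",")[[1]])
      } else NULL
      dep_link(row$controller,
               as.integer(strsplit(as.character(row$enabling), ",")[[1]]),
               row$dependent, ds)
    })
  }
  links <- c(links, extra_links)
  for (l in links) {
    if (l$dependent < 1L || l$dependent > nch ||
        l$controller < 1L || l$controller > nch) {
      stop("link references character outside 1..", nch)
    }
    ctrl_states <- m$characters$states[[l$controller]]
    if (!all(l$enabling %in% ctrl_states)) {
      stop("link enabling states ", paste(l$enabling, collapse = ","),
           " not all declared for character ", l$controller)
    }
  }
  check_serial_blocks(serial_blocks, m)
  g <- structure(list(links = links, serial_blocks = serial_blocks),
                 class = "dep_graph")
  check_acyclic(g, nch)
  attr(g, "participating") <- length(participating_characters(g))
  g
}

check_serial_blocks <- function(serial_blocks, m) {
  seen <- list()
  for (b in serial_blocks) {
    stopifnot(inherits(b, "serial_block"))
    if (any(b$members < 1L | b$members > n_characters(m))) {
      stop("serial block member outside the matrix")
    }
    sets <- m$characters$states[b$members]
    if (length(unique(lapply(sets, sort))) != 1L) {
      stop("serial block members must share one state-code set (members ",
           paste(b$members, collapse = ","), ")")
    }
    for (prev in seen) {
      shared <- intersect(prev$members, b$members)
      if (length(shared)) {
        stop("serial blocks overlap on character(s) ",
             paste(shared, collapse = ","))
      }
    }
    seen[[length(seen) + 1L]] <- b
  }
  invisible(TRUE)
}

check_acyclic <- function(g, nch) {
  if (!length(g$links)) return(invisible(TRUE))
  edges <- unlist(lapply(g$links, function(l) c(l$controller, l$dependent)))
  ig <- igraph::make_graph(edges, n = nch, directed = TRUE)
  if (!igraph::is_dag(ig)) {
    comp <- igraph::components(ig, mode = "strong")
    cyc <- which(comp$membership == which.max(comp$csize))
    stop("dependency cycle among characters: ",
         paste(cyc, collapse = " -> "))
  }
  invisible(TRUE)
}

#' Characters participating in any dependency link or serial block
#' @param g a `dep_graph`.
#' @return sorted integer vector of 1-based character indices.
#' @export
participating_characters <- function(g) {
  sort(unique(c(
    unlist(lapply(g$links, function(l) c(l$controller, l$dependent))),
    unlist(lapply(g$serial_blocks, function(b) b$members)))))
}

#' @export
print.dep_graph <- function(x, ...) {
  full <- sum(vapply(x$links, function(l) is.null(l$dependent_states), TRUE))
  cat("dep_graph:", length(x$links), "links (", full, "full-character,",
      length(x$links) - full, "single-state ),",
      length(x$serial_blocks), "serial blocks;",
      attr(x, "participating") %||% length(participating_characters(x)),
      "participating characters\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full-character links pointing at character j
controllers_of <- function(g, j) {
  Filter(function(l) l$dependent == j && is.null(l$dependent_states),
         g$links)
}

# is the controller cell definitely non-enabling? ("-" counts: an
# inapplicable controller cannot be in an enabling state)
definitely_nonenabling <- function(tok, enabling) {
  if (tok == "?") return(FALSE)
  if (tok == "-") return(TRUE)
  !any(token_states(tok) %in% enabling)
}

definitely_enabling <- function(tok, enabling) {
  if (tok %in% c("?", "-")) return(FALSE)
  all(token_states(tok) %in% enabling)
}

#' Validate scoring against a dependency graph, optionally enforcing it
#'
#' A violation is reported where (i) some controller is scored a definite
#' non-enabling state while the dependent carries an actual state, or
#' (ii) the dependent is inapplicable although every controller is
#' definitely enabling, or (iii) a single-state dependency's restricted
#' states are asserted while its controller disables them. Enforcement
#' rewrites dependent cells to inapplicable when any controller is
#' definitely non-enabling (missing controllers are never acted on) and
#' strips unavailable states from single-state dependents; it is
#' idempotent and never touches controller cells.
#'
#' @param m a [char_matrix()].
#' @param g a `dep_graph` over the same character space.
#' @param mode `"report"` returns the violation table; `"enforce"` returns
#'   the corrected matrix.
#' @return data frame of violations (taxon, character, controller, kind),
#'   or a corrected `char_matrix` when `mode = "enforce"`.
#' @export
validate_and_autoscore <- function(m, g, mode = c("report", "enforce")) {
  mode <- match.arg(mode)
  cells <- m$cells
  viol <- list()
  note <- function(i, j, ctrl, kind) {
    viol[[length(viol) + 1L]] <<- data.frame(
      taxon = m$taxa[i], character = j, controller = ctrl, kind = kind)
  }
  for (l in g$links) {
    j <- l$dependent
    for (i in seq_along(m$taxa)) {
      ctok <- cells[i, l$controller]
      dtok <- cells[i, j]
      if (is.null(l$dependent_states)) {
        if (definitely_nonenabling(ctok, l$enabling)) {
          if (!dtok %in% c("-", "?")) {
            note(i, j, l$controller, "state_under_disabled_controller")
          }
          if (mode == "enforce") cells[i, j] <- "-"
        }
      } else if (definitely_nonenabling(ctok, l$enabling) &&
                 !dtok %in% c("-", "?")) {
        st <- token_states(dtok)
        if (all(st %in% l$dependent_states)) {
          note(i, j, l$controller, "unavailable_state_asserted")
        }
        if (mode == "enforce") {
          left <- setdiff(st, l$dependent_states)
          cells[i, j] <- if (length(left)) states_to_token(left) else "-"
        }
      }
    }
  }
  # dependent-side check: inapplicable although all controllers enable
  for (j in seq_len(n_characters(m))) {
    ctl <- controllers_of(g, j)
    if (!length(ctl)) next
    for (i in seq_along(m$taxa)) {
      if (m$cells[i, j] != "-") next
      all_on <- all(vapply(ctl, function(l) {
        definitely_enabling(m$cells[i, l$controller], l$enabling)
      }, TRUE))
      if (all_on) note(i, j, ctl[[1]]$controller,
                       "inapplicable_under_enabled_controllers")
    }
  }
  report <- if (length(viol)) do.call(rbind, viol) else
    data.frame(taxon = character(), character = integer(),
               controller = integer(), kind = character())
  if (mode == "report") return(report)
  m$cells <- cells
  m
}

#' Emit xlinks-style command text for a dependency graph
#'
#' One command per controller/enabling-state group of full-character
#' links, one command per single-state link, and one starred command per
#' serial block; deterministic ordering (controller, then dependents).
#' Character numbers are rendered in the configured base (default 0-based,
#' following TNT's character numbering).
#'
#' @param g a `dep_graph`.
#' @param template list: `keyword` (default `"xlinks"`), `serial_keyword`
#'   (default `"xlinks *"`), `numbering_base` (0 or 1).
#' @return character vector of command strings (no trailing semicolons).
#' @export
emit_xlink_commands <- function(g, template = list()) {
  tpl <- utils::modifyList(
    list(keyword = "xlinks", serial_keyword = "xlinks *",
         numbering_base = 0L), template)
  off <- tpl$numbering_base - 1L
  out <- character(0)
  full <- Filter(function(l) is.null(l$dependent_states), g$links)
  if (length(full)) {
    grp_key <- vapply(full, function(l) {
      paste0(l$controller, ".", paste(l$enabling, collapse = ","))
    }, "")
    for (k in unique(grp_key[order(
      vapply(full, `[[`, 1L, "controller"), grp_key)])) {
      members <- full[grp_key == k]
      ctrl <- members[[1]]$controller + off
      enab <- paste(members[[1]]$enabling, collapse = ",")
      deps <- sort(vapply(members, `[[`, 1L, "dependent")) + off
      out <- c(out, sprintf("%s = %d.%s > %s", tpl$keyword, ctrl, enab,
                            paste(deps, collapse = " ")))
    }
  }
  single <- Filter(function(l) !is.null(l$dependent_states), g$links)
  ord <- order(vapply(single, `[[`, 1L, "controller"),
               vapply(single, `[[`, 1L, "dependent"))
  for (l in single[ord]) {
    out <- c(out, sprintf("%s = %d.%s > %d.%s", tpl$keyword,
                          l$controller + off,
                          paste(l$enabling, collapse = ","),
                          l$dependent + off,
                          paste(l$dependent_states, collapse = ",")))
  }
  for (b in g$serial_blocks) {
    out <- c(out, sprintf("%s = %s%s", tpl$serial_keyword,
                          paste(b$members + off, collapse = " "),
                          if (b$streak) " streak" else ""))
  }
  out
}

#' Read structured extra dependency links from a delimited file
#'
#' Expected columns: `controller`, `enabling` (comma-separated state
#' codes), `dependent`, optional `dependent_states`.
#'
#' @param path CSV/TSV file path.
#' @return data frame suitable for [build_dependency_graph()]'s
#'   `extra_links`.
#' @export
read_dep_links <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    colClasses = "character", stringsAsFactors = FALSE)
}
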