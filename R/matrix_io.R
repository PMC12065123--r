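#' Read a TNT-dialect (xread) character matrix
#'
#' Parses the `xread` dialect produced by common matrix editors (including
#' MorphoBank TNT exports): an optional quoted title, the declared character
#' and taxon counts (characters first, per TNT convention), data rows of
#' `0`–`9`, `-` (inapplicable), `?` (missing) and bracketed polymorphisms
#' (`[01]` or `(01)`), optionally interleaved (a taxon appearing again has
#' its row continued). Command blocks following the data (`cnames`, `ccode`,
#' `xlinks`, ...) are captured verbatim into `source_commands`; `ccode`
#' weight settings (`/w` followed by 0-based character ranges `a.b`) and
#' `cnames` statements are additionally interpreted.
#'
#' @param path_or_text path to a file, or a character scalar containing the
#'   matrix text itself (anything containing a newline is treated as text).
#' @param dialect_options list of dialect tweaks: `strip_quotes` (drop
#'   straight/curly quotation marks from names; default `TRUE`),
#'   `space_to_underscore` (normalize whitespace in quoted taxon labels to
#'   underscores; default `TRUE`).
#'
#' @return A [char_matrix()].
#' @export
read_tnt_matrix <- function(path_or_text, dialect_options = list()) {
  opts <- utils::modifyList(
    list(strip_quotes = TRUE, space_to_underscore = TRUE), dialect_options)
  txt <- if (length(path_or_text) == 1L && !grepl("\n", path_or_text) &&
             file.exists(path_or_text)) {
    paste(readLines(path_or_text, warn = FALSE), collapse = "\n")
  } else {
    paste(path_or_text, collapse = "\n")
  }
  pos <- regexpr("\\bxread\\b", txt)
  if (pos < 0) stop("no xread block found")
  body <- substring(txt, pos + attr(pos, "match.length"))
  # optional quoted title (may span lines)
  body <- sub("^\\s*'[^']*'", "", body)
  hdr <- regmatches(body, regexec("^\\s*(\\d+)\\s+(\\d+)", body))[[1]]
  if (length(hdr) != 3L) stop("xread header must declare NCHAR NTAX")
  nchar_m <- as.integer(hdr[2])
  ntax <- as.integer(hdr[3])
  body <- sub("^\\s*\\d+\\s+\\d+", "", body)
  semi <- find_unquoted(body, ";")
  if (is.na(semi)) stop("xread data block not terminated by ';'")
  data_part <- substring(body, 1, semi - 1L)
  rest <- substring(body, semi + 1L)

  rows <- parse_xread_rows(data_part, opts)
  taxa <- unique(vapply(rows, `[[`, "", "taxon"))
  if (length(taxa) != ntax) {
    stop("header declares ", ntax, " taxa but ", length(taxa), " found")
  }
  tokens <- stats::setNames(vector("list", length(taxa)), taxa)
  for (r in rows) {
    tokens[[r$taxon]] <- c(tokens[[r$taxon]], r$tokens)
  }
  nt <- vapply(tokens, length, 1L)
  if (any(nt != nchar_m)) {
    bad <- taxa[which(nt != nchar_m)[1]]
    stop("taxon '", bad, "' has ", nt[[bad]],
         " characters, header declares ", nchar_m)
  }
  cells <- do.call(rbind, tokens)

  cmds <- split_commands(rest)
  weights <- rep(1, nchar_m)
  statements <- NULL
  for (cmd in cmds) {
    if (grepl("^ccode\\b", cmd)) {
      weights <- apply_ccode_weights(cmd, weights)
    } else if (grepl("^cnames\\b", cmd)) {
      statements <- parse_cnames(cmd, nchar_m, opts)
    }
  }
  chars <- data.frame(row = seq_len(nchar_m))
  chars$weight <- weights
  if (!is.null(statements)) chars$statement <- statements
  char_matrix(taxa, cells, characters = chars, source_commands = cmds)
}

# first occurrence of `what` outside single quotes (NA if none)
find_unquoted <- function(s, what) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  inq <- FALSE
  for (i in seq_along(chars)) {
    if (chars[i] == "'") inq <- !inq
    else if (!inq && chars[i] == what) return(i)
  }
  NA_integer_
}

parse_xread_rows <- function(data_part, opts) {
  lines <- strsplit(data_part, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^&", lines)]  # skip interleave marks
  rows <- list()
  for (ln in lines) {
    if (grepl("^'", ln)) {  # quoted taxon label possibly containing spaces
      m <- regexec("^'([^']*)'\\s*(.*)$", ln)[[1]]
      label <- regmatches(ln, list(m))[[1]][2]
      seqtxt <- regmatches(ln, list(m))[[1]][3]
    } else {
      sp <- regexpr("\\s", ln)
      if (sp < 0) stop("malformed data row (no states): '", ln, "'")
      label <- substring(ln, 1, sp - 1L)
      seqtxt <- substring(ln, sp + 1L)
    }
    label <- clean_label(label, opts)
    rows[[length(rows) + 1L]] <-
      list(taxon = label, tokens = tokenize_states(seqtxt, label))
  }
  rows
}

clean_label <- function(label, opts) {
  if (isTRUE(opts$strip_quotes)) {
    label <- gsub("['\"‘’“”]", "", label)
  }
  if (isTRUE(opts$space_to_underscore)) label <- gsub("\\s+", "_", label)
  label
}

tokenize_states <- function(seqtxt, label) {
  chars <- strsplit(gsub("\\s", "", seqtxt), "", fixed = TRUE)[[1]]
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("[", "(")) {
      closing <- if (ch == "[") "]" else ")"
      j <- i + 1L
      while (j <= length(chars) && chars[j] != closing) j <- j + 1L
      if (j > length(chars)) {
        stop("unterminated polymorphism in row of '", label, "'")
      }
      poly <- chars[(i + 1L):(j - 1L)]
      if (length(poly) < 2L || !all(poly %in% as.character(0:9))) {
        stop("malformed polymorphism '",
             paste(chars[i:j], collapse = ""), "' in row of '", label, "'")
      }
      out <- c(out, states_to_token(as.integer(poly)))
      i <- j + 1L
    } else if (ch %in% c(as.character(0:9), "-", "?")) {
      out <- c(out, ch)
      i <- i + 1L
    } else {
      stop("unknown symbol '", ch, "' at position ", length(out) + 1L,
           " in row of '", label, "'")
    }
  }
  out
}

split_commands <- function(rest) {
  parts <- character(0)
  while (nzchar(trimws(rest))) {
    semi <- find_unquoted(rest, ";")
    if (is.na(semi)) {
      parts <- c(parts, trimws(rest))
      break
    }
    parts <- c(parts, trimws(substring(rest, 1, semi - 1L)))
    rest <- substring(rest, semi + 1L)
  }
  parts <- parts[nzchar(parts)]
  parts[!grepl("^proc\\s*[/-]?\\s*$", parts)]
}

# ccode weight clauses: "/w" sets the running weight, subsequent 0-based
# character numbers or a.b ranges receive it; other ccode flags (+ - [ ] *)
# are ignored here but kept verbatim in source_commands.
apply_ccode_weights <- function(cmd, weights) {
  body <- sub("^ccode\\b", "", cmd)
  toks <- strsplit(trimws(body), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  w <- NA_real_
  n <- length(weights)
  for (tk in toks) {
    if (grepl("^/", tk)) {
      w <- as.numeric(sub("^/", "", tk))
      if (!is.finite(w) || w <= 0) stop("bad ccode weight token '", tk, "'")
    } else if (grepl("^\\d+\\.\\d+$", tk)) {
      ab <- as.integer(strsplit(tk, ".", fixed = TRUE)[[1]])
      idx <- (ab[1]:ab[2]) + 1L
      if (any(idx < 1L | idx > n)) stop("ccode range '", tk, "' out of bounds")
      if (!is.na(w)) weights[idx] <- w
    } else if (grepl("^\\d+$", tk)) {
      idx <- as.integer(tk) + 1L
      if (idx < 1L || idx > n) stop("ccode index '", tk, "' out of bounds")
      if (!is.na(w)) weights[idx] <- w
    }
    # any other flag token: no weight effect
  }
  weights
}

parse_cnames <- function(cmd, nchar_m, opts) {
  body <- sub("^cnames\\b", "", cmd)
  statements <- rep(NA_character_, nchar_m)
  # entries of the form: { <0-based index> <name_with_underscores> <states...> ;
  pat <- gregexpr("\\{[^{}]*", body)[[1]]
  entries <- regmatches(body, list(pat))[[1]]
  for (e in entries) {
    toks <- strsplit(trimws(sub("^\\{", "", e)), "\\s+")[[1]]
    if (length(toks) < 2L || !grepl("^\\d+$", toks[1])) next
    idx <- as.integer(toks[1]) + 1L
    if (idx >= 1L && idx <= nchar_m) {
      stmt <- gsub("_", " ", paste(toks[-1], collapse = " "))
      if (isTRUE(opts$strip_quotes)) {
        stmt <- gsub("['\"‘’“”]", "", stmt)
      }
      statements[idx] <- trimws(stmt)
    }
  }
  if (all(is.na(statements))) NULL else {
    statements[is.na(statements)] <- paste0("Character ",
                                            which(is.na(statements)))
    statements
  }
}

#' Write a character matrix in TNT xread dialect
#'
#' The output reparses to the same cells, labels and weights
#' ([read_tnt_matrix()] round trip). Captured `source_commands` are emitted
#' after the data block when `include_commands` is `TRUE`; if no command in
#' them encodes non-unit weights, a `ccode` command is generated.
#'
#' @param m a [char_matrix()].
#' @param path optional output file; when `NULL` the text is returned.
#' @param include_commands emit `source_commands` (and a generated weight
#'   command if needed) after the data block.
#' @return The matrix text, invisibly when written to a file.
#' @export
write_tnt_matrix <- function(m, path = NULL, include_commands = TRUE) {
  rows <- vapply(seq_along(m$taxa), function(i) {
    toks <- vapply(m$cells[i, ], function(tok) {
      if (nchar(tok) > 1L) paste0("[", tok, "]") else tok
    }, "")
    paste0(m$taxa[i], " ", paste(toks, collapse = ""))
  }, "")
  out <- c("xread", "'depclad character matrix'",
           paste(ncol(m$cells), length(m$taxa)), rows, ";")
  if (include_commands) {
    cmds <- m$source_commands
    if (any(m$characters$weight != 1) && !any(grepl("^ccode\\b", cmds))) {
      cmds <- c(weight_ccode(m$characters$weight), cmds)
    }
    default_stmts <- paste0("Character ", seq_len(ncol(m$cells)))
    if (!identical(m$characters$statement, default_stmts) &&
        !any(grepl("^cnames\\b", cmds))) {
      cmds <- c(cnames_command(m$characters$statement), cmds)
    }
    out <- c(out, paste0(cmds, " ;"))
  }
  out <- c(out, "proc/ ;")
  txt <- paste(out, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

weight_ccode <- function(weights) {
  parts <- character(0)
  for (w in unique(weights)) {
    idx <- which(weights == w) - 1L  # 0-based on output
    runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
    spans <- vapply(runs, function(r) {
      if (length(r) == 1L) as.character(r) else paste0(r[1], ".", r[length(r)])
    }, "")
    parts <- c(parts, paste0("/", format(w, scientific = FALSE), " ",
                             paste(spans, collapse = " ")))
  }
  paste("ccode", paste(parts, collapse = " "))
}

# statement block: entries "{<0-based index> <name, spaces as
# underscores>"; no internal semicolons so the command survives the
# block splitter
cnames_command <- function(statements) {
  paste("cnames", paste(sprintf(
    "{%d %s", seq_along(statements) - 1L,
    gsub("\\s+", "_", statements)), collapse = " "))
}

#' Read a NEXUS CHARACTERS/DATA block as a character matrix
#'
#' Thin wrapper over [ape::read.nexus.data()], converting its per-taxon
#' token lists to [char_matrix()] cell tokens (`-` inapplicable, `?`
#' missing, multi-state tokens as polymorphisms).
#'
#' @param path NEXUS file path.
#' @return A [char_matrix()].
#' @export
read_nexus_matrix <- function(path) {
  dat <- ape::read.nexus.data(path)
  cells <- do.call(rbind, lapply(dat, function(v) {
    vapply(v, function(tok) {
      tok <- paste(tok, collapse = "")
      if (tok %in% c("?", "-")) return(tok)
      states_to_token(token_states(tok))
    }, "")
  }))
  char_matrix(names(dat), cells)
}

#' Read Newick trees against a fixed taxon set
#'
#' Trees are unrooted and validated: every tree must carry exactly the
#' given leaf set, with no duplicates.
#'
#' @param path Newick file (one or more trees).
#' @param taxon_labels expected leaf labels.
#' @return list of unrooted `phylo` trees.
#' @export
read_trees <- function(path, taxon_labels) {
  first <- readLines(path, n = 1L, warn = FALSE)
  trees <- if (grepl("#NEXUS", first, ignore.case = TRUE)) {
    ape::read.nexus(path)   # translate tables resolved by the reader
  } else {
    ape::read.tree(path)
  }
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(trees, function(tr) {
    if (anyDuplicated(tr$tip.label)) {
      stop("duplicate leaf label: ",
           tr$tip.label[duplicated(tr$tip.label)][1])
    }
    extra <- setdiff(tr$tip.label, taxon_labels)
    if (length(extra)) stop("unknown leaf label: ", extra[1])
    if (length(tr$tip.label) != length(taxon_labels)) {
      stop("tree has ", length(tr$tip.label), " leaves, expected ",
           length(taxon_labels))
    }
    canonical_tree(tr)
  })
}

#' Write trees to a Newick file
#' @param trees a `phylo` or list of `phylo`.
#' @param path output path.
#' @export
write_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, function(tr) {
    ape::write.tree(tr)
  }, ""), path)
  invisible(path)
}

#' Write a labelled distance matrix as CSV or SVG heat map
#'
#' @param dist a [distance_matrix()] result (or any square labelled
#'   numeric matrix with values in `[0, 1]`).
#' @param path output file.
#' @param format `"csv"` or `"svg-heatmap"`.
#' @param digits display rounding for the heat map cell labels.
#' @return `path`, invisibly.
#' @export
write_table <- function(dist, path, format = c("csv", "svg-heatmap"),
                        digits = 2) {
  format <- match.arg(format)
  vals <- if (inherits(dist, "nrf_dist")) dist$values else as.matrix(dist)
  if (nrow(vals) != ncol(vals)) stop("distance matrix must be square")
  if (any(vals < 0 | vals > 1)) stop("distance values must lie in [0, 1]")
  labels <- rownames(vals)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(vals)))
  if (format == "csv") {
    df <- as.data.frame(vals)
    colnames(df) <- labels
    utils::write.csv(cbind(label = labels, df), path, row.names = FALSE)
  } else {
    writeLines(svg_heatmap(vals, labels, digits), path)
  }
  invisible(path)
}

# Minimal self-contained SVG heat map: white (0) to dark red (1),
# row/column labels, cell values printed when space allows.
svg_heatmap <- function(vals, labels, digits = 2) {
  n <- nrow(vals)
  cell <- 28; margin <- 120
  wh <- margin + n * cell + 10
  esc <- function(s) gsub("&", "&amp;", gsub("<", "&lt;", s))
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    wh, wh))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- vals[i, j]
    col <- grDevices::rgb(1, 1 - 0.85 * v, 1 - 0.85 * v)
    x <- margin + (j - 1) * cell
    y <- margin + (i - 1) * cell
    out <- c(out, sprintf(
      '<rect x="%d" y="%d" width="%d" height="%d" fill="%s" stroke="#999"/>',
      x, y, cell, cell, col))
    if (cell >= 24) {
      out <- c(out, sprintf(
        '<text x="%d" y="%d" font-size="8" text-anchor="middle">%s</text>',
        x + cell %/% 2, y + cell %/% 2 + 3,
        formatC(round_half_up(v, digits), format = "g")))
    }
  }
  for (i in seq_len(n)) {
    y <- margin + (i - 1) * cell + cell %/% 2 + 3
    out <- c(out, sprintf(
      '<text x="%d" y="%d" font-size="9" text-anchor="end">%s</text>',
      margin - 4, y, esc(labels[i])))
    x <- margin + (i - 1) * cell + cell %/% 2
    out <- c(out, sprintf(
      paste0('<text x="%d" y="%d" font-size="9" text-anchor="start" ',
             'transform="rotate(-60 %d %d)">%s</text>'),
      x, margin - 4, x, margin - 4, esc(labels[i])))
  }
  c(out, "</svg>")
}
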