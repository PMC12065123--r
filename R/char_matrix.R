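#' Construct a morphological character matrix
#'
#' A `char_matrix` holds a taxa-by-characters grid of discrete scorings
#' together with per-character metadata. Cells are stored as compact string
#' tokens: a single digit (`"0"`–`"9"`) for a definite state, several digits
#' (e.g. `"01"`) for a polymorphism, `"-"` for an inapplicable cell (no state
#' of the character can logically apply, because a hierarchically higher
#' character is in a disabling state), and `"?"` for missing data.
#'
#' @param taxa character vector of unique taxon labels.
#' @param cells character matrix (taxa in rows, characters in columns) of
#'   cell tokens as described above.
#' @param characters optional data frame with one row per character and
#'   columns `statement` (free text, may carry a dependency-annotation
#'   prefix), `char_type` (`"neomorphic"` or `"transformational"`),
#'   `states` (list column of integer state codes) and `weight`
#'   (positive numeric). Missing columns are filled with defaults; state
#'   codes default to those observed in the cells (at least `0:1`).
#' @param source_commands character vector of raw command strings found in
#'   the source file (e.g. `ccode` or `xlinks` blocks), kept verbatim.
#'
#' @return An object of class `char_matrix`.
#' @export
char_matrix <- function(taxa, cells, characters = NULL,
                        source_commands = character()) {
  taxa <- as.character(taxa)
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  cells <- as.matrix(cells)
  storage.mode(cells) <- "character"
  if (nrow(cells) != length(taxa)) {
    stop("cells has ", nrow(cells), " rows but there are ",
         length(taxa), " taxa")
  }
  rownames(cells) <- taxa
  nchar_m <- ncol(cells)
  if (is.null(characters)) characters <- data.frame(row = seq_len(nchar_m))
  characters <- as.data.frame(characters)
  if (nrow(characters) != nchar_m) {
    stop("characters table has ", nrow(characters),
         " rows but cells has ", nchar_m, " columns")
  }
  if (is.null(characters$statement)) {
    characters$statement <- paste0("Character ", seq_len(nchar_m))
  }
  if (is.null(characters$char_type)) {
    characters$char_type <- "transformational"
  }
  if (is.null(characters$weight)) characters$weight <- 1
  if (any(!is.finite(characters$weight)) || any(characters$weight <= 0)) {
    stop("character weights must be positive")
  }
  if (is.null(characters$states)) {
    characters$states <- lapply(seq_len(nchar_m), function(j) {
      obs <- observed_state_codes(cells[, j])
      sort(unique(c(0L, 1L, obs)))
    })
  }
  characters$row <- NULL
  bad <- which(vapply(characters$states, length, 1L) < 2L)
  if (length(bad)) {
    stop("characters must declare at least 2 state codes; offending: ",
         paste(bad, collapse = ", "))
  }
  m <- structure(
    list(taxa = taxa, characters = characters, cells = cells,
         source_commands = as.character(source_commands)),
    class = "char_matrix")
  validate_char_matrix(m)
  m
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("char_matrix:", length(x$taxa), "taxa x",
      ncol(x$cells), "characters\n")
  n_missing <- sum(x$cells == "?")
  n_inap <- sum(x$cells == "-")
  total <- length(x$cells)
  cat(sprintf("  cells: %d (%d missing [%.2f%%], %d inapplicable)\n",
              total, n_missing, 100 * n_missing / total, n_inap))
  if (length(x$source_commands)) {
    cat("  source commands:", length(x$source_commands), "\n")
  }
  invisible(x)
}

#' Number of taxa / characters of a matrix
#' @param m a `char_matrix`.
#' @return integer count.
#' @export
n_taxa <- function(m) length(m$taxa)

#' @rdname n_taxa
#' @export
n_characters <- function(m) ncol(m$cells)

validate_char_matrix <- function(m) {
  for (j in seq_len(ncol(m$cells))) {
    codes <- m$characters$states[[j]]
    for (i in seq_len(nrow(m$cells))) {
      tok <- m$cells[i, j]
      if (tok %in% c("?", "-")) next
      st <- token_states(tok)
      if (length(st) == 0L || !all(st %in% codes)) {
        stop("invalid cell token '", tok, "' at taxon '", m$taxa[i],
             "', character ", j)
      }
    }
  }
  invisible(m)
}

# integer states named in a cell token ("-"/"?" give integer(0))
token_states <- function(tok) {
  if (tok %in% c("?", "-") || !nzchar(tok)) return(integer(0))
  ch <- strsplit(tok, "", fixed = TRUE)[[1]]
  if (!all(ch %in% as.character(0:9))) {
    stop("malformed cell token '", tok, "'")
  }
  sort(unique(as.integer(ch)))
}

observed_state_codes <- function(col) {
  sort(unique(unlist(lapply(col, function(tok) {
    if (tok %in% c("?", "-")) integer(0) else token_states(tok)
  }))))
}

# The set of states a cell may take for scoring purposes. `inapplicable`
# chooses how "-" is read: "missing" expands it to the full state set
# (the traditional treatment), "distinct" keeps it empty (the caller
# handles applicability itself).
cell_state_set <- function(tok, codes, inapplicable = c("missing", "distinct")) {
  inapplicable <- match.arg(inapplicable)
  if (tok == "?") return(codes)
  if (tok == "-") {
    return(if (inapplicable == "missing") codes else integer(0))
  }
  token_states(tok)
}

states_to_token <- function(states) {
  states <- sort(unique(as.integer(states)))
  paste(states, collapse = "")
}
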