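#' Discrete morphological character matrix
#'
#' Characters are stored as per-cell state sets encoded as integer bitmasks
#' (bit `s` set means state `s` is compatible with the observation), which
#' represents unambiguous scores, polymorphism `{01}` and missing `?`
#' uniformly. Inapplicable `-` is treated as missing.
#'
#' @param masks Integer matrix, taxa in rows, characters in columns; entry
#'   is the bitmask of observed states.
#' @param taxa Character vector of taxon labels.
#' @param state_count Integer vector, one per character, each >= 2.
#' @param coding `"all"` or `"variable"` (variable-only ascertainment).
#' @return An object of class `char_matrix`.
#' @export
char_matrix <- function(masks, taxa, state_count,
                        coding = c("all", "variable")) {
  coding <- match.arg(coding)
  masks <- as.matrix(masks)
  storage.mode(masks) <- "integer"
  if (nrow(masks) != length(taxa)) stop("one row per taxon required")
  if (ncol(masks) != length(state_count)) {
    stop("one state count per character required")
  }
  if (any(state_count < 2)) stop("state_count must be >= 2")
  full <- bitwShiftL(1L, as.integer(state_count)) - 1L
  for (j in seq_len(ncol(masks))) {
    if (any(bitwAnd(masks[, j], bitwNot(full[j])) != 0L)) {
      stop(sprintf("character %d: observed state >= its state count", j))
    }
    if (any(masks[, j] == 0L)) stop(sprintf("character %d: empty state set", j))
  }
  rownames(masks) <- taxa
  obj <- structure(
    list(masks = masks, taxa = taxa,
         state_count = as.integer(state_count), coding = coding),
    class = "char_matrix"
  )
  if (coding == "variable") {
    const <- which(vapply(seq_along(state_count), function(j) {
      char_is_constant(masks[, j], full[j])
    }, logical(1)))
    if (length(const)) {
      stop(sprintf("variable-only coding but character(s) %s constant",
                   paste(const, collapse = ", ")))
    }
  }
  obj
}

# A character is (definitely) constant when every scoreable cell is the same
# single state; fully-missing cells are not scoreable and polymorphic cells
# leave the character potentially variable.
char_is_constant <- function(col, full_mask) {
  scored <- col[col != full_mask]
  if (!length(scored)) return(FALSE)
  single <- bitwAnd(scored, scored - 1L) == 0L
  all(single) && length(unique(scored)) == 1L
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("char_matrix: %d taxa x %d characters (coding: %s)\n",
              nrow(x$masks), ncol(x$masks), x$coding))
  cat(sprintf("state counts: %s\n",
              paste(names(table(x$state_count)), "states x",
                    table(x$state_count), collapse = ", ")))
  invisible(x)
}

#' @export
dim.char_matrix <- function(x) dim(x$masks)

mask_to_states <- function(mask, k) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1L))) != 0L) - 1L
}

#' Read a NEXUS DATA/CHARACTERS block into a character matrix
#'
#' Accepts digit symbols, `?` for missing, `-` for inapplicable (treated as
#' missing), and `{..}`/`(..)` polymorphism sets. State counts default to
#' one more than the largest observed state (floor 2) and can be overridden
#' per character.
#'
#' @param path Path to a NEXUS file.
#' @param state_count Optional integer vector overriding inferred counts.
#' @param coding `"infer"` uses variable-only when no character is constant,
#'   otherwise force `"all"` or `"variable"`.
#' @return A [char_matrix].
#' @export
read_nexus_matrix <- function(path, state_count = NULL,
                              coding = c("infer", "all", "variable")) {
  coding <- match.arg(coding)
  lines <- readLines(path, warn = FALSE)
  up <- toupper(lines)
  beg <- grep("BEGIN\\s+(DATA|CHARACTERS)\\s*;", up)
  if (!length(beg)) stop("no DATA/CHARACTERS block found")
  dim_ln <- grep("DIMENSIONS", up)
  dim_ln <- dim_ln[dim_ln > beg[1]][1]
  if (is.na(dim_ln)) stop(sprintf("line %d: block lacks DIMENSIONS", beg[1]))
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*(\\d+).*", "\\1", up[dim_ln]))
  nchar_ <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1", up[dim_ln]))
  if (is.na(ntax) || is.na(nchar_)) {
    stop(sprintf("line %d: cannot parse NTAX/NCHAR", dim_ln))
  }
  mat_ln <- grep("^\\s*MATRIX\\s*$", up)
  mat_ln <- mat_ln[mat_ln > beg[1]][1]
  if (is.na(mat_ln)) stop(sprintf("line %d: block lacks MATRIX", beg[1]))

  taxa <- character(0)
  rows <- list()
  i <- mat_ln + 1L
  while (i <= length(lines)) {
    ln <- sub("\\[[^]]*\\]", "", lines[i])  # bracket comments
    if (grepl("^\\s*;", ln) || grepl(";\\s*$", ln)) {
      ln <- sub(";.*$", "", ln)
      if (nzchar(trimws(ln))) {
        parsed <- parse_matrix_row(ln, i)
        taxa <- c(taxa, parsed$taxon); rows <- c(rows, list(parsed$cells))
      }
      break
    }
    if (nzchar(trimws(ln))) {
      parsed <- parse_matrix_row(ln, i)
      taxa <- c(taxa, parsed$taxon); rows <- c(rows, list(parsed$cells))
    }
    i <- i + 1L
  }
  if (length(taxa) != ntax) {
    stop(sprintf("line %d: expected %d taxa, found %d", mat_ln, ntax,
                 length(taxa)))
  }
  lens <- lengths(rows)
  if (any(lens != nchar_)) {
    bad <- which(lens != nchar_)[1]
    stop(sprintf(
      "dimension error: taxon '%s' has %d characters, expected %d",
      taxa[bad], lens[bad], nchar_))
  }
  masks <- do.call(rbind, rows)
  max_state <- apply(masks, 2, function(col) {
    obs <- col[col != MISSING_MASK]
    if (!length(obs)) 1 else floor(log2(max(as.numeric(obs))))
  })
  inferred <- pmax(2L, as.integer(max_state) + 1L)
  if (!is.null(state_count)) {
    if (length(state_count) != nchar_) stop("state_count override wrong length")
    inferred <- pmax(inferred, as.integer(state_count))
  }
  # '?' cells were parsed as all-bits over a provisional cap; clamp to k
  full <- bitwShiftL(1L, inferred) - 1L
  for (j in seq_len(nchar_)) masks[, j] <- bitwAnd(masks[, j], full[j])
  if (coding == "infer") {
    any_const <- any(vapply(seq_len(nchar_), function(j) {
      char_is_constant(masks[, j], full[j])
    }, logical(1)))
    coding <- if (any_const) "all" else "variable"
  }
  char_matrix(masks, taxa, inferred, coding = coding)
}

MISSING_MASK <- bitwShiftL(1L, 10L) - 1L  # provisional all-states mask

parse_matrix_row <- function(ln, lineno) {
  s <- trimws(ln)
  m <- regexpr("^\\S+", s)
  taxon <- regmatches(s, m)
  rest <- gsub("\\s", "", substring(s, attr(m, "match.length") + 1L))
  cells <- integer(0)
  pos <- 1L
  n <- nchar(rest)
  while (pos <= n) {
    ch <- substr(rest, pos, pos)
    if (ch %in% c("?", "-")) {
      cells <- c(cells, MISSING_MASK); pos <- pos + 1L
    } else if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      end <- pos + 1L
      while (end <= n && substr(rest, end, end) != close) end <- end + 1L
      if (end > n) stop(sprintf("line %d: unterminated state set", lineno))
      digs <- strsplit(substr(rest, pos + 1L, end - 1L), "")[[1]]
      if (!length(digs) || !all(grepl("[0-9]", digs))) {
        stop(sprintf("line %d: bad state set", lineno))
      }
      cells <- c(cells, sum(bitwShiftL(1L, as.integer(digs))))
      pos <- end + 1L
    } else if (grepl("[0-9]", ch)) {
      cells <- c(cells, bitwShiftL(1L, as.integer(ch))); pos <- pos + 1L
    } else {
      stop(sprintf("line %d: unexpected symbol '%s'", lineno, ch))
    }
  }
  list(taxon = taxon, cells = cells)
}

#' @rdname read_nexus_matrix
#' @param x A [char_matrix].
#' @export
write_nexus_matrix <- function(x, path) {
  cells <- vapply(seq_len(nrow(x$masks)), function(i) {
    paste(vapply(seq_len(ncol(x$masks)), function(j) {
      k <- x$state_count[j]
      st <- mask_to_states(x$masks[i, j], k)
      if (length(st) == k) "?"
      else if (length(st) == 1L) as.character(st)
      else paste0("{", paste(st, collapse = ""), "}")
    }, character(1)), collapse = "")
  }, character(1))
  pad <- formatC(x$taxa, width = max(nchar(x$taxa)) + 2L, flag = "-")
  writeLines(c(
    "#NEXUS", "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(x$masks), ncol(x$masks)),
    sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
            paste(0:(max(x$state_count) - 1L), collapse = "")),
    "  MATRIX", paste0("    ", pad, cells), "  ;", "END;"
  ), path)
  invisible(path)
}

#' Tidy long-format view of a character matrix
#'
#' @param x A [char_matrix].
#' @param ... Unused.
#' @return Tibble with columns taxon, character, states (list of integer
#'   vectors), missing flag.
#' @export
tidy.char_matrix <- function(x, ...) {
  grid <- tidyr::expand_grid(taxon = x$taxa,
                             character = seq_along(x$state_count))
  grid$states <- purrr::map2(grid$taxon, grid$character, function(t, j) {
    mask_to_states(x$masks[t, j], x$state_count[j])
  })
  grid$missing <- purrr::map2_lgl(grid$states, grid$character,
                                  ~ length(.x) == x$state_count[.y])
  grid
}
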