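#' Parse a PROSITE-style pattern
#'
#' Supports the core PROSITE grammar: hyphen-separated elements, each a
#' fixed residue, `x` (any residue), a residue class `[ABC]`, or a negated
#' class `{ABC}`, optionally followed by a repeat `(n)` or `(n,m)`; `<` and
#' `>` anchor the pattern to the sequence ends; a trailing `.` is ignored.
#'
#' @param text Pattern string, e.g.
#'   `"[LIVMYA]-[LIVA]-[LIVT]-[LIV]-E-P-D-[SAL]-[LI]-[PSAG]"`.
#' @param accession Optional label (e.g. `"PS00656"`).
#' @return An object of class `prosite_pattern` with `elements` (each:
#'   `type`, `residues`, `min`, `max`), `anchor_start`, `anchor_end`.
#' @export
parse_prosite_pattern <- function(text, accession = NULL) {
  raw <- gsub("\\s", "", text)
  raw <- sub("\\.$", "", raw)
  anchor_start <- grepl("^<", raw)
  anchor_end <- grepl(">$", raw)
  raw <- sub("^<", "", raw)
  raw <- sub(">$", "", raw)
  if (!nzchar(raw)) stop("empty PROSITE pattern")
  tokens <- strsplit(raw, "-", fixed = TRUE)[[1L]]
  elements <- lapply(seq_along(tokens), function(i) {
    parse_prosite_token(tokens[i], i)
  })
  structure(list(accession = accession, elements = elements,
                 anchor_start = anchor_start, anchor_end = anchor_end),
            class = "prosite_pattern")
}

parse_prosite_token <- function(tok, pos) {
  err <- function(msg) {
    stop("PROSITE parse error at token ", pos, " ('", tok, "'): ", msg)
  }
  if (!nzchar(tok)) err("empty element")
  rep_min <- 1L; rep_max <- 1L
  m <- regmatches(tok, regexec("\\((\\d+)(,(\\d+))?\\)$", tok))[[1L]]
  if (length(m) > 0L) {
    rep_min <- as.integer(m[2L])
    rep_max <- if (nzchar(m[4L])) as.integer(m[4L]) else rep_min
    if (rep_min > rep_max) err("repeat minimum exceeds maximum")
    tok <- sub("\\(\\d+(,\\d+)?\\)$", "", tok)
  } else if (grepl("[()]", tok)) {
    err("malformed repeat count")
  }
  if (tok == "x" || tok == "X") {
    el <- list(type = "any", residues = character())
  } else if (grepl("^\\[[A-Za-z]+\\]$", tok)) {
    el <- list(type = "class",
               residues = strsplit(toupper(substr(tok, 2L,
                                                  nchar(tok) - 1L)),
                                   "")[[1L]])
  } else if (grepl("^\\{[A-Za-z]+\\}$", tok)) {
    el <- list(type = "negated",
               residues = strsplit(toupper(substr(tok, 2L,
                                                  nchar(tok) - 1L)),
                                   "")[[1L]])
  } else if (grepl("^[A-Za-z]$", tok)) {
    el <- list(type = "fixed", residues = toupper(tok))
  } else if (grepl("^[\\[{]", tok)) {
    err("unbalanced or empty bracket expression")
  } else {
    err("unrecognised element")
  }
  el$min <- rep_min
  el$max <- rep_max
  el
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat(sprintf("<prosite_pattern>%s %d elements%s\n",
              if (is.null(x$accession)) "" else paste0(" ", x$accession),
              length(x$elements),
              if (pattern_is_fixed_length(x))
                sprintf(" (fixed length %d)", pattern_length(x)) else
                " (variable length)"))
  invisible(x)
}

pattern_is_fixed_length <- function(pattern) {
  all(vapply(pattern$elements, function(e) e$min == e$max, logical(1L)))
}

pattern_length <- function(pattern) {
  sum(vapply(pattern$elements, function(e) e$max, integer(1L)))
}

# one pattern element against one upper-case residue character;
# "X" in a sequence is matched only by "any" elements
element_matches <- function(el, ch) {
  switch(el$type,
         any = ch != "-",
         fixed = ch == el$residues,
         class = ch %in% el$residues,
         negated = ch != "-" && ch != "X" && !(ch %in% el$residues))
}

prosite_to_regex <- function(pattern) {
  parts <- vapply(pattern$elements, function(el) {
    core <- switch(el$type,
                   any = ".",
                   fixed = el$residues,
                   class = paste0("[", paste(el$residues, collapse = ""),
                                  "]"),
                   negated = paste0("[^X",
                                    paste(unique(el$residues),
                                          collapse = ""), "]"))
    if (el$min == 1L && el$max == 1L) core
    else if (el$min == el$max) paste0(core, "{", el$min, "}")
    else paste0(core, "{", el$min, ",", el$max, "}")
  }, character(1L))
  paste0(if (pattern$anchor_start) "^" else "",
         paste(parts, collapse = ""),
         if (pattern$anchor_end) "$" else "")
}

#' Scan a sequence for PROSITE pattern matches
#'
#' Reports every start position at which the pattern matches, including
#' overlapping matches; at each start, variable repeats are resolved
#' greedily (the longest match is reported).
#'
#' @param pattern A `prosite_pattern` or a pattern string.
#' @param seq Ungapped amino-acid sequence.
#' @return Data frame with columns `start`, `end` (1-based inclusive spans);
#'   zero rows when there is no match.
#' @export
scan_sequence <- function(pattern, seq) {
  if (is.character(pattern)) pattern <- parse_prosite_pattern(pattern)
  seq <- toupper(as.character(seq))
  rx <- paste0("(?=(", prosite_to_regex(pattern), "))")
  m <- gregexpr(rx, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(), end = integer()))
  }
  starts <- as.integer(attr(m, "capture.start")[, 1L])
  lens <- as.integer(attr(m, "capture.length")[, 1L])
  data.frame(start = starts, end = starts + lens - 1L)
}

#' Score a signature window across an alignment
#'
#' Locates a fixed-length pattern window by an anchor protein's residues,
#' lifts the window to alignment columns, and scores every row: `matches`
#' counts pattern positions whose residue satisfies the corresponding
#' element. Gaps always count as mismatches (the window has fixed length).
#'
#' @param pattern A fixed-length `prosite_pattern` (or pattern string);
#'   variable repeats are an error here (they have no fixed window).
#' @param alignment Named character vector of gapped rows.
#' @param anchor_id Protein whose residues place the window.
#' @param anchor_index 1-based residue index in the anchor protein of the
#'   window's first pattern position.
#' @return Data frame with columns `protein_id`, `window_start_column`,
#'   `matches`, `out_of`, `per_position` (a string of `1`/`0` flags).
#' @export
score_signature_window <- function(pattern, alignment, anchor_id,
                                   anchor_index) {
  if (is.character(pattern)) pattern <- parse_prosite_pattern(pattern)
  check_alignment(alignment)
  if (!pattern_is_fixed_length(pattern)) {
    stop("window scoring needs a fixed-length pattern; this one has ",
         "variable repeats")
  }
  if (!anchor_id %in% names(alignment)) {
    stop("anchor protein '", anchor_id, "' not in the alignment")
  }
  flat <- unlist(lapply(pattern$elements, function(e) {
    rep(list(e), e$max)
  }), recursive = FALSE)
  L <- length(flat)
  anchor_row <- alignment[[anchor_id]]
  n_res <- nchar(ungap(anchor_row))
  if (anchor_index < 1L || anchor_index + L - 1L > n_res) {
    stop("anchor window [", anchor_index, ", ", anchor_index + L - 1L,
         "] crosses the end of '", anchor_id, "' (", n_res, " residues)")
  }
  cols <- residue_to_column(anchor_row, anchor_index + seq_len(L) - 1L)
  out <- lapply(names(alignment), function(pid) {
    chars <- toupper(substring(alignment[[pid]], cols, cols))
    ok <- vapply(seq_len(L), function(i) {
      chars[i] != "-" && element_matches(flat[[i]], chars[i])
    }, logical(1L))
    data.frame(protein_id = pid, window_start_column = cols[1L],
               matches = sum(ok), out_of = L,
               per_position = paste(as.integer(ok), collapse = ""),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Check conservation of a catalytic residue across an alignment
#'
#' Anchors a reference residue (e.g. the catalytic aspartate D221 of
#' Hypocrea jecorina Cel6A) to its alignment column and reports, for every
#' row, the residue found there, that protein's own residue index, and
#' whether it equals the expected residue. Gapped rows are reported with
#' status `"gap"`.
#'
#' @param alignment Named character vector of gapped rows.
#' @param ref_id Reference protein id.
#' @param ref_protein_index Residue index in the reference protein.
#' @param expected Expected residue (one letter, default `"D"`).
#' @return Data frame with columns `protein_id`, `aligned_residue`,
#'   `aligned_protein_index`, `is_expected`, `status`, `label` (e.g.
#'   `"E197"`).
#' @export
catalytic_residue_check <- function(alignment, ref_id, ref_protein_index,
                                    expected = "D") {
  check_alignment(alignment)
  if (!ref_id %in% names(alignment)) {
    stop("reference protein '", ref_id, "' not in the alignment")
  }
  col <- residue_to_column(alignment[[ref_id]], ref_protein_index)
  ref_res <- substr(alignment[[ref_id]], col, col)
  if (ref_res != expected) {
    warning("reference residue at ", ref_id, ":", ref_protein_index,
            " is '", ref_res, "', not the expected '", expected, "'")
  }
  out <- lapply(names(alignment), function(pid) {
    res <- substr(alignment[[pid]], col, col)
    if (res == "-") {
      data.frame(protein_id = pid, aligned_residue = "-",
                 aligned_protein_index = NA_integer_, is_expected = FALSE,
                 status = "gap", label = "-", stringsAsFactors = FALSE)
    } else {
      idx <- column_to_residue_index(alignment[[pid]], col)
      data.frame(protein_id = pid, aligned_residue = toupper(res),
                 aligned_protein_index = idx,
                 is_expected = toupper(res) == toupper(expected),
                 status = "residue",
                 label = paste0(toupper(res), idx), stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
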