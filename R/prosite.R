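#' Parse a PROSITE-syntax pattern
#'
#' Implements the standard PROSITE pattern grammar: elements separated by
#' `-`; `x` for any residue; `[ACD]` allowed sets; `{ACD}` excluded sets;
#' `(n)` or `(n,m)` repeat counts; `<` / `>` terminal anchors; an optional
#' trailing `.`. Matching is case-insensitive.
#'
#' @param raw Pattern string, e.g. `"G-G-x-G-x-D-x-x-x"`.
#' @return An object of class `prosite_pattern`: the raw string, the parsed
#'   element list (each with `type` = any/set/negset, `residues`, `min`,
#'   `max`), anchor flags, and the minimum span (sum of minimum repeats).
#' @examples
#' parse_prosite_pattern("D-x-[LI]-x(4)-G")
#' @export
parse_prosite_pattern <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(raw)) {
    abort("`raw` must be a single non-empty PROSITE pattern string.")
  }
  txt <- sub("\\.$", "", trimws(raw))
  n_anchor <- startsWith(txt, "<")
  if (n_anchor) txt <- substring(txt, 2L)
  c_anchor <- endsWith(txt, ">")
  if (c_anchor) txt <- substring(txt, 1L, nchar(txt) - 1L)
  if (grepl("<|>", txt)) {
    abort("Parse error: interior anchors are not supported (at most one '<' and one '>').")
  }
  parts <- strsplit(txt, "-", fixed = TRUE)[[1]]
  if (!length(parts) || any(!nzchar(parts))) {
    abort("Parse error: empty pattern element (check '-' separators).")
  }
  elements <- purrr::imap(parts, parse_prosite_element)
  structure(
    list(
      raw = raw, elements = elements,
      n_anchor = n_anchor, c_anchor = c_anchor,
      min_span = sum(vapply(elements, `[[`, numeric(1), "min"))
    ),
    class = "prosite_pattern"
  )
}

parse_prosite_element <- function(part, idx) {
  m <- regmatches(part, regexec(
    "^(x|[A-Za-z]|\\[[A-Za-z]+\\]|\\{[A-Za-z]+\\})(\\(([0-9]+)(,([0-9]+))?\\))?$",
    part
  ))[[1]]
  if (!length(m)) {
    abort(sprintf("Parse error in PROSITE pattern at element %d: '%s'.", idx, part))
  }
  core <- m[2]
  lo <- if (nzchar(m[4])) as.integer(m[4]) else 1L
  hi <- if (nzchar(m[6])) as.integer(m[6]) else lo
  if (lo > hi || lo < 0L) {
    abort(sprintf("Parse error at element %d: bad repeat count in '%s'.", idx, part))
  }
  if (core == "x") {
    list(type = "any", residues = character(), min = lo, max = hi)
  } else if (startsWith(core, "[")) {
    list(
      type = "set",
      residues = strsplit(toupper(substr(core, 2L, nchar(core) - 1L)), "")[[1]],
      min = lo, max = hi
    )
  } else if (startsWith(core, "{")) {
    list(
      type = "negset",
      residues = strsplit(toupper(substr(core, 2L, nchar(core) - 1L)), "")[[1]],
      min = lo, max = hi
    )
  } else {
    list(type = "set", residues = toupper(core), min = lo, max = hi)
  }
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("<prosite_pattern> ", x$raw, "\n", sep = "")
  cat(
    "  elements: ", length(x$elements),
    ", minimum span: ", x$min_span,
    if (x$n_anchor) ", N-anchored" else "",
    if (x$c_anchor) ", C-anchored" else "", "\n",
    sep = ""
  )
  invisible(x)
}

element_matches <- function(el, residue) {
  switch(el$type,
    any = TRUE,
    set = residue %in% el$residues,
    negset = !(residue %in% el$residues)
  )
}

# All end offsets (inclusive) of matches of `elements` starting at `from`
# in the residue vector `chars`. Backtracks over variable repeat counts.
match_ends <- function(chars, elements, from) {
  if (!length(elements)) return(from - 1L)
  el <- elements[[1]]
  rest <- elements[-1]
  ends <- integer()
  # consume the mandatory minimum, then optionally up to max
  pos <- from
  consumed <- 0L
  while (consumed < el$min) {
    if (pos > length(chars) || !element_matches(el, chars[pos])) return(integer())
    pos <- pos + 1L
    consumed <- consumed + 1L
  }
  repeat {
    ends <- c(ends, match_ends(chars, rest, pos))
    if (consumed >= el$max || pos > length(chars) ||
      !element_matches(el, chars[pos])) {
      break
    }
    pos <- pos + 1L
    consumed <- consumed + 1L
  }
  ends
}

#' Scan a sequence for PROSITE pattern matches
#'
#' Reports every match at every offset; overlapping matches are allowed, and
#' a variable-length pattern may yield several matches with the same start.
#' Coordinates are 1-based inclusive and matching is case-insensitive.
#'
#' @param seq A single amino-acid sequence string.
#' @param pattern A [parse_prosite_pattern()] object or raw pattern string.
#' @return Tibble of hits: `start`, `end`, `matched`.
#' @examples
#' scan_pattern("GGSGDDTIV", nonamer_pattern())
#' @export
scan_pattern <- function(seq, pattern) {
  if (is.character(pattern)) pattern <- parse_prosite_pattern(pattern)
  stopifnot(inherits(pattern, "prosite_pattern"))
  seq <- toupper(as.character(seq))
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  starts <- if (pattern$n_anchor) 1L else seq_len(max(n - pattern$min_span + 1L, 0L))
  hits <- purrr::map_dfr(starts, function(s) {
    ends <- unique(match_ends(chars, pattern$elements, s))
    ends <- ends[ends >= s] # zero-length matches are not reported
    if (pattern$c_anchor) ends <- ends[ends == n]
    if (!length(ends)) return(NULL)
    tibble::tibble(start = s, end = sort(ends))
  })
  if (!nrow(hits)) {
    return(tibble::tibble(start = integer(), end = integer(), matched = character()))
  }
  hits$matched <- substring(seq, hits$start, hits$end)
  hits
}

#' The GGXGXDXXX nonamer repeat pattern
#'
#' The hemolysin-type calcium-binding nonapeptide repeat that marks T1SS/RTX
#' cargo proteins. Only the conserved positions are constrained: glycines at
#' positions 1, 2 and 4 and an aspartate at position 6; the remaining
#' positions are free.
#'
#' @return A parsed `prosite_pattern` for `G-G-x-G-x-D-x-x-x`.
#' @export
nonamer_pattern <- function() {
  parse_prosite_pattern("G-G-x-G-x-D-x-x-x")
}

#' Bundled calcium-binding repeat signature
#'
#' Loads the PROSITE-syntax signature used for the `require_ca_repeat`
#' criterion of the cargo screen. The bundled file,
#' `extdata/ps00330_synthetic.prosite`, is a synthetic stand-in constructed
#' from the tandem-nonapeptide architecture of hemolysin-type
#' calcium-binding repeats (two consecutive GGXGXDXXX turns); it is shipped
#' as a replaceable config datum so the genuine PROSITE release pattern
#' (accession PS00330) can be dropped in via `path`.
#'
#' @param path Optional path to a file whose first non-comment line is a
#'   PROSITE pattern.
#' @return A parsed `prosite_pattern`.
#' @export
ca_repeat_pattern <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ps00330_synthetic.prosite",
    package = "straindrift", mustWork = TRUE
  )
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines)) abort("Pattern file has no pattern line.")
  parse_prosite_pattern(trimws(lines[1]))
}
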