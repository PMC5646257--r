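#' Count cysteine residues
#'
#' @param seq Character vector of amino-acid sequences.
#' @return Integer vector of `C` counts (case-insensitive).
#' @examples
#' count_cysteines("ACDC")
#' @export
count_cysteines <- function(seq) {
  stringr::str_count(toupper(seq), stringr::fixed("C"))
}

#' Locate glycine/alanine-rich segments
#'
#' Slides a window of `window` residues along the sequence; windows whose
#' combined G+A fraction reaches `min_fraction` are merged into maximal
#' segments (1-based inclusive coordinates).
#'
#' @param seq A single amino-acid sequence.
#' @param window Window width in residues.
#' @param min_fraction Minimum G+A fraction within a window.
#' @return Tibble of segments: `start`, `end`.
#' @examples
#' find_glyala_segments(strrep("G", 30), window = 30, min_fraction = 0.4)
#' @export
find_glyala_segments <- function(seq, window = 30, min_fraction = 0.4) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (window > n) abort("`window` exceeds the sequence length.")
  is_ga <- strsplit(seq, "")[[1]] %in% c("G", "A")
  cs <- c(0L, cumsum(is_ga))
  starts <- seq_len(n - window + 1L)
  frac <- (cs[starts + window] - cs[starts]) / window
  hit <- starts[frac >= min_fraction]
  merge_intervals(hit, hit + window - 1L)
}

#' Criteria defining a T1SS/RTX cargo candidate
#'
#' The characteristics of type I secretion system export substrates: large
#' size, acidic isoelectric point, cysteine scarcity, a hemolysin-type
#' calcium-binding repeat signature, and GGXGXDXXX nonamer repeats near the
#' C terminus. Gly/Ala-rich segments are reported but do not gate the
#' verdict. Every criterion is individually configurable or switchable.
#'
#' @param min_length Minimum protein length (aa). The known cargo exceed
#'   2400 aa while a typical bacterial protein is ~300 aa; 1000 separates
#'   the classes cleanly.
#' @param max_pI Maximum isoelectric point ("acidic"; known cargo sit at
#'   4.03 and 4.20).
#' @param max_cysteines Maximum cysteine count ("few or no cysteines").
#' @param require_ca_repeat Require at least one hit of `ca_pattern`.
#' @param ca_pattern Calcium-binding repeat signature
#'   (default [ca_repeat_pattern()]).
#' @param nonamer PROSITE pattern of the nonamer repeat
#'   (default [nonamer_pattern()]).
#' @param min_nonamers Minimum nonamer hits starting within the C-terminal
#'   window.
#' @param c_term_window Fraction of the sequence counted as "near the C
#'   terminus" (default final 25%; the known repeats sit in the final ~6%).
#' @param glyala_window,glyala_min_fraction Parameters for the reported
#'   Gly/Ala-rich segments.
#' @param pka_set pKa set name for [compute_pI()].
#' @return A list of class `cargo_criteria`.
#' @export
cargo_criteria <- function(min_length = 1000, max_pI = 4.5, max_cysteines = 3,
                           require_ca_repeat = TRUE,
                           ca_pattern = ca_repeat_pattern(),
                           nonamer = nonamer_pattern(),
                           min_nonamers = 1, c_term_window = 0.25,
                           glyala_window = 30, glyala_min_fraction = 0.4,
                           pka_set = "bjellqvist") {
  assert_scalar_number(min_length, "min_length", positive = TRUE)
  assert_scalar_number(max_pI, "max_pI", positive = TRUE)
  assert_scalar_number(max_cysteines, "max_cysteines", min = 0)
  assert_scalar_number(min_nonamers, "min_nonamers", min = 0)
  assert_scalar_number(c_term_window, "c_term_window", min = 1e-9, max = 1)
  if (is.character(ca_pattern)) ca_pattern <- parse_prosite_pattern(ca_pattern)
  if (is.character(nonamer)) nonamer <- parse_prosite_pattern(nonamer)
  structure(
    list(
      min_length = min_length, max_pI = max_pI, max_cysteines = max_cysteines,
      require_ca_repeat = require_ca_repeat, ca_pattern = ca_pattern,
      nonamer = nonamer, min_nonamers = min_nonamers,
      c_term_window = c_term_window, glyala_window = glyala_window,
      glyala_min_fraction = glyala_min_fraction, pka_set = pka_set
    ),
    class = "cargo_criteria"
  )
}

#' Screen a proteome for T1SS/RTX cargo candidates
#'
#' Computes, for every protein, the full feature vector (length, pI,
#' cysteine count, calcium-binding repeat hits, C-terminal nonamer hits,
#' Gly/Ala segments) and a verdict. A protein is a `candidate` iff its
#' length, pI and cysteine count satisfy the thresholds, the calcium-binding
#' repeat signature is present (when required), and at least `min_nonamers`
#' nonamer hits start within the final `c_term_window` fraction of the
#' sequence. `failed_criteria` names every violated rule, so the verdict is
#' `candidate` exactly when that list is empty.
#'
#' @param proteins Data frame with columns `id` and `sequence` (e.g. from
#'   [read_fasta()]); a `description` column is carried through.
#' @param criteria A [cargo_criteria()] object.
#' @return Tibble with one row per protein: features, `nonamer_hits` /
#'   `ca_hits` / `glyala_segments` list columns, `n_cterm_nonamers`,
#'   `verdict` (`"candidate"`/`"rejected"`), `failed_criteria` (list).
#'   Row order follows the input; results are order-independent.
#' @export
screen_proteome <- function(proteins, criteria = cargo_criteria()) {
  stopifnot(inherits(criteria, "cargo_criteria"))
  proteins <- tibble::as_tibble(proteins)
  if (!all(c("id", "sequence") %in% names(proteins))) {
    abort("`proteins` needs `id` and `sequence` columns.")
  }
  if (anyDuplicated(proteins$id)) abort("Duplicate protein id in input.")
  rows <- purrr::map2(proteins$id, toupper(proteins$sequence), function(id, seq) {
    len <- nchar(seq)
    if (len == 0L) abort(paste0("Empty sequence for protein ", id))
    pi_val <- compute_pI(seq, pka_set = criteria$pka_set)
    ncys <- count_cysteines(seq)
    non_hits <- scan_pattern(seq, criteria$nonamer)
    ca_hits <- if (criteria$require_ca_repeat) {
      scan_pattern(seq, criteria$ca_pattern)
    } else {
      tibble::tibble(start = integer(), end = integer(), matched = character())
    }
    window_start <- floor(len * (1 - criteria$c_term_window)) + 1L
    cterm <- non_hits[non_hits$start >= window_start, , drop = FALSE]
    glyala <- if (len >= criteria$glyala_window) {
      find_glyala_segments(seq, criteria$glyala_window, criteria$glyala_min_fraction)
    } else {
      tibble::tibble(start = integer(), end = integer())
    }
    failed <- character()
    if (len < criteria$min_length) failed <- c(failed, "min_length")
    if (pi_val > criteria$max_pI) failed <- c(failed, "max_pI")
    if (ncys > criteria$max_cysteines) failed <- c(failed, "max_cysteines")
    if (criteria$require_ca_repeat && nrow(ca_hits) == 0L) {
      failed <- c(failed, "ca_repeat")
    }
    if (nrow(cterm) < criteria$min_nonamers) failed <- c(failed, "c_term_nonamers")
    tibble::tibble(
      id = id, length = len, pI = pi_val, n_cys = ncys,
      n_nonamers = nrow(non_hits), n_cterm_nonamers = nrow(cterm),
      n_ca_hits = nrow(ca_hits),
      nonamer_hits = list(non_hits), ca_hits = list(ca_hits),
      glyala_segments = list(glyala),
      verdict = if (length(failed)) "rejected" else "candidate",
      failed_criteria = list(failed)
    )
  })
  out <- dplyr::bind_rows(rows)
  if ("description" %in% names(proteins)) {
    out <- dplyr::mutate(out, description = proteins$description, .after = "id")
  }
  out
}
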