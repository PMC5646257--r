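#' Thresholds for the variant acceptance rule
#'
#' A candidate deviation from the reference is accepted as a true variant when
#' its read frequency is at least `min_frequency` and, unless the frequency
#' reaches `high_frequency_cutoff`, its strand bias stays strictly below
#' `max_strand_bias`. These defaults encode the rule used for 63x bacterial
#' resequencing data: at least 10% of covering reads must carry the deviation,
#' and below 80% frequency the strand bias must be less than 70%.
#'
#' @param min_frequency Minimum alternate-read frequency (fraction).
#' @param high_frequency_cutoff Frequency at or above which the strand-bias
#'   clause is waived.
#' @param max_strand_bias Strand-bias bound applied below the cutoff; the
#'   comparison is strict (`bias < max_strand_bias` passes).
#' @return A list of class `filter_thresholds`.
#' @examples
#' filter_thresholds()
#' @export
filter_thresholds <- function(min_frequency = 0.10,
                              high_frequency_cutoff = 0.80,
                              max_strand_bias = 0.70) {
  assert_scalar_number(min_frequency, "min_frequency", min = 0, max = 1)
  assert_scalar_number(high_frequency_cutoff, "high_frequency_cutoff", min = 0, max = 1)
  assert_scalar_number(max_strand_bias, "max_strand_bias", min = 0.5, max = 1)
  if (!(min_frequency > 0 && min_frequency < high_frequency_cutoff)) {
    abort("Need 0 < min_frequency < high_frequency_cutoff <= 1.")
  }
  structure(
    list(
      min_frequency = min_frequency,
      high_frequency_cutoff = high_frequency_cutoff,
      max_strand_bias = max_strand_bias
    ),
    class = "filter_thresholds"
  )
}

#' Alternate-read frequency of a pileup observation
#'
#' @param alt_depth Reads supporting the alternate allele.
#' @param depth Total reads covering the site; must be positive.
#' @return `alt_depth / depth`, vectorized.
#' @examples
#' estimate_frequency(34, 50)
#' @export
estimate_frequency <- function(alt_depth, depth) {
  if (any(depth <= 0)) abort("Site is uncovered: depth must be > 0.")
  if (any(alt_depth < 0 | alt_depth > depth)) {
    abort("`alt_depth` must lie in [0, depth].")
  }
  alt_depth / depth
}

#' Strand bias of alternate-supporting reads
#'
#' Defined as the share of alternate reads on the majority strand,
#' `max(alt_fwd, alt_rev) / alt_depth`, so a perfectly balanced variant scores
#' 0.5 and a single-strand artifact scores 1.
#'
#' @param alt_fwd,alt_rev Forward- and reverse-strand alternate read counts.
#' @return Strand bias in `[0.5, 1]`, vectorized.
#' @examples
#' strand_bias(14, 1)
#' @export
strand_bias <- function(alt_fwd, alt_rev) {
  alt <- alt_fwd + alt_rev
  if (any(alt <= 0)) abort("Strand bias is undefined when alt_depth = 0.")
  if (any(alt_fwd < 0 | alt_rev < 0)) abort("Strand counts must be non-negative.")
  pmax(alt_fwd, alt_rev) / alt
}

#' Apply the acceptance rule to a pileup table
#'
#' Takes one row per candidate site per sample (columns `depth`, `alt_depth`,
#' `alt_fwd`, `alt_rev`; any identifying columns such as `sample`, `pos`,
#' `ref`, `alt` are carried through) and appends the computed `frequency`,
#' `strand_bias`, the verdict `passed`, and `fail_reason` (`"none"`,
#' `"below_min_frequency"`, or `"strand_biased"`, in that order of
#' precedence).
#'
#' @param pileup Data frame of pileup observations.
#' @param thresholds A [filter_thresholds()] object.
#' @return The input as a tibble with call columns appended.
#' @examples
#' calls <- call_variants(tibble::tibble(
#'   sample = "s1", pos = 1903, ref = "G", alt = "C",
#'   depth = 64, alt_depth = 15, alt_fwd = 14, alt_rev = 1
#' ))
#' calls$fail_reason
#' @export
call_variants <- function(pileup, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  pileup <- tibble::as_tibble(pileup)
  needed <- c("depth", "alt_depth", "alt_fwd", "alt_rev")
  missing <- setdiff(needed, names(pileup))
  if (length(missing)) {
    abort(paste0("Pileup table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(pileup) == 0L) {
    return(dplyr::mutate(pileup,
      frequency = numeric(), strand_bias = numeric(),
      passed = logical(), fail_reason = character()
    ))
  }
  if (any(pileup$depth <= 0)) abort("Uncovered site (depth = 0) in pileup table.")
  if (any(pileup$alt_fwd + pileup$alt_rev != pileup$alt_depth)) {
    abort("Strand counts must satisfy alt_fwd + alt_rev = alt_depth.")
  }
  freq <- pileup$alt_depth / pileup$depth
  bias <- ifelse(pileup$alt_depth > 0,
    pmax(pileup$alt_fwd, pileup$alt_rev) / pileup$alt_depth, NA_real_
  )
  above_min <- freq >= thresholds$min_frequency
  waived <- freq >= thresholds$high_frequency_cutoff
  balanced <- !is.na(bias) & bias < thresholds$max_strand_bias
  passed <- above_min & (waived | balanced)
  fail_reason <- dplyr::case_when(
    passed ~ "none",
    !above_min ~ "below_min_frequency",
    .default = "strand_biased"
  )
  dplyr::mutate(pileup,
    frequency = freq, strand_bias = bias,
    passed = passed, fail_reason = fail_reason
  )
}
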