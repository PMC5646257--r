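#' End-to-end variant screen
#'
#' Drives the full variant stage on a pileup table: applies the
#' frequency/strand-bias acceptance rule per sample ([call_variants()]),
#' classifies each variant key across samples ([classify_variants()]), and,
#' when CDS annotations are supplied, appends codon consequences
#' ([annotate_variants()]). The result is one row per variant key sorted by
#' position, with per-sample frequency columns (`freq_<sample>`), the
#' cross-sample label, a `near_fixed` flag, and (optionally) codon fields.
#'
#' @param pileup Pileup table (`sample`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_depth`, `alt_fwd`, `alt_rev`).
#' @param thresholds A [filter_thresholds()] object.
#' @param strains Sample-to-strain map (named vector or data frame).
#' @param emergent_samples Samples treated as "later" observations.
#' @param cds,genome Optional CDS interval table ([read_gff3_cds()]) and
#'   genome sequences for codon annotation.
#' @param near_fixed_frequency Frequency at or above which a variant is
#'   reported as near-fixed (default 0.9, i.e. "at or near 100%").
#' @return A tibble report, one row per variant key.
#' @export
screen_variants <- function(pileup,
                            thresholds = filter_thresholds(),
                            strains,
                            emergent_samples = character(),
                            cds = NULL, genome = NULL,
                            near_fixed_frequency = 0.9) {
  calls <- call_variants(pileup, thresholds)
  if (nrow(calls) == 0L) {
    return(tibble::tibble(
      pos = integer(), ref = character(), alt = character(),
      label = character(), strain = character(),
      n_samples_passing = integer(), max_frequency = numeric(),
      near_fixed = logical()
    ))
  }
  report <- classify_variants(calls, strains, emergent_samples)
  freq_wide <- calls |>
    dplyr::select("sample", "pos", "ref", "alt", "frequency") |>
    tidyr::pivot_wider(
      names_from = "sample", values_from = "frequency",
      names_prefix = "freq_", values_fill = NA
    )
  report <- report |>
    dplyr::left_join(freq_wide, by = c("pos", "ref", "alt")) |>
    dplyr::mutate(near_fixed = .data$max_frequency >= near_fixed_frequency)
  if (!is.null(cds)) {
    if (is.null(genome)) abort("Codon annotation needs both `cds` and `genome`.")
    report <- annotate_variants(report, cds, genome)
  }
  dplyr::arrange(report, .data$pos, .data$ref, .data$alt)
}
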