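#' Classify variants across samples
#'
#' Given per-sample calls (the output of [call_variants()]) and a map from
#' sample to strain, each variant key `(pos, ref, alt)` receives exactly one
#' label:
#'
#' * `shared_all` - a passing call in every sample (the signature of an error
#'   in the original reference rather than a new mutation);
#' * `emergent` - passing calls confined to the designated later sample(s) of
#'   a strain (e.g. a biofilm sample resequenced after selection);
#' * `strain_unique` - passing calls confined to the samples of exactly one
#'   strain;
#' * `other` - anything else, including keys that pass nowhere.
#'
#' @param calls Data frame with at least `sample`, `pos`, `ref`, `alt`,
#'   `passed`, and `frequency` columns.
#' @param strains Named character vector or two-column data frame
#'   (`sample`, `strain`) assigning every sample to a strain.
#' @param emergent_samples Character vector of samples treated as "later"
#'   observations of their strain (may be empty).
#' @return A tibble with one row per variant key: `pos`, `ref`, `alt`,
#'   `label`, `strain` (for strain-confined labels, else `NA`),
#'   `n_samples_passing`, `samples_passing` (list column), `max_frequency`,
#'   and `frequencies` (named list column of per-sample frequencies).
#' @examples
#' calls <- call_variants(tibble::tibble(
#'   sample = c("MT_batch", "MO_batch", "MO_biofilm"),
#'   pos = 1118956, ref = "G", alt = "C",
#'   depth = c(68, 64, 50), alt_depth = c(0, 63, 12),
#'   alt_fwd = c(0, 31, 6), alt_rev = c(0, 32, 6)
#' ))
#' classify_variants(calls,
#'   strains = c(MT_batch = "MT", MO_batch = "MO", MO_biofilm = "MO"),
#'   emergent_samples = "MO_biofilm"
#' )
#' @export
classify_variants <- function(calls, strains, emergent_samples = character()) {
  calls <- tibble::as_tibble(calls)
  strains <- as_strain_map(strains)
  if (nrow(calls) && !all(calls$sample %in% strains$sample)) {
    unknown <- setdiff(unique(calls$sample), strains$sample)
    abort(paste0("Sample(s) not in strain map: ", paste(unknown, collapse = ", ")))
  }
  if (nrow(strains) < 2L) abort("Cross-sample classification needs >= 2 samples.")
  if (length(emergent_samples) && !all(emergent_samples %in% strains$sample)) {
    abort("`emergent_samples` must be samples of the strain map.")
  }
  all_samples <- strains$sample
  strain_of <- setNames(strains$strain, strains$sample)

  calls |>
    dplyr::group_by(.data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      samples_passing = list(.data$sample[.data$passed]),
      frequencies = list(setNames(.data$frequency, .data$sample)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_samples_passing = lengths(.data$samples_passing),
      label = purrr::map_chr(.data$samples_passing, function(sp) {
        if (length(sp) == 0L) return("other")
        if (setequal(sp, all_samples)) return("shared_all")
        if (length(emergent_samples) && all(sp %in% emergent_samples)) {
          return("emergent")
        }
        if (length(unique(strain_of[sp])) == 1L) return("strain_unique")
        "other"
      }),
      strain = purrr::map2_chr(.data$samples_passing, .data$label, function(sp, lb) {
        if (lb %in% c("strain_unique", "emergent")) unique(strain_of[sp]) else NA_character_
      }),
      max_frequency = purrr::map_dbl(
        .data$frequencies,
        ~ if (length(.x)) max(.x) else NA_real_
      )
    ) |>
    dplyr::select(
      "pos", "ref", "alt", "label", "strain", "n_samples_passing",
      "max_frequency", "samples_passing", "frequencies"
    ) |>
    dplyr::arrange(.data$pos, .data$ref, .data$alt)
}

as_strain_map <- function(strains) {
  if (is.data.frame(strains)) {
    stopifnot(all(c("sample", "strain") %in% names(strains)))
    out <- tibble::as_tibble(strains[c("sample", "strain")])
  } else if (is.character(strains) && !is.null(names(strains))) {
    out <- tibble::tibble(sample = names(strains), strain = unname(strains))
  } else {
    abort("`strains` must be a named character vector or a sample/strain data frame.")
  }
  if (anyDuplicated(out$sample)) abort("Duplicate sample in strain map.")
  out
}
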