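#' Catalogued strain-unique mutations of the biofilm-deficient lineage
#'
#' The twelve mutations fixed in the DvH-MO lineage of *Desulfovibrio
#' vulgaris* Hildenborough relative to the published reference, as detected
#' at (or near) 100% frequency in batch-culture resequencing: position,
#' replicon, affected locus, amino-acid change where coding, and the
#' reference/alternate alleles. Shipped as a plain-text table in
#' `extdata/dvh_mo_unique_variants.tsv`; plasmid positions are plasmid-local
#' coordinates.
#'
#' @return Tibble with columns `position`, `replicon`, `locus_tag`, `note`,
#'   `aa_change`, `ref`, `alt`.
#' @examples
#' nrow(dvh_mo_variants()) # 12
#' @export
dvh_mo_variants <- function() {
  path <- system.file("extdata", "dvh_mo_unique_variants.tsv",
    package = "straindrift", mustWork = TRUE
  )
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

#' Sample-to-strain map of the three-sample resequencing design
#'
#' Two batch cultures (one per strain lineage) plus a biofilm sample of the
#' biofilm-deficient lineage collected after extended selection in the
#' reactor.
#'
#' @return Named character vector mapping sample to strain.
#' @export
demo_strains <- function() {
  c(MT_batch = "MT", MO_batch = "MO", MO_biofilm = "MO")
}

#' Build the demonstration pileup plan
#'
#' Emulates the three-sample resequencing experiment: the twelve catalogued
#' strain-unique mutations ([dvh_mo_variants()]) planted near fixation in
#' the two DvH-MO samples only, `n_shared` reference-error deviations
#' planted in all three samples, and spurious sub-threshold noise at the
#' plan's `noise_rate`, all at 63x Poisson coverage over a
#' bacterial-genome-sized region.
#'
#' @param seed Integer seed driving both the shared-deviation positions and
#'   the pileup simulation.
#' @param n_shared Number of deviations shared by all samples (reference
#'   errors).
#' @param unique_frequency Planted frequency of the strain-unique set
#'   (near-fixed, default 0.98).
#' @param noise_rate Per-site spurious-call probability.
#' @return A [pileup_plan()].
#' @export
demo_pileup_plan <- function(seed = 1, n_shared = 29, unique_frequency = 0.98,
                             noise_rate = 2e-6) {
  stopifnot(unique_frequency >= 0.95)
  genome_length <- 3570858L
  tab <- dvh_mo_variants()
  # plasmid positions are plasmid-local; offset them past the chromosome so
  # every site key is unique in one coordinate space
  pos <- ifelse(tab$replicon == "plasmid", tab$position + genome_length, tab$position)
  region_length <- genome_length + 202301L
  shared <- with_seed_if(seed, {
    spos <- sort(sample(setdiff(seq_len(region_length), pos), n_shared))
    bases <- c("A", "C", "G", "T")
    sref <- sample(bases, n_shared, replace = TRUE)
    salt <- vapply(sref, function(r) sample(setdiff(bases, r), 1L), character(1))
    planted_variants(spos, sref, salt,
      true_frequency = 0.99, strand_skew = 0.5, samples = list(NULL)
    )
  })
  unique_set <- planted_variants(
    pos, tab$ref, tab$alt,
    true_frequency = unique_frequency, strand_skew = 0.5,
    samples = list(c("MO_batch", "MO_biofilm"))
  )
  pileup_plan(
    samples = names(demo_strains()),
    variants = dplyr::bind_rows(unique_set, shared),
    mean_depth = 63, depth_model = "poisson",
    noise_rate = noise_rate, region_length = region_length,
    seed = seed
  )
}
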