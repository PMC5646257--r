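#' Describe variants to plant in a simulated pileup
#'
#' @param position 1-based genome coordinates.
#' @param ref,alt Nucleotide strings (equal-length runs give MNVs); `ref`
#'   must differ from `alt`.
#' @param true_frequency Fraction of cells carrying the variant, in `[0, 1]`.
#' @param strand_skew Expected share of alternate reads on the forward
#'   strand (0.5 = balanced).
#' @param samples List of character vectors naming the samples that carry
#'   each variant; `NULL` entries mean "all samples of the plan".
#' @return A tibble of planted variants.
#' @export
planted_variants <- function(position, ref, alt, true_frequency,
                             strand_skew = 0.5, samples = NULL) {
  out <- tibble::tibble(
    position = as.integer(position), ref = toupper(ref), alt = toupper(alt),
    true_frequency = true_frequency, strand_skew = strand_skew,
    samples = if (is.null(samples)) list(NULL) else samples
  )
  if (any(out$ref == out$alt)) abort("Planted variant with ref == alt.")
  if (any(nchar(out$ref) < 1L | nchar(out$alt) < 1L)) {
    abort("Planted alleles must be non-empty.")
  }
  if (any(out$true_frequency < 0 | out$true_frequency > 1)) {
    abort("`true_frequency` must lie in [0, 1].")
  }
  if (any(out$strand_skew < 0 | out$strand_skew > 1)) {
    abort("`strand_skew` must lie in [0, 1].")
  }
  out
}

#' Plan a simulated pileup experiment
#'
#' Describes a resequencing experiment summarised as per-site pileups: a set
#' of samples, planted variants with known frequencies and strand skews, a
#' depth model, and a rate of spurious low-frequency noise calls.
#'
#' @param samples Character vector of sample identifiers.
#' @param variants Tibble from [planted_variants()] (may have zero rows).
#' @param mean_depth Mean read depth per site (default 63, typical bacterial
#'   resequencing coverage).
#' @param depth_model `"poisson"` (depth ~ Poisson(mean_depth), the shotgun
#'   approximation) or `"fixed"`.
#' @param noise_rate Per-site probability that a spurious low-frequency
#'   variant (true frequency uniform on 0.01-0.08, balanced strands) is
#'   emitted at that site, assigned to one random sample. Default 2e-6,
#'   a handful of artifact sites per bacterial genome.
#' @param region_length Number of sites in the simulated region (the noise
#'   universe). Defaults to the largest planted position, padded, or 10 kb
#'   for variant-free plans.
#' @param seed Integer seed; fixes all randomness of [simulate_pileup()].
#' @return A list of class `pileup_plan`.
#' @export
pileup_plan <- function(samples, variants = planted_variants(integer(), character(), character(), numeric()),
                        mean_depth = 63, depth_model = c("poisson", "fixed"),
                        noise_rate = 2e-6, region_length = NULL, seed = NULL) {
  depth_model <- match.arg(depth_model)
  if (!is.character(samples) || !length(samples) || anyDuplicated(samples)) {
    abort("`samples` must be distinct sample identifiers.")
  }
  assert_scalar_number(mean_depth, "mean_depth", positive = TRUE)
  assert_scalar_number(noise_rate, "noise_rate", min = 0, max = 1 - 1e-12)
  variants <- tibble::as_tibble(variants)
  if (is.null(region_length)) {
    region_length <- if (nrow(variants)) max(variants$position) + 1000L else 10000L
  }
  assert_scalar_number(region_length, "region_length", positive = TRUE)
  # resolve per-variant carrier sets and check for same-sample overlap
  if (nrow(variants)) {
    carriers <- purrr::map(variants$samples, function(s) {
      if (is.null(s) || (length(s) == 1L && is.na(s))) samples else s
    })
    if (!all(unlist(carriers) %in% samples)) {
      abort("Planted variant names a sample absent from the plan.")
    }
    variants$samples <- carriers
    spans <- tibble::tibble(
      idx = rep(seq_len(nrow(variants)), lengths(carriers)),
      sample = unlist(carriers)
    )
    spans$start <- variants$position[spans$idx]
    spans$end <- spans$start + nchar(variants$ref[spans$idx]) - 1L
    clash <- spans |>
      dplyr::group_by(.data$sample) |>
      dplyr::group_map(function(g, key) {
        g <- g[order(g$start), ]
        any(nrow(g) > 1L & c(FALSE, g$start[-1] <= g$end[-nrow(g)]))
      })
    if (any(unlist(clash))) {
      abort("Overlapping planted variants at the same position in the same sample.")
    }
  }
  structure(
    list(
      samples = samples, variants = variants, mean_depth = mean_depth,
      depth_model = depth_model, noise_rate = noise_rate,
      region_length = as.integer(region_length), seed = seed
    ),
    class = "pileup_plan"
  )
}

#' Simulate per-site pileup summaries with planted truth
#'
#' For every planted variant and carrying sample, the site depth follows the
#' plan's depth model, the alternate read count is Binomial(depth,
#' true_frequency), and the forward-strand alternate count is
#' Binomial(alt_depth, strand_skew). Samples that do not carry a variant
#' still receive a row (alternate depth 0) so downstream cross-sample
#' classification sees the full site-by-sample grid. Spurious noise variants
#' are added per the plan's `noise_rate` at true frequencies uniform on
#' 0.01-0.08 with balanced strands. Deterministic given the plan's seed.
#'
#' @param plan A [pileup_plan()].
#' @return Tibble with columns `sample`, `pos`, `ref`, `alt`, `depth`,
#'   `alt_depth`, `alt_fwd`, `alt_rev`, plus `planted` (logical truth flag)
#'   and `true_frequency`.
#' @examples
#' plan <- pileup_plan(
#'   samples = c("a", "b"),
#'   variants = planted_variants(100, "G", "C", 1.0),
#'   depth_model = "fixed", mean_depth = 50, seed = 1
#' )
#' simulate_pileup(plan)
#' @export
simulate_pileup <- function(plan) {
  stopifnot(inherits(plan, "pileup_plan"))
  with_seed_if(plan$seed, {
    sites <- plan$variants
    noise <- simulate_noise_sites(plan)
    planted_grid <- NULL
    if (nrow(sites)) {
      site_tbl <- tibble::tibble(
        pos = sites$position, ref = sites$ref, alt = sites$alt,
        true_frequency = sites$true_frequency,
        strand_skew = sites$strand_skew, carriers = sites$samples,
        planted = TRUE
      )
      planted_grid <- expand_sites(site_tbl, plan$samples)
    }
    grid <- dplyr::bind_rows(planted_grid, noise)
    if (nrow(grid) == 0L) {
      return(tibble::tibble(
        sample = character(), pos = integer(), ref = character(),
        alt = character(), depth = integer(), alt_depth = integer(),
        alt_fwd = integer(), alt_rev = integer(), planted = logical(),
        true_frequency = numeric()
      ))
    }
    carries <- purrr::map2_lgl(grid$carriers, grid$sample, ~ .y %in% .x)
    n <- nrow(grid)
    depth <- switch(plan$depth_model,
      fixed = rep(as.integer(round(plan$mean_depth)), n),
      poisson = rpois(n, plan$mean_depth)
    )
    depth <- pmax(depth, 1L) # a summarised candidate site was, by construction, covered
    p <- ifelse(carries, grid$true_frequency, 0)
    alt_depth <- rbinom(n, depth, p)
    alt_fwd <- rbinom(n, alt_depth, grid$strand_skew)
    tibble::tibble(
      sample = grid$sample, pos = grid$pos, ref = grid$ref, alt = grid$alt,
      depth = depth, alt_depth = alt_depth, alt_fwd = alt_fwd,
      alt_rev = alt_depth - alt_fwd,
      planted = grid$planted & carries,
      true_frequency = ifelse(carries, grid$true_frequency, 0)
    ) |>
      dplyr::arrange(.data$pos, .data$ref, .data$alt, .data$sample)
  })
}

# Draw spurious low-frequency sites: Binomial(region_length, noise_rate)
# sites at distinct positions away from planted variants, each an artifact
# of one randomly chosen sample.
simulate_noise_sites <- function(plan) {
  n_noise <- rbinom(1L, plan$region_length, plan$noise_rate)
  empty <- tibble::tibble(
    pos = integer(), ref = character(), alt = character(),
    true_frequency = numeric(), strand_skew = numeric(),
    carriers = list(), planted = logical(), sample = character()
  )
  if (n_noise == 0L) return(empty)
  taken <- unique(plan$variants$position)
  pool <- setdiff(seq_len(plan$region_length), taken)
  n_noise <- min(n_noise, length(pool))
  pos <- sort(sample(pool, n_noise))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_noise, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  affected <- sample(plan$samples, n_noise, replace = TRUE)
  expand_sites(
    tibble::tibble(
      pos = pos, ref = unname(ref), alt = unname(alt),
      true_frequency = runif(n_noise, 0.01, 0.08),
      strand_skew = 0.5,
      carriers = as.list(affected),
      planted = FALSE
    ),
    plan$samples
  )
}

# Cartesian product of a site table with the sample list (one row per
# site per sample), preserving list columns.
expand_sites <- function(site_tbl, samples) {
  idx <- rep(seq_len(nrow(site_tbl)), each = length(samples))
  out <- site_tbl[idx, ]
  out$sample <- rep(samples, times = nrow(site_tbl))
  out
}
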