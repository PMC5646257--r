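#' Reactor surface geometry
#'
#' Areas colonizable by biofilm inside a CDC-style reactor: the vessel wall
#' plus a set of glass-slide coupons.
#'
#' @param vessel_area Vessel wall area (cm^2).
#' @param slide_area Area of each glass slide (cm^2).
#' @param n_slides Number of slides.
#' @return A list of class `reactor_geometry`.
#' @examples
#' total_area(reactor_geometry()) # 336
#' @export
reactor_geometry <- function(vessel_area = 231, slide_area = 15, n_slides = 7) {
  assert_scalar_number(vessel_area, "vessel_area", positive = TRUE)
  assert_scalar_number(slide_area, "slide_area", positive = TRUE)
  assert_scalar_number(n_slides, "n_slides", min = 0)
  structure(
    list(vessel_area = vessel_area, slide_area = slide_area, n_slides = n_slides),
    class = "reactor_geometry"
  )
}

#' Biomass conversion constants
#'
#' @param protein_per_cell Protein content per cell in femtograms (default
#'   278 fg/cell, measured in *Desulfovibrio desulfuricans*).
#' @param detection_limit Areal protein detection limit (µg/cm^2).
#' @return A list of class `conversion_constants`.
#' @export
conversion_constants <- function(protein_per_cell = 278, detection_limit = 1.3) {
  assert_scalar_number(protein_per_cell, "protein_per_cell", positive = TRUE)
  assert_scalar_number(detection_limit, "detection_limit", positive = TRUE)
  structure(
    list(protein_per_cell = protein_per_cell, detection_limit = detection_limit),
    class = "conversion_constants"
  )
}

#' Total colonizable surface area
#'
#' @param geometry A [reactor_geometry()].
#' @return Area in cm^2: `vessel_area + n_slides * slide_area`.
#' @export
total_area <- function(geometry = reactor_geometry()) {
  stopifnot(inherits(geometry, "reactor_geometry"))
  geometry$vessel_area + geometry$n_slides * geometry$slide_area
}

#' Convert areal protein to a cell count
#'
#' `areal_protein [µg/cm^2] * area [cm^2] * 1e9 [fg/µg] / protein_per_cell
#' [fg/cell]`.
#'
#' @param areal_protein Areal protein density (µg/cm^2); vectorized.
#' @param area Surface area (cm^2).
#' @param constants A [conversion_constants()].
#' @return Cell count(s).
#' @examples
#' cells_from_protein(4.5, 336) # ~5.4e9
#' @export
cells_from_protein <- function(areal_protein, area = total_area(),
                               constants = conversion_constants()) {
  stopifnot(inherits(constants, "conversion_constants"))
  if (any(areal_protein < 0) || area <= 0) abort("Inputs must be non-negative (area positive).")
  areal_protein * area * 1e9 / constants$protein_per_cell
}

#' Biofilm-producing subpopulation
#'
#' @param total Total cell count; vectorized.
#' @param non_producer_fraction Fraction of cells unable to produce biofilm,
#'   in `[0, 1)`.
#' @return `total * (1 - non_producer_fraction)`.
#' @export
producer_cells <- function(total, non_producer_fraction = 0) {
  assert_scalar_number(non_producer_fraction, "non_producer_fraction",
    min = 0, max = 1 - 1e-12
  )
  total * (1 - non_producer_fraction)
}

#' Number of doublings in an elapsed time
#'
#' @param elapsed_time Elapsed time (h); total residence including any batch
#'   lead; vectorized.
#' @param generation_time Doubling time (h).
#' @param mode `"nearest"` (default; 120 h at 6.8 h/generation gives 18),
#'   `"floor"`, or `"continuous"` (the unrounded quotient).
#' @return Doubling count(s).
#' @examples
#' count_doublings(120, 6.8) # 18
#' @export
count_doublings <- function(elapsed_time, generation_time,
                            mode = c("nearest", "floor", "continuous")) {
  mode <- match.arg(mode)
  if (any(elapsed_time < 0)) abort("`elapsed_time` must be non-negative.")
  assert_scalar_number(generation_time, "generation_time", positive = TRUE)
  q <- elapsed_time / generation_time
  switch(mode, nearest = round(q), floor = floor(q), continuous = q)
}

#' Back-calculate the founder population of a biofilm
#'
#' Chains the conversion from an observed areal protein density to the
#' minimal number of biofilm-producing cells that must have been present at
#' time zero: areal protein -> total cells (via surface area and protein per
#' cell) -> producing cells (discounting known non-producers) -> founders =
#' producers / 2^doublings. With the default geometry and constants, 4.5
#' µg/cm^2 after 120 h at a 6.8-h generation time and 24% non-producers
#' gives ~1.6e4 founders. Observations below the detection limit are refused
#' rather than imputed.
#'
#' @param areal_protein Observed areal protein (µg/cm^2).
#' @param elapsed_time Total residence time (h), including any batch lead.
#' @param generation_time Doubling time (h).
#' @param non_producer_fraction Fraction of the biofilm that cannot produce
#'   biofilm on its own.
#' @param geometry A [reactor_geometry()].
#' @param constants A [conversion_constants()].
#' @param rounding Doubling rounding mode (see [count_doublings()]).
#' @return An object of class `founder_backcalc`; see [tidy.founder_backcalc()].
#' @examples
#' fit <- back_calculate_founders(4.5, 120, 6.8, 0.24)
#' glance(fit)
#' @export
back_calculate_founders <- function(areal_protein, elapsed_time, generation_time,
                                    non_producer_fraction = 0,
                                    geometry = reactor_geometry(),
                                    constants = conversion_constants(),
                                    rounding = c("nearest", "floor", "continuous")) {
  rounding <- match.arg(rounding)
  assert_scalar_number(areal_protein, "areal_protein", positive = TRUE)
  assert_scalar_number(elapsed_time, "elapsed_time", min = 0)
  if (areal_protein < constants$detection_limit) {
    abort(sprintf(
      "Censored input: areal protein %.3g is below the detection limit %.3g ug/cm^2.",
      areal_protein, constants$detection_limit
    ))
  }
  area <- total_area(geometry)
  total <- cells_from_protein(areal_protein, area, constants)
  producers <- producer_cells(total, non_producer_fraction)
  doublings <- count_doublings(elapsed_time, generation_time, rounding)
  founders <- producers / 2^doublings
  structure(
    list(
      areal_protein = areal_protein, elapsed_time = elapsed_time,
      generation_time = generation_time,
      non_producer_fraction = non_producer_fraction,
      area = area, total_cells = total, producer_cells = producers,
      doublings = doublings, founder_cells = founders, rounding = rounding,
      geometry = geometry, constants = constants
    ),
    class = "founder_backcalc"
  )
}

#' @export
print.founder_backcalc <- function(x, ...) {
  cat("Biofilm founder back-calculation\n")
  cat(sprintf(
    "  %.3g ug/cm^2 over %g cm^2  ->  %s cells\n",
    x$areal_protein, x$area, format_sig2(x$total_cells)
  ))
  cat(sprintf(
    "  minus %g%% non-producers    ->  %s producing cells\n",
    100 * x$non_producer_fraction, format_sig2(x$producer_cells)
  ))
  cat(sprintf(
    "  %g h at %g h/doubling      ->  %s doublings (%s)\n",
    x$elapsed_time, x$generation_time, format(x$doublings), x$rounding
  ))
  cat(sprintf("  founders: %s cells\n", format_sig2(x$founder_cells)))
  invisible(x)
}

#' Tidy a founder back-calculation
#'
#' @param x A `founder_backcalc` object.
#' @param ... Unused.
#' @return `tidy()`: one row per quantity in the chain with `quantity`,
#'   `value`, `units`, and the two-significant-figure string `reported`.
#'   `glance()`: a one-row tibble of the headline numbers.
#' @export
tidy.founder_backcalc <- function(x, ...) {
  tibble::tibble(
    quantity = c(
      "areal_protein", "total_area", "total_cells", "producer_cells",
      "doublings", "founder_cells"
    ),
    value = c(
      x$areal_protein, x$area, x$total_cells, x$producer_cells,
      x$doublings, x$founder_cells
    ),
    units = c("ug/cm^2", "cm^2", "cells", "cells", "doublings", "cells"),
    reported = c(
      format(x$areal_protein), format(x$area), format_sig2(x$total_cells),
      format_sig2(x$producer_cells), format(x$doublings),
      format_sig2(x$founder_cells)
    )
  )
}

#' @rdname tidy.founder_backcalc
#' @export
glance.founder_backcalc <- function(x, ...) {
  tibble::tibble(
    total_cells = x$total_cells, producer_cells = x$producer_cells,
    doublings = x$doublings, founder_cells = x$founder_cells,
    rounding = x$rounding
  )
}

#' Back-calculate founders along a reactor trajectory
#'
#' Applies [back_calculate_founders()] to every uncensored observation of a
#' trajectory table, e.g. the output of [simulate_reactor()].
#'
#' @param trajectory Data frame with `time_h`, `protein_ug_per_cm2`,
#'   `censored`.
#' @param generation_time,non_producer_fraction,geometry,constants,rounding
#'   Passed to [back_calculate_founders()].
#' @return The uncensored rows with `founder_cells`, `total_cells`,
#'   `doublings` columns appended.
#' @export
back_calculate_trajectory <- function(trajectory, generation_time,
                                      non_producer_fraction = 0,
                                      geometry = reactor_geometry(),
                                      constants = conversion_constants(),
                                      rounding = "continuous") {
  trajectory <- tibble::as_tibble(trajectory)
  keep <- !trajectory$censored & trajectory$time_h > 0
  rows <- trajectory[keep, ]
  est <- purrr::map(seq_len(nrow(rows)), function(i) {
    back_calculate_founders(
      rows$protein_ug_per_cm2[i], rows$time_h[i], generation_time,
      non_producer_fraction, geometry, constants, rounding
    )
  })
  dplyr::mutate(rows,
    total_cells = purrr::map_dbl(est, "total_cells"),
    doublings = purrr::map_dbl(est, "doublings"),
    founder_cells = purrr::map_dbl(est, "founder_cells")
  )
}

#' Dilution rate of a continuous reactor
#'
#' `D = flow * 60 / volume` (flow in ml/min, volume in ml, D in 1/h). A
#' dilution rate above the planktonic growth rate `ln(2)/generation_time`
#' washes suspended cells out of the vessel.
#'
#' @param flow Medium flow rate (ml/min).
#' @param volume Working volume (ml).
#' @return Dilution rate (1/h).
#' @examples
#' dilution_rate(0.95, 375) # 0.152
#' @export
dilution_rate <- function(flow, volume) {
  if (any(flow <= 0) || any(volume <= 0)) abort("Inputs must be positive.")
  flow * 60 / volume
}

#' @rdname dilution_rate
#' @param D Dilution rate (1/h).
#' @return `infer_volume()`: working volume in ml.
#' @examples
#' infer_volume(0.70, 0.112) # 375
#' @export
infer_volume <- function(flow, D) {
  if (any(flow <= 0) || any(D <= 0)) abort("Inputs must be positive.")
  flow * 60 / D
}

#' Planktonic washout advisory
#'
#' @param D Dilution rate (1/h).
#' @param generation_time Doubling time (h).
#' @return `TRUE` when `D > ln(2)/generation_time`, i.e. suspended cells
#'   cannot grow fast enough to persist (advisory only; biofilm is retained
#'   regardless).
#' @export
washout_flag <- function(D, generation_time) {
  D > log(2) / generation_time
}
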