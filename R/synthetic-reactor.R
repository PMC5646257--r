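#' Parameters of a simulated biofilm reactor
#'
#' Bundles geometry, conversion constants, growth parameters and the
#' carrying capacity of the forward biofilm model. Defaults mirror a
#' CDC-style reactor: 231 cm^2 of vessel wall plus seven 15-cm^2 slides,
#' 278 fg protein/cell, a 6.8-h generation time, a 24-h batch lead before
#' continuous flow, a 1.3 µg/cm^2 detection limit, and a carrying capacity
#' of 400 µg/cm^2 (the order of observed steady-state biofilm).
#'
#' @param vessel_area,slide_area,n_slides See [reactor_geometry()].
#' @param protein_per_cell,detection_limit See [conversion_constants()].
#' @param generation_time Doubling time (h).
#' @param batch_lead Batch growth period before continuous flow (h).
#' @param carrying_capacity Areal protein ceiling (µg/cm^2); must exceed the
#'   detection limit.
#' @param seed Integer seed (reserved for stochastic extensions; the default
#'   forward model is deterministic).
#' @return A list of class `reactor_params`.
#' @export
reactor_params <- function(vessel_area = 231, slide_area = 15, n_slides = 7,
                           protein_per_cell = 278, generation_time = 6.8,
                           batch_lead = 24, detection_limit = 1.3,
                           carrying_capacity = 400, seed = NULL) {
  geometry <- reactor_geometry(vessel_area, slide_area, n_slides)
  constants <- conversion_constants(protein_per_cell, detection_limit)
  assert_scalar_number(generation_time, "generation_time", positive = TRUE)
  assert_scalar_number(batch_lead, "batch_lead", min = 0)
  assert_scalar_number(carrying_capacity, "carrying_capacity", positive = TRUE)
  if (detection_limit >= carrying_capacity) {
    abort("`detection_limit` must be below `carrying_capacity`.")
  }
  structure(
    list(
      geometry = geometry, constants = constants,
      generation_time = generation_time, batch_lead = batch_lead,
      carrying_capacity = carrying_capacity, seed = seed
    ),
    class = "reactor_params"
  )
}

#' Simulate a biofilm growth trajectory
#'
#' Forward model inverse to [back_calculate_founders()]: the biofilm
#' population doubles every `generation_time` hours from `founders` cells at
#' time zero (total residence time, so any batch lead is already inside the
#' clock) until the areal protein reaches the carrying capacity. Areal
#' protein is `cells * protein_per_cell / total area`; observations below
#' the detection limit are flagged `censored` and their protein value is
#' reported as `NA` rather than a number.
#'
#' @param params A [reactor_params()].
#' @param founders Founding cell count (>= 0).
#' @param duration Trajectory length (h); must be positive.
#' @param sample_every Sampling interval (h).
#' @return Tibble: `time_h`, `cells`, `protein_ug_per_cm2` (`NA` when
#'   censored), `censored`, `at_capacity`.
#' @examples
#' simulate_reactor(reactor_params(), founders = 1.6e4, duration = 144)
#' @export
simulate_reactor <- function(params = reactor_params(), founders, duration,
                             sample_every = 12) {
  stopifnot(inherits(params, "reactor_params"))
  if (founders < 0) abort("`founders` must be >= 0.")
  if (duration <= 0) abort("`duration` must be positive.")
  assert_scalar_number(sample_every, "sample_every", positive = TRUE)
  area <- total_area(params$geometry)
  cap_cells <- params$carrying_capacity * area * 1e9 / params$constants$protein_per_cell
  time_h <- seq(0, duration, by = sample_every)
  cells <- pmin(founders * 2^(time_h / params$generation_time), cap_cells)
  areal <- cells * params$constants$protein_per_cell / (area * 1e9)
  censored <- areal < params$constants$detection_limit
  tibble::tibble(
    time_h = time_h,
    cells = cells,
    protein_ug_per_cm2 = ifelse(censored, NA_real_, areal),
    censored = censored,
    at_capacity = cells >= cap_cells
  )
}

#' Plot a reactor trajectory
#'
#' @param trajectory Output of [simulate_reactor()] or a trajectory table
#'   read with [read_trajectory()].
#' @param detection_limit Detection limit drawn as a dashed line (µg/cm^2).
#' @return A ggplot: areal protein over time on a log axis, censored
#'   observations shown at the detection limit as open triangles.
#' @export
plot_trajectory <- function(trajectory, detection_limit = 1.3) {
  trajectory <- tibble::as_tibble(trajectory)
  shown <- dplyr::mutate(trajectory,
    value = ifelse(.data$censored, detection_limit, .data$protein_ug_per_cm2)
  )
  ggplot2::ggplot(shown, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_hline(
      yintercept = detection_limit,
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::geom_line(data = dplyr::filter(shown, !.data$censored)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$censored), size = 2) +
    ggplot2::scale_shape_manual(
      values = c(`FALSE` = 16, `TRUE` = 2),
      labels = c(`FALSE` = "quantified", `TRUE` = "below detection"),
      name = NULL
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Time in reactor (h)",
      y = expression("Areal protein (" * mu * "g/cm"^2 * ")")
    ) +
    ggplot2::theme_minimal()
}
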