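#' Estimate the generation time from batch growth data
#'
#' Fits `ln(OD)` against time over an exponential-phase window and returns
#' the doubling time `ln(2)/slope`. The window is either user-supplied or
#' detected automatically: among all contiguous windows of at least
#' `min_window` points (default: half the usable points), the fit with the
#' highest R-squared wins, longer windows breaking ties.
#'
#' @param growth Data frame with columns `time_h` and `od`.
#' @param od_floor Observations at or below this OD are excluded (default
#'   0.01, the practical blank level of a spectrophotometer).
#' @param window Optional two-element numeric `(t_min, t_max)` restricting
#'   the fit to a time range; disables the automatic search.
#' @param min_window Minimum points per candidate window in the automatic
#'   search.
#' @return An object of class `generation_fit` with `generation_time` (h),
#'   `growth_rate` (1/h), `r_squared`, the window bounds, and the fitted
#'   points; see [tidy.generation_fit()].
#' @examples
#' g <- tibble::tibble(time_h = seq(0, 40, 4), od = 0.02 * 2^(time_h / 6.8))
#' glance(fit_generation_time(g))$generation_time
#' @export
fit_generation_time <- function(growth, od_floor = 0.01, window = NULL,
                                min_window = NULL) {
  growth <- tibble::as_tibble(growth)
  stopifnot(all(c("time_h", "od") %in% names(growth)))
  if (!is.null(window)) {
    stopifnot(length(window) == 2L)
    in_win <- growth$time_h >= window[1] & growth$time_h <= window[2]
    if (any(in_win & (is.na(growth$od) | growth$od <= 0))) {
      abort("Non-positive OD inside the requested window.")
    }
  }
  usable <- growth[!is.na(growth$od) & growth$od > od_floor, ]
  usable <- usable[order(usable$time_h), ]
  if (!is.null(window)) {
    usable <- usable[usable$time_h >= window[1] & usable$time_h <= window[2], ]
  }
  n <- nrow(usable)
  if (n < 3L) abort("Fewer than 3 usable points above the OD floor.")
  y <- log(usable$od)
  t <- usable$time_h

  fit_range <- function(i, j) {
    tt <- t[i:j]
    yy <- y[i:j]
    f <- stats::lm.fit(cbind(1, tt), yy)
    ss_res <- sum(f$residuals^2)
    ss_tot <- sum((yy - mean(yy))^2)
    list(
      slope = unname(f$coefficients[2]),
      r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 0
    )
  }

  if (!is.null(window)) {
    best <- c(1L, n)
    bf <- fit_range(1L, n)
  } else {
    min_window <- min_window %||% max(3L, ceiling(n / 2))
    best <- NULL
    bf <- NULL
    for (i in seq_len(n - min_window + 1L)) {
      for (j in seq(i + min_window - 1L, n)) {
        f <- fit_range(i, j)
        better <- is.null(bf) ||
          f$r2 > bf$r2 + 1e-9 ||
          (abs(f$r2 - bf$r2) <= 1e-9 && (j - i) > (best[2] - best[1]))
        if (better) {
          best <- c(i, j)
          bf <- f
        }
      }
    }
  }
  # slopes at numerical-noise level are no growth, not slow growth
  if (!is.finite(bf$slope) || bf$slope <= 1e-8) {
    abort("No exponential growth detected (non-positive slope of ln(OD)).")
  }
  structure(
    list(
      generation_time = log(2) / bf$slope,
      growth_rate = bf$slope,
      r_squared = bf$r2,
      window_start = t[best[1]], window_end = t[best[2]],
      n_points = best[2] - best[1] + 1L,
      data = usable,
      in_window = seq_len(n) >= best[1] & seq_len(n) <= best[2]
    ),
    class = "generation_fit"
  )
}

#' @export
print.generation_fit <- function(x, ...) {
  cat(sprintf(
    "Generation time %.3g h (growth rate %.4g /h, R^2 %.4f, %d points, window %g-%g h)\n",
    x$generation_time, x$growth_rate, x$r_squared, x$n_points,
    x$window_start, x$window_end
  ))
  invisible(x)
}

#' Tidy a generation-time fit
#'
#' @param x A `generation_fit` object.
#' @param ... Unused.
#' @return `tidy()`: the fitted points with an `in_window` flag.
#'   `glance()`: one-row tibble with `generation_time`, `growth_rate`,
#'   `r_squared`, `n_points`, `window_start`, `window_end`.
#' @export
tidy.generation_fit <- function(x, ...) {
  dplyr::mutate(x$data, in_window = x$in_window)
}

#' @rdname tidy.generation_fit
#' @export
glance.generation_fit <- function(x, ...) {
  tibble::tibble(
    generation_time = x$generation_time, growth_rate = x$growth_rate,
    r_squared = x$r_squared, n_points = x$n_points,
    window_start = x$window_start, window_end = x$window_end
  )
}

#' @export
autoplot.generation_fit <- function(object, ...) {
  pts <- tidy(object)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$time_h, y = .data$od)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$in_window)) +
    ggplot2::geom_function(
      fun = function(t) {
        exp(object$growth_rate * (t - object$window_start)) *
          pts$od[pts$time_h == object$window_start][1]
      },
      linetype = "dashed"
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "black", `FALSE` = "grey60"),
      name = "in fit window"
    ) +
    ggplot2::labs(x = "Time (h)", y = "OD600") +
    ggplot2::theme_minimal()
}
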