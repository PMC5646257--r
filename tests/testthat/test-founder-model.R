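test_that("surface area sums vessel and slides", {
  expect_equal(total_area(reactor_geometry()), 336)
  expect_equal(total_area(reactor_geometry(n_slides = 0)), 231)
  expect_equal(total_area(reactor_geometry(100, 10, 3)), 130)
})

test_that("protein-to-cell conversion is linear with the right units", {
  cells <- cells_from_protein(4.5, 336)
  expect_equal(signif(cells, 2), 5.4e9)
  expect_equal(cells_from_protein(0, 336), 0)
  expect_equal(cells_from_protein(9.0, 336), 2 * cells)
  # unit audit: scaling protein_per_cell by k scales cells by 1/k
  k <- 3.7
  expect_equal(
    cells_from_protein(4.5, 336, conversion_constants(protein_per_cell = 278 * k)),
    cells / k
  )
})

test_that("producer discounting and doubling counts", {
  expect_equal(signif(producer_cells(5.44e9, 0.24), 2), 4.1e9)
  expect_equal(producer_cells(100, 0), 100)
  expect_equal(producer_cells(100, 0.5), 50)
  expect_equal(count_doublings(120, 6.8), 18)
  expect_equal(count_doublings(13.6, 6.8), 2)
  expect_equal(count_doublings(120, 6.8, "continuous"), 120 / 6.8)
  expect_equal(count_doublings(120, 6.8, "floor"), 17)
})

test_that("the founder back-calculation chains all conversions", {
  fit <- back_calculate_founders(4.5, 120, 6.8, 0.24)
  expect_equal(fit$area, 336)
  expect_equal(signif(fit$total_cells, 2), 5.4e9)
  expect_equal(signif(fit$producer_cells, 2), 4.1e9)
  expect_equal(fit$doublings, 18)
  expect_equal(signif(fit$founder_cells, 2), 1.6e4)
  td <- tidy(fit)
  expect_equal(td$reported[td$quantity == "founder_cells"], "1.6e+04")
  expect_equal(nrow(glance(fit)), 1)
  # zero elapsed time in continuous mode: founders equal producers
  f0 <- back_calculate_founders(4.5, 0, 6.8, 0, rounding = "continuous")
  expect_equal(f0$founder_cells, f0$producer_cells)
})

test_that("censored observations are refused for inference", {
  expect_error(back_calculate_founders(1.0, 120, 6.8), "Censored")
  expect_error(
    back_calculate_founders(0.5, 120, 6.8,
      constants = conversion_constants(detection_limit = 0.4)
    ),
    NA
  )
})

test_that("founders decrease with time and increase with protein", {
  f <- function(p, t) {
    back_calculate_founders(p, t, 6.8, rounding = "continuous")$founder_cells
  }
  times <- seq(24, 144, by = 12)
  est <- vapply(times, function(t) f(4.5, t), numeric(1))
  expect_true(all(diff(est) < 0))
  prot <- seq(1.5, 30, by = 1.5)
  est2 <- vapply(prot, function(p) f(p, 120), numeric(1))
  expect_true(all(diff(est2) > 0))
})

test_that("dilution-rate conversions invert each other", {
  expect_equal(infer_volume(0.70, 0.112), 375)
  expect_equal(round(dilution_rate(0.95, 375), 3), 0.152)
  for (flow in c(0.3, 0.7, 1.2)) {
    v <- infer_volume(flow, 0.13)
    expect_equal(dilution_rate(flow, v), 0.13)
  }
  expect_error(dilution_rate(0, 100), "positive")
})

test_that("washout advisory compares dilution to growth rate", {
  expect_true(washout_flag(0.152, 6.8)) # ln2/6.8 = 0.102
  expect_false(washout_flag(0.05, 6.8))
})
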