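test_that("frequency and strand bias follow their definitions", {
  expect_equal(estimate_frequency(0, 50), 0)
  expect_equal(estimate_frequency(34, 50), 0.68)
  expect_equal(estimate_frequency(50, 50), 1)
  expect_error(estimate_frequency(5, 0), "depth")

  expect_equal(strand_bias(7, 7), 0.5)
  expect_equal(strand_bias(14, 1), 14 / 15)
  expect_equal(strand_bias(0, 9), 1)
  expect_error(strand_bias(0, 0), "undefined")
})

test_that("the acceptance rule passes and fails the canonical cases", {
  th <- filter_thresholds()
  # 6% frequency, balanced strands: below the 10% rule
  low <- call_variants(obs_row(3, 50, 2), th)
  expect_false(low$passed)
  expect_equal(low$fail_reason, "below_min_frequency")
  # 23.4% with 14/1 strand split: strand artifact
  biased <- call_variants(obs_row(15, 64, 14), th)
  expect_false(biased$passed)
  expect_equal(biased$fail_reason, "strand_biased")
  # 90% all-forward: strand clause waived at/above 80%
  fixed <- call_variants(obs_row(45, 50, 45), th)
  expect_true(fixed$passed)
  expect_equal(fixed$fail_reason, "none")
  # boundary: exactly 10% passes, just under fails
  expect_true(call_variants(obs_row(5, 50, 3), th)$passed)
  expect_false(call_variants(obs_row(4, 41, 2), th)$passed)
  # boundary: bias exactly 0.70 fails (strict comparison)
  expect_false(call_variants(obs_row(10, 40, 7), th)$passed)
  expect_true(call_variants(obs_row(10, 40, 6), th)$passed)
})

test_that("the rule agrees with clause-by-clause evaluation on all small pileups", {
  cases <- list()
  for (d in 1:30) {
    for (a in 0:d) {
      for (f in 0:a) {
        cases[[length(cases) + 1L]] <- c(a, d, f)
      }
    }
  }
  m <- do.call(rbind, cases)
  tbl <- tibble::tibble(
    sample = "s", pos = seq_len(nrow(m)), ref = "G", alt = "C",
    depth = m[, 2], alt_depth = m[, 1], alt_fwd = m[, 3],
    alt_rev = m[, 1] - m[, 3]
  )
  got <- call_variants(tbl)$passed
  want <- vapply(
    seq_len(nrow(m)),
    function(i) oracle_filter_pass(m[i, 1], m[i, 2], m[i, 3]),
    logical(1)
  )
  expect_identical(got, want)
})

test_that("passing is monotone in alt depth at fixed depth and strand ratio", {
  th <- filter_thresholds()
  for (d in c(20L, 50L, 63L)) {
    passed <- vapply(0:d, function(a) {
      f <- round(a / 2)
      call_variants(obs_row(a, d, f), th)$passed
    }, logical(1))
    # once passing, stays passing for larger alt depth
    expect_true(all(diff(as.integer(passed)) >= 0))
  }
})

test_that("degenerate and malformed inputs are rejected", {
  expect_error(call_variants(obs_row(5, 0, 2)), "depth")
  bad <- obs_row(5, 50, 2, alt_rev = 1) # 2 + 1 != 5
  expect_error(call_variants(bad), "alt_fwd")
  expect_error(filter_thresholds(min_frequency = 0.9, high_frequency_cutoff = 0.8))
  empty <- call_variants(obs_row(5, 50, 2)[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("frequency", "passed", "fail_reason") %in% names(empty)))
})
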