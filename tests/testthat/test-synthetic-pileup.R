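test_that("fixed variants at full depth give frequency exactly 1", {
  plan <- pileup_plan(
    samples = "s1",
    variants = planted_variants(100, "G", "C", true_frequency = 1.0),
    mean_depth = 50, depth_model = "fixed", noise_rate = 0, seed = 1
  )
  out <- simulate_pileup(plan)
  expect_equal(out$depth, 50)
  expect_equal(out$alt_depth, 50)
  expect_equal(estimate_frequency(out$alt_depth, out$depth), 1.0)
})

test_that("an empty plan yields an empty observation table", {
  plan <- pileup_plan(samples = c("a", "b"), noise_rate = 0, seed = 1)
  out <- simulate_pileup(plan)
  expect_equal(nrow(out), 0)
  expect_true(all(c("sample", "pos", "ref", "alt", "depth") %in% names(out)))
})

test_that("identical plans and seeds give identical pileups", {
  mk <- function() {
    simulate_pileup(pileup_plan(
      samples = c("a", "b", "c"),
      variants = planted_variants(c(10, 500, 900), "G", "C", c(0.3, 0.6, 1)),
      noise_rate = 0.01, region_length = 1000, seed = 99
    ))
  }
  expect_identical(mk(), mk())
})

test_that("sampled frequencies are binomial around the planted truth", {
  freqs <- vapply(1:200, function(s) {
    out <- simulate_pileup(pileup_plan(
      samples = "s1",
      variants = planted_variants(10, "A", "T", 0.68),
      mean_depth = 50, depth_model = "fixed", noise_rate = 0, seed = s
    ))
    out$alt_depth / out$depth
  }, numeric(1))
  se <- sqrt(0.68 * 0.32 / 50) / sqrt(200)
  expect_lt(abs(mean(freqs) - 0.68), 3 * se)
})

test_that("strand splits are binomial in the skew", {
  out <- simulate_pileup(pileup_plan(
    samples = "s1",
    variants = planted_variants(
      position = seq(10, 2000, by = 10), ref = "A", alt = "T",
      true_frequency = 1, strand_skew = 0.9
    ),
    mean_depth = 63, depth_model = "fixed", noise_rate = 0, seed = 2
  ))
  expect_equal(out$alt_fwd + out$alt_rev, out$alt_depth)
  share <- sum(out$alt_fwd) / sum(out$alt_depth)
  expect_lt(abs(share - 0.9), 0.01)
})

test_that("noise sites stay below the 10% rule in truth", {
  plan <- pileup_plan(
    samples = c("a", "b"),
    noise_rate = 0.05, region_length = 2000, seed = 31
  )
  out <- simulate_pileup(plan)
  noise <- out[out$true_frequency > 0, ]
  expect_gt(nrow(noise), 0)
  expect_true(all(noise$true_frequency >= 0.01 & noise$true_frequency <= 0.08))
  expect_true(all(!out$planted))
})

test_that("overlapping planted variants in one sample are rejected", {
  expect_error(
    pileup_plan(
      samples = "s1",
      variants = planted_variants(c(100, 100), c("G", "G"), c("C", "T"), c(0.5, 0.5))
    ),
    "Overlapping"
  )
  # an MNV overlapping a downstream SNV is also an overlap
  expect_error(
    pileup_plan(
      samples = "s1",
      variants = planted_variants(c(100, 101), c("GC", "C"), c("CT", "T"), c(0.5, 0.5))
    ),
    "Overlapping"
  )
  # same position in different samples is fine
  plan <- pileup_plan(
    samples = c("s1", "s2"),
    variants = planted_variants(c(100, 100), c("G", "G"), c("C", "T"), c(0.5, 0.5),
      samples = list("s1", "s2")
    ),
    noise_rate = 0, seed = 1
  )
  expect_s3_class(plan, "pileup_plan")
})

test_that("the filter recovers nearly all planted variants at adequate depth", {
  hits <- 0L
  total <- 0L
  for (s in 1:100) {
    freqs <- withr::with_seed(1000 + s, runif(12, 0.2, 1))
    out <- simulate_pileup(pileup_plan(
      samples = "s1",
      variants = planted_variants(
        position = seq(100, 1200, by = 100), ref = "G", alt = "A",
        true_frequency = freqs
      ),
      mean_depth = 63, depth_model = "poisson", noise_rate = 0, seed = s
    ))
    out <- out[out$depth >= 50, ]
    calls <- call_variants(out)
    hits <- hits + sum(calls$passed)
    total <- total + nrow(calls)
  }
  expect_gte(hits / total, 0.95)
})
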