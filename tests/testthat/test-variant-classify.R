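strains3 <- c(MT_batch = "MT", MO_batch = "MO", MO_biofilm = "MO")

calls_for <- function(pass_in, pos = 100L) {
  samples <- names(strains3)
  call_variants(tibble::tibble(
    sample = samples, pos = pos, ref = "G", alt = "C",
    depth = 60L,
    alt_depth = ifelse(samples %in% pass_in, 58L, 0L),
    alt_fwd = ifelse(samples %in% pass_in, 29L, 0L),
    alt_rev = ifelse(samples %in% pass_in, 29L, 0L)
  ))
}

test_that("cross-sample labels follow the passing pattern", {
  cls <- function(pass_in) {
    classify_variants(calls_for(pass_in), strains3, emergent_samples = "MO_biofilm")
  }
  expect_equal(cls(c("MT_batch", "MO_batch", "MO_biofilm"))$label, "shared_all")
  mo <- cls(c("MO_batch", "MO_biofilm"))
  expect_equal(mo$label, "strain_unique")
  expect_equal(mo$strain, "MO")
  bio <- cls("MO_biofilm")
  expect_equal(bio$label, "emergent")
  expect_equal(bio$strain, "MO")
  expect_equal(cls(c("MT_batch", "MO_batch"))$label, "other")
  expect_equal(cls(character())$label, "other")
  # without a designated later sample, a biofilm-only variant is strain-unique
  expect_equal(
    classify_variants(calls_for("MO_biofilm"), strains3)$label,
    "strain_unique"
  )
})

test_that("every variant key receives exactly one label", {
  set.seed(11)
  plan <- pileup_plan(
    samples = names(strains3),
    variants = planted_variants(
      position = seq(1000, 9000, by = 1000),
      ref = "A", alt = "G",
      true_frequency = runif(9, 0.05, 1),
      samples = replicate(9, sample(names(strains3), sample(3, 1)), simplify = FALSE)
    ),
    noise_rate = 0.001, region_length = 10000, seed = 23
  )
  calls <- call_variants(simulate_pileup(plan))
  out <- classify_variants(calls, strains3, emergent_samples = "MO_biofilm")
  keys <- unique(calls[c("pos", "ref", "alt")])
  expect_equal(nrow(out), nrow(keys))
  expect_true(all(out$label %in% c("shared_all", "strain_unique", "emergent", "other")))
})

test_that("unknown samples and undersized designs are rejected", {
  calls <- calls_for("MO_batch")
  expect_error(classify_variants(calls, c(MO_batch = "MO", MO_biofilm = "MO")),
    "not in strain map"
  )
  expect_error(classify_variants(calls, c(s = "MO")), "not in strain map")
  one <- call_variants(obs_row(50, 60, 25))
  expect_error(classify_variants(one, c(s1 = "MO")), ">= 2 samples")
})
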