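test_that("cysteine counting and Gly/Ala segment detection", {
  expect_equal(count_cysteines("ACDC"), 2)
  expect_equal(count_cysteines("acdc"), 2)
  expect_equal(count_cysteines(c("AAAA", "CCCC")), c(0, 4))

  seg <- find_glyala_segments(strrep("G", 30), window = 30, min_fraction = 0.4)
  expect_equal(nrow(seg), 1)
  expect_equal(c(seg$start, seg$end), c(1, 30))
  none <- find_glyala_segments(strrep("KDEST", 20), window = 30, min_fraction = 0.4)
  expect_equal(nrow(none), 0)
  # a planted Gly-rich block inside a GA-free background is recovered
  set.seed(8)
  bg <- paste(sample(c("K", "D", "E", "S", "T", "V"), 200, replace = TRUE), collapse = "")
  seq <- paste0(substr(bg, 1, 80), strrep("GA", 25), substr(bg, 81, 200))
  seg2 <- find_glyala_segments(seq, window = 30, min_fraction = 0.4)
  expect_equal(nrow(seg2), 1)
  expect_true(seg2$start <= 131 && seg2$end >= 81 + 20)
  expect_error(find_glyala_segments("GGG", window = 30), "exceeds")
})

test_that("planted cargo are recovered and decoys rejected", {
  prot <- simulate_proteome(
    n_decoys = 12,
    cargo = list(
      planted_cargo(3038, 4, n_cys = 0),
      planted_cargo(2414, 3, n_cys = 3)
    ),
    seed = 7
  )
  rep <- screen_proteome(prot)
  expect_equal(sum(rep$verdict == "candidate"), 2)
  expect_identical(
    rep$id[rep$verdict == "candidate"],
    prot$id[prot$is_cargo]
  )
  cand <- rep[rep$verdict == "candidate", ]
  expect_equal(cand$n_cys, c(0, 3))
  expect_true(all(cand$pI >= 4.0 & cand$pI <= 4.3))
  expect_true(all(lengths(cand$failed_criteria) == 0))
})

test_that("the verdict is candidate exactly when no criterion failed", {
  prot <- simulate_proteome(10, list(planted_cargo(1200, 2, n_cys = 0)), seed = 3)
  rep <- screen_proteome(prot)
  expect_identical(
    rep$verdict == "candidate",
    lengths(rep$failed_criteria) == 0
  )
})

test_that("N-terminal nonamers do not satisfy the C-terminal window rule", {
  # build a protein whose repeats sit in the N-terminal half
  set.seed(4)
  block <- strrep("GGSGSDSSS", 4)
  bg <- paste(sample(c("D", "E", "S", "T", "V", "L", "N"), 1400, replace = TRUE),
    collapse = ""
  )
  seq <- paste0(substr(bg, 1, 50), block, substr(bg, 51, 1400))
  rep <- screen_proteome(tibble::tibble(id = "p1", sequence = seq))
  expect_equal(rep$verdict, "rejected")
  expect_true("c_term_nonamers" %in% rep$failed_criteria[[1]])
  expect_gt(rep$n_nonamers, 0)
  expect_equal(rep$n_cterm_nonamers, 0)
})

test_that("short proteins are rejected regardless of motifs", {
  seq <- paste0(strrep("D", 100), strrep("GGSGSDSSS", 4))
  rep <- screen_proteome(tibble::tibble(id = "small", sequence = seq))
  expect_equal(rep$verdict, "rejected")
  expect_true("min_length" %in% rep$failed_criteria[[1]])
})

test_that("removing a failed criterion flips the verdict iff nothing else failed", {
  prot <- simulate_proteome(0, list(planted_cargo(1500, 3, n_cys = 2)), seed = 9)
  seq <- prot$sequence[1]
  # push the protein over the cysteine limit only
  rep1 <- screen_proteome(
    tibble::tibble(id = "p", sequence = seq),
    cargo_criteria(max_cysteines = 1)
  )
  expect_identical(rep1$failed_criteria[[1]], "max_cysteines")
  relaxed <- screen_proteome(
    tibble::tibble(id = "p", sequence = seq),
    cargo_criteria(max_cysteines = 5)
  )
  expect_equal(relaxed$verdict, "candidate")
  # two failures: relaxing one still leaves the other
  rep2 <- screen_proteome(
    tibble::tibble(id = "p", sequence = seq),
    cargo_criteria(max_cysteines = 1, min_length = 2000)
  )
  expect_setequal(rep2$failed_criteria[[1]], c("max_cysteines", "min_length"))
  rep3 <- screen_proteome(
    tibble::tibble(id = "p", sequence = seq),
    cargo_criteria(max_cysteines = 5, min_length = 2000)
  )
  expect_identical(rep3$failed_criteria[[1]], "min_length")
})

test_that("reports are independent of record order", {
  prot <- simulate_proteome(6, list(planted_cargo(1200, 2, n_cys = 0)), seed = 12)
  fwd <- screen_proteome(prot)
  rev <- screen_proteome(prot[rev(seq_len(nrow(prot))), ])
  expect_identical(
    dplyr::arrange(fwd, id),
    dplyr::arrange(rev, id)
  )
})
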