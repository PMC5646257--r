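test_that("pattern parsing recovers element structure and spans", {
  p <- parse_prosite_pattern("G-G-x-G-x-D-x-x-x")
  expect_equal(length(p$elements), 9)
  expect_equal(p$min_span, 9)
  expect_equal(p$elements[[1]]$type, "set")
  expect_equal(p$elements[[1]]$residues, "G")
  expect_equal(p$elements[[3]]$type, "any")

  p2 <- parse_prosite_pattern("x(2)")
  expect_equal(p2$min_span, 2)
  expect_equal(nrow(scan_pattern("AC", p2)), 1)

  p3 <- parse_prosite_pattern("D-x-[LI]-x(4)-G")
  expect_equal(p3$min_span, 8)
  expect_equal(p3$elements[[3]]$residues, c("L", "I"))
  expect_equal(p3$elements[[4]]$min, 4)

  p4 <- parse_prosite_pattern("<A-x(2,4)-{PG}-C>.")
  expect_true(p4$n_anchor)
  expect_true(p4$c_anchor)
  expect_equal(p4$elements[[2]]$max, 4)
  expect_equal(p4$elements[[3]]$type, "negset")
})

test_that("malformed patterns raise parse errors naming the element", {
  expect_error(parse_prosite_pattern("G--G"), "element")
  expect_error(parse_prosite_pattern("G-[?]-C"), "element 2")
  expect_error(parse_prosite_pattern("G-x(3,1)"), "repeat")
  expect_error(parse_prosite_pattern(""), "non-empty")
})

test_that("the nonamer repeat matches its canonical instances", {
  hits <- scan_pattern("GGSGDDTIV", nonamer_pattern())
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 1)
  expect_equal(hits$end, 9)
  expect_equal(hits$matched, "GGSGDDTIV")
  # position 6 must be aspartate
  expect_equal(nrow(scan_pattern("GGSGDETIV", nonamer_pattern())), 0)
  # lowercase input matches case-insensitively (as in 'GGsGdDtiv')
  expect_equal(nrow(scan_pattern("ggsgddtiv", nonamer_pattern())), 1)
  # overlapping matches are all reported
  tandem <- strrep("GGSGSDSSS", 3)
  expect_equal(scan_pattern(tandem, nonamer_pattern())$start, c(1, 10, 19))
})

test_that("anchored patterns restrict match offsets", {
  p <- parse_prosite_pattern("<M-x(2)")
  expect_equal(scan_pattern("MABMCD", p)$start, 1)
  q <- parse_prosite_pattern("C-x>")
  expect_equal(scan_pattern("CACA", q)$start, 3)
})

test_that("the scanner agrees with a brute-force enumerator on random cases", {
  set.seed(101)
  for (i in 1:200) {
    pat <- parse_prosite_pattern(random_prosite_pattern())
    seq <- random_aa_seq(sample(10:100, 1))
    got <- scan_pattern(seq, pat)[c("start", "end")]
    want <- oracle_scan(seq, pat)
    expect_identical(
      as.data.frame(dplyr::arrange(got, start, end)),
      as.data.frame(want)
    )
  }
})

test_that("the bundled calcium-repeat signature loads and hits tandem repeats", {
  ca <- ca_repeat_pattern()
  expect_s3_class(ca, "prosite_pattern")
  expect_equal(nrow(scan_pattern(strrep("GGSGSDSSS", 2), ca)), 1)
  expect_equal(nrow(scan_pattern("GGSGSDSSS", ca)), 0)
})
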