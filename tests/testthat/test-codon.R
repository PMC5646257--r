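test_that("substitutions at the 635th codon give the known amino-acid changes", {
  cds <- fixture_cds_635()
  snp <- annotate_codon_change(cds, 1903, "G", "C")
  expect_equal(snp$aa_change, "A635P")
  expect_equal(snp$residue_index, 635)
  expect_false(snp$synonymous)
  expect_equal(annotate_codon_change(cds, 1903, "GC", "CT")$aa_change, "A635L")
  expect_equal(annotate_codon_change(cds, 1903, "G", "T")$aa_change, "A635S")
  expect_equal(snp$residue_index, ceiling(1903 / 3))
})

test_that("third-position wobble changes are flagged synonymous", {
  cds <- fixture_cds_635()
  syn <- annotate_codon_change(cds, 1905, "G", "A") # GCG -> GCA
  expect_equal(syn$ref_aa, "A")
  expect_equal(syn$alt_aa, "A")
  expect_true(syn$synonymous)
})

test_that("an MNV spanning a codon boundary yields one row per codon", {
  # codons 2 and 3 of ATG|GCT|GAT...: change T|G across the boundary
  cds <- "ATGGCTGATAAA"
  out <- annotate_codon_change(cds, 6, "TG", "AC")
  expect_equal(nrow(out), 2)
  expect_equal(out$residue_index, c(2, 3))
  expect_equal(out$ref_codon, c("GCT", "GAT"))
  expect_equal(out$alt_codon, c("GCA", "CAT"))
})

test_that("mismatched references and indels are rejected", {
  cds <- fixture_cds_635()
  expect_error(annotate_codon_change(cds, 1903, "A", "C"), "ref mismatch")
  expect_error(annotate_codon_change(cds, 1903, "G", "GT"), "equal length")
  expect_error(annotate_codon_change(cds, nchar(cds), "AA", "TT"), "beyond")
})

test_that("GFF3 CDS parsing validates structure", {
  fx <- fixture_toy_genome()
  cds <- read_gff3_cds(fx$gff_path)
  expect_equal(nrow(cds), 2)
  expect_setequal(cds$gene_id, c("geneA", "geneB"))
  expect_equal(cds$end - cds$start + 1, c(18, 15))

  dir <- withr::local_tempdir()
  bad1 <- file.path(dir, "bad1.gff3")
  writeLines(c("##gff-version 3", "chr1\tt\tCDS\t50\t10\t.\t+\t0\tID=x"), bad1)
  expect_error(read_gff3_cds(bad1), "start > end")
  bad2 <- file.path(dir, "bad2.gff3")
  writeLines(c("##gff-version 3", "chr1\tt\tCDS\t10\t50\t.\t?\t0\tID=x"), bad2)
  expect_error(read_gff3_cds(bad2), "strand")
  bad3 <- file.path(dir, "bad3.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tCDS\t10\t50\t.\t+\t0\tID=x;locus_tag=g",
    "chr1\tt\tCDS\t40\t80\t.\t+\t0\tID=y;locus_tag=g"
  ), bad3)
  expect_error(read_gff3_cds(bad3), "Overlapping")
  frameless <- file.path(dir, "frameless.gff3")
  writeLines(c("##gff-version 3", "chr1\tt\tCDS\t10\t50\t.\t+\t0\tID=x"), frameless)
  expect_warning(read_gff3_cds(frameless), "multiple of 3")
})

test_that("minus-strand genes are annotated via the reverse complement", {
  fx <- fixture_toy_genome()
  cds <- suppressWarnings(read_gff3_cds(fx$gff_path))
  expect_equal(cds_sequence(cds, fx$genome, "geneB"), fx$minus$cds)
  # mutate the genome base pairing with the first base of minus-strand codon 2
  # geneB CDS codon 2 = TTT (F); genome position of its first base:
  gpos <- fx$minus$end - 3L # CDS position 4 on the minus strand
  genome_base <- substr(fx$genome[["chr1"]], gpos, gpos) # "A" (pairs with T)
  expect_equal(genome_base, "A")
  out <- annotate_variants(
    tibble::tibble(pos = gpos, ref = "A", alt = "C"),
    cds, fx$genome
  )
  expect_equal(out$gene_id, "geneB")
  expect_equal(out$cds_position, 4L)
  # T -> G at codon TTT position 1: F2V
  expect_equal(out$aa_change, "F2V")
  # plus-strand gene annotates directly
  out2 <- annotate_variants(
    tibble::tibble(pos = fx$plus$start + 3L, ref = "G", alt = "C"),
    cds, fx$genome
  )
  expect_equal(out2$aa_change, "A2P")
  # intergenic variant: classification columns present, codon fields empty
  out3 <- annotate_variants(
    tibble::tibble(pos = 2L, ref = "T", alt = "C"),
    cds, fx$genome
  )
  expect_true(is.na(out3$gene_id))
  expect_true(is.na(out3$aa_change))
})

test_that("reported substitutions round-trip back to their nucleotide change", {
  # for every SNV in a CDS: apply the reported aa change to the translated
  # protein, then search the codon for the nucleotide edit that produces it
  set.seed(5)
  cds <- paste(sample(c("GCT", "GAA", "TTT", "CGC", "ATG", "TGG"), 30, replace = TRUE),
    collapse = ""
  )
  for (i in 1:25) {
    pos <- sample(nchar(cds), 1)
    ref <- substr(cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    ann <- annotate_codon_change(cds, pos, ref, alt)
    # re-derive: the codon index and within-codon offset recover (pos, ref, alt)
    ci <- ann$residue_index
    offset <- pos - (3 * ci - 2) + 1
    expect_equal(substr(ann$ref_codon, offset, offset), ref)
    expect_equal(substr(ann$alt_codon, offset, offset), alt)
    expect_equal(3 * (ci - 1) + offset, pos)
  }
})
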