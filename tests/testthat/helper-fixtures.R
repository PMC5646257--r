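# Fixtures built in code at test time.

# CDS whose 635th codon is GCG (alanine) so that substitutions at CDS
# position 1903 reproduce the A635P / A635L / A635S worked examples.
fixture_cds_635 <- function() {
  paste0(strrep("ATG", 634), "GCG", strrep("AAA", 12))
}

# Toy two-gene genome (one gene per strand) with a GFF3 file on disk.
# Returns list(genome =, gff_path =, plus =, minus =).
fixture_toy_genome <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  plus_cds <- "ATGGCTGATAAAGGCTAA" # M A D K G *
  minus_cds <- "ATGTTTGCCGAATAA" # M F A E *
  spacer1 <- strrep("T", 10)
  spacer2 <- strrep("C", 8)
  chrom <- paste0(
    spacer1, plus_cds, spacer2,
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(minus_cds))),
    strrep("A", 6)
  )
  plus_start <- nchar(spacer1) + 1L
  plus_end <- plus_start + nchar(plus_cds) - 1L
  minus_start <- plus_end + nchar(spacer2) + 1L
  minus_end <- minus_start + nchar(minus_cds) - 1L
  gff <- c(
    "##gff-version 3",
    sprintf("chr1\ttest\tCDS\t%d\t%d\t.\t+\t0\tID=cds1;locus_tag=geneA", plus_start, plus_end),
    sprintf("chr1\ttest\tCDS\t%d\t%d\t.\t-\t0\tID=cds2;locus_tag=geneB", minus_start, minus_end)
  )
  gff_path <- file.path(dir, "toy.gff3")
  writeLines(gff, gff_path)
  list(
    genome = c(chr1 = chrom), gff_path = gff_path,
    plus = list(cds = plus_cds, start = plus_start, end = plus_end),
    minus = list(cds = minus_cds, start = minus_start, end = minus_end)
  )
}

# Small pileup row constructor for filter tests.
obs_row <- function(alt_depth, depth, alt_fwd, alt_rev = alt_depth - alt_fwd,
                    sample = "s1", pos = 100L, ref = "G", alt = "C") {
  tibble::tibble(
    sample = sample, pos = pos, ref = ref, alt = alt,
    depth = depth, alt_depth = alt_depth, alt_fwd = alt_fwd, alt_rev = alt_rev
  )
}

fixture_growth_curve <- function(generation = 6.8, od0 = 0.02,
                                 times = seq(0, 40, by = 4), sd = 0) {
  tibble::tibble(
    time_h = times,
    od = od0 * 2^(times / generation) + rnorm(length(times), 0, sd)
  )
}
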