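#' Annotate the codon consequence of a substitution within a CDS
#'
#' Takes a coding sequence (already in coding orientation, 5'->3') and a
#' substitution given in CDS coordinates, and reports the affected codon(s).
#' Multi-nucleotide substitutions (equal-length `ref`/`alt` runs such as
#' `GC -> CT`) are supported; a run spanning a codon boundary yields one row
#' per affected codon. Length-changing alleles (indels) are rejected.
#'
#' @param cds_sequence Nucleotide string (A/C/G/T) of the CDS, length a
#'   multiple of 3.
#' @param cds_position 1-based offset of the first substituted base within
#'   the CDS.
#' @param ref,alt Equal-length nucleotide strings; `ref` must match the CDS
#'   at `cds_position`.
#' @param gene_id,strand Optional annotations carried into the output.
#' @return A tibble with one row per affected codon: `gene_id`, `strand`,
#'   `cds_position`, `residue_index`, `ref_codon`, `alt_codon`, `ref_aa`,
#'   `alt_aa`, `aa_change` (e.g. `"A635P"`), and `synonymous`. Translation
#'   uses the standard genetic code (as for bacterial protein-coding genes).
#' @examples
#' cds <- paste0(strrep("ATG", 634), "GCG", strrep("AAA", 10))
#' annotate_codon_change(cds, 1903, "G", "C")$aa_change # "A635P"
#' @export
annotate_codon_change <- function(cds_sequence, cds_position, ref, alt,
                                  gene_id = NA_character_, strand = "+") {
  cds_sequence <- toupper(as.character(cds_sequence))
  ref <- toupper(ref)
  alt <- toupper(alt)
  n <- nchar(ref)
  if (n != nchar(alt)) {
    abort("Unsupported variant: ref and alt must have equal length (substitutions only).")
  }
  if (n < 1L || ref == alt) abort("ref and alt must be non-empty and differ.")
  assert_scalar_number(cds_position, "cds_position", min = 1)
  if (cds_position + n - 1L > nchar(cds_sequence)) {
    abort("Variant extends beyond the CDS.")
  }
  found <- substr(cds_sequence, cds_position, cds_position + n - 1L)
  if (found != ref) {
    abort(sprintf(
      "ref mismatch at CDS position %d: expected '%s', CDS has '%s'.",
      cds_position, ref, found
    ))
  }
  alt_cds <- cds_sequence
  substr(alt_cds, cds_position, cds_position + n - 1L) <- alt

  first_codon <- ceiling(cds_position / 3)
  last_codon <- ceiling((cds_position + n - 1L) / 3)
  purrr::map_dfr(first_codon:last_codon, function(ci) {
    from <- 3L * ci - 2L
    ref_codon <- substr(cds_sequence, from, from + 2L)
    alt_codon <- substr(alt_cds, from, from + 2L)
    ref_aa <- translate_codon(ref_codon)
    alt_aa <- translate_codon(alt_codon)
    tibble::tibble(
      gene_id = gene_id, strand = strand,
      cds_position = max(cds_position, from),
      residue_index = ci,
      ref_codon = ref_codon, alt_codon = alt_codon,
      ref_aa = ref_aa, alt_aa = alt_aa,
      aa_change = paste0(ref_aa, ci, alt_aa),
      synonymous = ref_aa == alt_aa
    )
  })
}

translate_codon <- function(codon) {
  if (grepl("[^ACGT]", codon)) return("X")
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Read CDS intervals from a GFF3 file
#'
#' Parses the `CDS`-typed rows of a GFF3 file into a tidy interval table.
#' Coordinates are 1-based inclusive per the GFF3 specification; the strand
#' column is honored and must be `+` or `-`. Multi-segment CDS (several rows
#' sharing one gene id) are kept as separate rows, ordered in strand
#' direction; overlapping segments of one gene are rejected. A warning is
#' raised when a gene's summed CDS length is not a multiple of 3.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `seqid`, `start`, `end`, `strand`,
#'   `gene_id`, `segment` (rank of the segment in translation order).
#' @export
read_gff3_cds <- function(path) {
  if (!file.exists(path)) abort(paste0("GFF3 file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) abort("GFF3 file contains no feature rows.")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9L)) abort("Malformed GFF3: expected 9 tab-separated columns.")
  m <- do.call(rbind, fields)
  cds <- m[m[, 3] == "CDS", , drop = FALSE]
  if (!nrow(cds)) abort("GFF3 file contains no CDS rows.")
  start <- as.integer(cds[, 4])
  end <- as.integer(cds[, 5])
  strand <- cds[, 7]
  if (any(is.na(start) | is.na(end))) abort("Malformed GFF3: non-numeric coordinates.")
  if (any(start > end)) abort("Malformed GFF3: CDS with start > end.")
  if (!all(strand %in% c("+", "-"))) abort("Unknown strand in CDS row (must be '+' or '-').")
  gene_id <- vapply(cds[, 9], gff3_gene_id, character(1), USE.NAMES = FALSE)

  out <- tibble::tibble(
    seqid = cds[, 1], start = start, end = end,
    strand = strand, gene_id = gene_id
  )
  out <- out |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(g, key) {
      if (length(unique(g$strand)) != 1L || length(unique(g$seqid)) != 1L) {
        abort(sprintf("Gene '%s' mixes strands or sequences.", key$gene_id))
      }
      g <- g[order(g$start), ]
      if (nrow(g) > 1L && any(g$start[-1] <= g$end[-nrow(g)])) {
        abort(sprintf("Overlapping CDS segments for gene '%s'.", key$gene_id))
      }
      if (sum(g$end - g$start + 1L) %% 3L != 0L) {
        warn(sprintf("CDS length of gene '%s' is not a multiple of 3.", key$gene_id))
      }
      # translation order: ascending on '+', descending on '-'
      g$segment <- if (g$strand[1] == "+") seq_len(nrow(g)) else rev(seq_len(nrow(g)))
      g
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$seqid, .data$start)
  out
}

gff3_gene_id <- function(attrs) {
  kv <- strsplit(strsplit(attrs, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  for (k in c("locus_tag", "gene_id", "Parent", "ID")) {
    hit <- match(k, keys)
    if (!is.na(hit)) return(vals[hit])
  }
  abort("CDS row lacks an identifying attribute (locus_tag/gene_id/Parent/ID).")
}

#' Extract the spliced coding sequence of a gene
#'
#' @param cds Interval table from [read_gff3_cds()], possibly filtered to one
#'   gene.
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   genome sequences keyed by `seqid`.
#' @param gene_id Gene to extract.
#' @return Coding-orientation nucleotide string (reverse complement of the
#'   genome for minus-strand genes).
#' @export
cds_sequence <- function(cds, genome, gene_id) {
  g <- cds[cds$gene_id == gene_id, ]
  if (!nrow(g)) abort(paste0("Unknown gene_id: ", gene_id))
  genome <- as_genome_vector(genome)
  chrom <- genome[[g$seqid[1]]]
  g <- g[order(g$segment), ]
  parts <- purrr::map2_chr(g$start, g$end, function(s, e) {
    seg <- substr(chrom, s, e)
    if (g$strand[1] == "-") revcomp(seg) else seg
  })
  paste(parts, collapse = "")
}

as_genome_vector <- function(genome) {
  if (is.list(genome) && !is.null(names(genome))) {
    return(genome) # already normalized
  }
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome) || is.null(names(genome))) {
    abort("`genome` must be a named character vector or DNAStringSet.")
  }
  as.list(toupper(genome))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Map a genome coordinate to (cds_position) within a gene's spliced CDS.
# For minus-strand genes the offset is counted from the highest genome
# coordinate of the highest segment (the 5' end of the mRNA).
genome_to_cds_position <- function(cds_gene, position) {
  g <- cds_gene[order(cds_gene$segment), ]
  cum <- 0L
  for (i in seq_len(nrow(g))) {
    width <- g$end[i] - g$start[i] + 1L
    if (position >= g$start[i] && position <= g$end[i]) {
      within <- if (g$strand[i] == "+") {
        position - g$start[i] + 1L
      } else {
        g$end[i] - position + 1L
      }
      return(cum + within)
    }
    cum <- cum + width
  }
  NA_integer_
}

#' Annotate genome-coordinate substitutions with codon consequences
#'
#' Maps genome-space substitutions into any covering CDS and reports the
#' amino-acid consequence. Variants in intergenic regions are returned with
#' empty codon fields. For minus-strand genes the alleles are
#' reverse-complemented before codon lookup; for multi-nucleotide variants
#' the mapped CDS position is that of the 5'-most substituted base in coding
#' orientation.
#'
#' @param variants Data frame with `pos`, `ref`, `alt` (genome forward-strand
#'   alleles; equal lengths).
#' @param cds Interval table from [read_gff3_cds()].
#' @param genome Named character vector or `DNAStringSet`.
#' @return The input tibble with `gene_id`, `strand`, `cds_position`,
#'   `residue_index`, `aa_change`, `synonymous` and a `codon_changes` list
#'   column (one tibble per variant; multi-codon MNVs have several rows, and
#'   the scalar columns then summarise the joined changes).
#' @export
annotate_variants <- function(variants, cds, genome) {
  variants <- tibble::as_tibble(variants)
  genome <- as_genome_vector(genome)
  gene_seq_cache <- new.env(parent = emptyenv())
  ann <- purrr::pmap(
    list(variants$pos, variants$ref, variants$alt),
    function(pos, ref, alt, ...) {
      span <- pos + nchar(ref) - 1L
      hit <- cds[cds$start <= pos & cds$end >= span, ]
      if (!nrow(hit)) return(NULL)
      gid <- hit$gene_id[1]
      gene <- cds[cds$gene_id == gid, ]
      if (is.null(gene_seq_cache[[gid]])) {
        gene_seq_cache[[gid]] <- cds_sequence(cds, genome, gid)
      }
      seq <- gene_seq_cache[[gid]]
      minus <- gene$strand[1] == "-"
      cpos <- genome_to_cds_position(gene, if (minus) span else pos)
      r <- if (minus) revcomp(ref) else ref
      a <- if (minus) revcomp(alt) else alt
      annotate_codon_change(seq, cpos, r, a,
        gene_id = gid, strand = gene$strand[1]
      )
    }
  )
  variants |>
    dplyr::mutate(
      codon_changes = ann,
      gene_id = purrr::map_chr(ann, ~ if (is.null(.x)) NA_character_ else .x$gene_id[1]),
      strand = purrr::map_chr(ann, ~ if (is.null(.x)) NA_character_ else .x$strand[1]),
      cds_position = purrr::map_int(ann, ~ if (is.null(.x)) NA_integer_ else .x$cds_position[1]),
      residue_index = purrr::map_int(ann, ~ if (is.null(.x)) NA_integer_ else .x$residue_index[1]),
      aa_change = purrr::map_chr(ann, function(x) {
        if (is.null(x)) NA_character_ else paste(x$aa_change, collapse = ",")
      }),
      synonymous = purrr::map_lgl(ann, ~ if (is.null(.x)) NA else all(.x$synonymous))
    )
}
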