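#' Read a protein or nucleotide FASTA file into a tibble
#'
#' Sequences are uppercase-normalized; records whose original sequence
#' contained lowercase letters keep a `was_lowercase` flag. Duplicate record
#' identifiers and empty files are rejected.
#'
#' @param path Path to a FASTA file.
#' @param type `"AA"` or `"DNA"`; controls alphabet validation.
#' @return Tibble with `id`, `description`, `sequence`, `was_lowercase`.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort("FASTA file contains no records.")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    abort(paste0("Duplicate FASTA id: ", dup))
  }
  seqs <- as.character(set)
  lower <- grepl("[a-z]", seqs)
  seqs <- toupper(seqs)
  allowed <- if (type == "AA") "[^ACDEFGHIKLMNPQRSTVWYX*]" else "[^ACGTN]"
  bad <- grepl(allowed, seqs)
  if (any(bad)) {
    abort(paste0("Non-sequence characters in record ", ids[which(bad)[1]], "."))
  }
  tibble::tibble(
    id = unname(ids), description = unname(desc),
    sequence = unname(seqs), was_lowercase = unname(lower)
  )
}

#' Write records to FASTA (60-column wrap)
#'
#' @param records Data frame with `id`, `sequence`, optional `description`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("id", "sequence") %in% names(records)))
  if (anyDuplicated(records$id)) abort("Duplicate id in records.")
  set <- Biostrings::BStringSet(records$sequence)
  desc <- if ("description" %in% names(records)) records$description else ""
  names(set) <- trimws(paste(records$id, desc))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read and write pileup summary tables
#'
#' Pileup TSVs carry one row per candidate site per sample with the header
#' `sample pos ref alt depth alt_depth alt_fwd alt_rev` (extra columns such
#' as the simulator's truth flags are preserved). Written files start with
#' comment lines recording the package version, seed, and configuration
#' digest.
#'
#' @param path File path.
#' @return `read_pileup()`: a tibble.
#' @export
read_pileup <- function(path) {
  tbl <- readr::read_tsv(path,
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
  needed <- c("sample", "pos", "ref", "alt", "depth", "alt_depth", "alt_fwd", "alt_rev")
  missing <- setdiff(needed, names(tbl))
  if (length(missing)) {
    abort(paste0("Pileup file lacks column(s): ", paste(missing, collapse = ", ")))
  }
  tbl
}

#' @rdname read_pileup
#' @param pileup Pileup tibble.
#' @param seed,config_digest Recorded in the file header.
#' @export
write_pileup <- function(pileup, path, seed = NULL, config_digest = NULL) {
  write_tsv_with_header(pileup, path, seed, config_digest)
}

#' Read and write reactor trajectory tables
#'
#' Trajectories are TSVs with columns `time_h`, `protein_ug_per_cm2`
#' (empty for censored observations), and `censored`.
#'
#' @param path File path.
#' @return `read_trajectory()`: a tibble.
#' @export
read_trajectory <- function(path) {
  tbl <- readr::read_tsv(path,
    comment = "#", show_col_types = FALSE, progress = FALSE
  )
  needed <- c("time_h", "protein_ug_per_cm2", "censored")
  missing <- setdiff(needed, names(tbl))
  if (length(missing)) {
    abort(paste0("Trajectory file lacks column(s): ", paste(missing, collapse = ", ")))
  }
  tbl
}

#' @rdname read_trajectory
#' @param trajectory Trajectory tibble.
#' @param seed,config_digest Recorded in the file header.
#' @export
write_trajectory <- function(trajectory, path, seed = NULL, config_digest = NULL) {
  write_tsv_with_header(trajectory, path, seed, config_digest)
}

write_tsv_with_header <- function(tbl, path, seed = NULL, config_digest = NULL) {
  flat <- dplyr::mutate(
    tbl,
    dplyr::across(dplyr::where(is.list), ~ purrr::map_chr(.x, flatten_cell))
  )
  readr::write_lines(output_header(seed, config_digest), path)
  readr::write_tsv(flat, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

flatten_cell <- function(x) {
  if (is.null(x)) return("")
  if (is.data.frame(x)) {
    return(paste(purrr::pmap_chr(x, function(...) paste(..., sep = ":")), collapse = ";"))
  }
  if (!is.null(names(x))) {
    return(paste(names(x), format(unname(x), trim = TRUE), sep = "=", collapse = ";"))
  }
  paste(format(x, trim = TRUE), collapse = ";")
}

#' Read a minimal VCF subset into a pileup table
#'
#' A tolerant adapter for single-sample VCF v4.x files: uses `CHROM`, `POS`,
#' `REF`, `ALT` and the INFO keys `DP` (depth), `AD` (alt depth) and
#' `SAF`/`SAR` (forward/reverse alt counts); unknown INFO keys are ignored.
#' Multi-allelic rows are split. Only substitution alleles (equal-length
#' REF/ALT) are retained.
#'
#' @param path Path to an uncompressed VCF file.
#' @param sample Sample identifier for the resulting rows (default: the
#'   file's sample column name, or the file name).
#' @return A pileup tibble as accepted by [call_variants()].
#' @export
read_variant_vcf <- function(path, sample = NULL) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  lines <- readr::read_lines(path)
  header <- lines[startsWith(lines, "#CHROM")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) abort("VCF contains no variant rows.")
  if (is.null(sample)) {
    cols <- if (length(header)) strsplit(header[1], "\t")[[1]] else character()
    sample <- if (length(cols) >= 10L) cols[10] else basename(path)
  }
  rows <- purrr::map_dfr(strsplit(body, "\t", fixed = TRUE), function(f) {
    if (length(f) < 8L) abort("Malformed VCF row (fewer than 8 columns).")
    info <- parse_vcf_info(f[8])
    alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    purrr::map_dfr(alts, function(alt) {
      if (nchar(alt) != nchar(f[4])) return(NULL) # substitutions only
      tibble::tibble(
        chrom = f[1], pos = as.integer(f[2]), ref = f[4], alt = alt,
        depth = as.integer(info[["DP"]] %||% NA),
        alt_depth = as.integer(info[["AD"]] %||% NA),
        alt_fwd = as.integer(info[["SAF"]] %||% NA),
        alt_rev = as.integer(info[["SAR"]] %||% NA)
      )
    })
  })
  dplyr::mutate(rows, sample = sample, .before = 1)
}

parse_vcf_info <- function(info) {
  if (info == "." || !nzchar(info)) return(list())
  kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- lapply(kv, function(x) if (length(x) > 1L) x[2] else TRUE)
  setNames(vals, vapply(kv, `[`, character(1), 1))
}

#' Write variant calls as a minimal VCF
#'
#' Emits one row per call with `PASS` or the fail reason
#' (`below_min_frequency`, `strand_biased`) in the FILTER column and
#' DP/AD/SAF/SAR/AF INFO keys.
#'
#' @param calls Output of [call_variants()] for a single sample.
#' @param path Output path.
#' @param chrom Chromosome name for the CHROM column.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(calls, path, chrom = "chr") {
  calls <- tibble::as_tibble(calls)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=straindrift-%s", as.character(packageVersion("straindrift"))),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##INFO=<ID=AD,Number=1,Type=Integer,Description=\"Alt depth\">",
    "##INFO=<ID=SAF,Number=1,Type=Integer,Description=\"Alt forward-strand depth\">",
    "##INFO=<ID=SAR,Number=1,Type=Integer,Description=\"Alt reverse-strand depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Alt frequency\">",
    "##FILTER=<ID=below_min_frequency,Description=\"Alt frequency below the minimum\">",
    "##FILTER=<ID=strand_biased,Description=\"Strand bias at or above the bound\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- purrr::pmap_chr(calls, function(pos, ref, alt, depth, alt_depth,
                                          alt_fwd, alt_rev, frequency,
                                          passed, fail_reason, ...) {
    sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t%s\tDP=%d;AD=%d;SAF=%d;SAR=%d;AF=%.6g",
      chrom, pos, ref, alt,
      if (passed) "PASS" else fail_reason,
      depth, alt_depth, alt_fwd, alt_rev, frequency
    )
  })
  readr::write_lines(c(hdr, body), path)
  invisible(path)
}
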