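#' Describe a cargo protein to plant in a synthetic proteome
#'
#' @param length Protein length in amino acids.
#' @param n_nonamers Number of tandem GGXGXDXXX repeats to embed.
#' @param nonamer_window Fraction of the C-terminal sequence that receives
#'   the repeats.
#' @param target_pI_band Two-element numeric `(low, high)` pI band the
#'   generated sequence must land in.
#' @param n_cys Exact cysteine count of the generated sequence.
#' @param embed_ps00330 Plant the calcium-binding repeat signature. The
#'   bundled signature is a tandem of two nonamer turns, so this requires
#'   `n_nonamers >= 2`.
#' @return A list of class `planted_cargo`.
#' @export
planted_cargo <- function(length = 3038, n_nonamers = 4, nonamer_window = 0.25,
                          target_pI_band = c(4.0, 4.3), n_cys = 0,
                          embed_ps00330 = TRUE) {
  assert_scalar_number(length, "length", positive = TRUE)
  assert_scalar_number(n_nonamers, "n_nonamers", min = 0)
  assert_scalar_number(nonamer_window, "nonamer_window", min = 1e-9, max = 1)
  assert_scalar_number(n_cys, "n_cys", min = 0)
  stopifnot(is.numeric(target_pI_band), length(target_pI_band) == 2L,
    target_pI_band[1] < target_pI_band[2])
  if (9 * n_nonamers > floor(nonamer_window * length)) {
    abort("`length` too small: the nonamer block does not fit in the C-terminal window.")
  }
  if (embed_ps00330 && n_nonamers < 2) {
    abort("Embedding the Ca-repeat signature requires n_nonamers >= 2 (tandem turns).")
  }
  structure(
    list(
      length = as.integer(length), n_nonamers = as.integer(n_nonamers),
      nonamer_window = nonamer_window, target_pI_band = target_pI_band,
      n_cys = as.integer(n_cys), embed_ps00330 = embed_ps00330
    ),
    class = "planted_cargo"
  )
}

# Residues allowed in the free positions of planted nonamers: no G (would
# shift-match the conserved glycines) and no D (ditto for position 6), no C
# (cysteine count is controlled exactly).
nonamer_x_alphabet <- c("S", "T", "V", "L", "I", "N", "E")

# Background composition for cargo backbones: acid-heavy, Gly/Ala-enriched,
# cysteine-free (cysteines are placed explicitly afterwards).
cargo_backbone_freqs <- c(
  A = 0.09, D = 0.10, E = 0.09, F = 0.03, G = 0.08, H = 0.01, I = 0.05,
  K = 0.02, L = 0.08, M = 0.02, N = 0.05, P = 0.04, Q = 0.03, R = 0.02,
  S = 0.08, T = 0.08, V = 0.08, W = 0.01, Y = 0.02
)

#' Simulate a proteome with planted T1SS cargo among decoys
#'
#' Generates `length(cargo)` cargo sequences satisfying, by construction and
#' bounded rejection, exactly the requested features (tandem nonamer count
#' within the C-terminal window, exact cysteine count, pI inside the target
#' band) plus `n_decoys` decoy proteins guaranteed by rejection not to
#' satisfy the full cargo criteria. Half of the decoys are
#' dipeptide-preserving shuffles of the planted cargo (realistic
#' composition); the rest are random-composition proteins of typical length.
#' Deterministic given `seed`.
#'
#' @param n_decoys Number of decoy proteins.
#' @param cargo List of [planted_cargo()] specifications.
#' @param seed Integer seed.
#' @param criteria Criteria the decoys must fail (default
#'   [cargo_criteria()]).
#' @param max_attempts Rejection bound per sequence before erroring (e.g.
#'   for an infeasible pI band).
#' @return Tibble with `id`, `description`, `sequence`, and the truth flag
#'   `is_cargo`.
#' @export
simulate_proteome <- function(n_decoys, cargo = list(planted_cargo()), seed = NULL,
                              criteria = cargo_criteria(), max_attempts = 50L) {
  if (inherits(cargo, "planted_cargo")) cargo <- list(cargo)
  stopifnot(all(vapply(cargo, inherits, logical(1), "planted_cargo")))
  assert_scalar_number(n_decoys, "n_decoys", min = 0)
  with_seed_if(seed, {
    cargo_seqs <- purrr::imap_chr(cargo, function(spec, i) {
      generate_cargo_sequence(spec, criteria, max_attempts)
    })
    cargo_tbl <- tibble::tibble(
      id = sprintf("cargo_%02d", seq_along(cargo_seqs)),
      description = "planted T1SS cargo (synthetic)",
      sequence = cargo_seqs, is_cargo = TRUE
    )
    decoy_tbl <- if (n_decoys > 0) {
      seqs <- character(n_decoys)
      for (i in seq_len(n_decoys)) {
        seqs[i] <- generate_decoy(i, cargo_seqs, criteria, max_attempts)
      }
      tibble::tibble(
        id = sprintf("decoy_%03d", seq_len(n_decoys)),
        description = "decoy protein (synthetic)",
        sequence = seqs, is_cargo = FALSE
      )
    } else {
      NULL
    }
    dplyr::bind_rows(cargo_tbl, decoy_tbl)
  })
}

generate_cargo_sequence <- function(spec, criteria, max_attempts) {
  nonamer <- nonamer_pattern()
  for (attempt in seq_len(max_attempts)) {
    seq <- try_cargo_sequence(spec, nonamer, criteria)
    if (!is.null(seq)) return(seq)
  }
  abort(paste0(
    "Could not generate a cargo sequence in ", max_attempts, " attempts; ",
    "the requested pI band [", spec$target_pI_band[1], ", ",
    spec$target_pI_band[2], "] is likely infeasible for this composition."
  ))
}

try_cargo_sequence <- function(spec, nonamer, criteria) {
  L <- spec$length
  block <- paste(replicate(spec$n_nonamers, paste0(
    "GG", sample(nonamer_x_alphabet, 1), "G", sample(nonamer_x_alphabet, 1),
    "D", paste(sample(nonamer_x_alphabet, 3, replace = TRUE), collapse = "")
  )), collapse = "")
  backbone_len <- L - nchar(block)
  chars <- sample(names(cargo_backbone_freqs), backbone_len,
    replace = TRUE, prob = cargo_backbone_freqs
  )
  # exact cysteine count
  if (spec$n_cys > 0) {
    chars[sample(backbone_len, spec$n_cys)] <- "C"
  }
  # insert the repeat block inside the C-terminal window
  win <- floor(spec$nonamer_window * L)
  ins_min <- L - win + 1L
  ins_max <- L - nchar(block) + 1L
  ins <- sample(seq(ins_min, ins_max), 1L)
  seq <- paste0(
    paste(chars[seq_len(ins - 1L)], collapse = ""),
    block,
    paste(chars[seq(ins, backbone_len)[seq_len(backbone_len - ins + 1L)]], collapse = "")
  )
  seq <- scrub_spurious_nonamers(seq, ins, nchar(block), nonamer)
  seq <- tune_pI(seq, spec, ins, nchar(block))
  if (is.null(seq)) return(NULL)
  # final integrity check: exact hit count, all inside the window
  hits <- scan_pattern(seq, nonamer)
  if (nrow(hits) != spec$n_nonamers) return(NULL)
  if (spec$n_cys != count_cysteines(seq)) return(NULL)
  seq
}

# Mutate away any nonamer match that does not start inside the planted
# block (positions ins .. ins+block_len-1): flip its leading G.
scrub_spurious_nonamers <- function(seq, ins, block_len, nonamer) {
  for (i in 1:20) {
    hits <- scan_pattern(seq, nonamer)
    bad <- hits$start[hits$start < ins | hits$start > ins + block_len - 9L]
    if (!length(bad)) return(seq)
    for (b in bad) substr(seq, b, b) <- "T"
  }
  seq
}

# Nudge the sequence into the target pI band by swapping neutral residues
# to D/E (to lower) or D/E to N/Q (to raise), never touching the planted
# block. Returns NULL when the band cannot be reached.
tune_pI <- function(seq, spec, ins, block_len) {
  band <- spec$target_pI_band
  protected <- seq(ins, ins + block_len - 1L)
  for (i in 1:400) {
    pi_val <- compute_pI(seq)
    if (pi_val >= band[1] && pi_val <= band[2]) return(seq)
    chars <- strsplit(seq, "")[[1]]
    free <- setdiff(seq_along(chars), protected)
    if (pi_val > band[2]) {
      cand <- free[chars[free] %in% c("S", "T", "N", "Q", "L", "V", "I", "K", "R", "H")]
      if (!length(cand)) return(NULL)
      idx <- sample(cand, min(10L, length(cand)))
      chars[idx] <- sample(c("D", "E"), length(idx), replace = TRUE)
    } else {
      cand <- free[chars[free] %in% c("D", "E")]
      if (!length(cand)) return(NULL)
      idx <- sample(cand, min(10L, length(cand)))
      chars[idx] <- sample(c("N", "Q"), length(idx), replace = TRUE)
    }
    seq <- paste(chars, collapse = "")
  }
  NULL
}

generate_decoy <- function(i, cargo_seqs, criteria, max_attempts) {
  for (attempt in seq_len(max_attempts)) {
    seq <- if (i %% 2L == 0L && length(cargo_seqs)) {
      dipeptide_shuffle(cargo_seqs[[(i %/% 2L - 1L) %% length(cargo_seqs) + 1L]])
    } else {
      len <- sample(200:1200, 1L)
      paste(sample(names(cargo_backbone_freqs), len, replace = TRUE), collapse = "")
    }
    report <- screen_proteome(
      tibble::tibble(id = "d", sequence = seq), criteria
    )
    if (report$verdict == "rejected") return(seq)
  }
  abort("Could not generate a criteria-failing decoy (rejection bound hit).")
}

# Shuffle a sequence in dipeptide chunks, preserving local composition.
dipeptide_shuffle <- function(seq) {
  n <- nchar(seq)
  cut <- seq(1L, n, by = 2L)
  chunks <- substring(seq, cut, pmin(cut + 1L, n))
  paste(sample(chunks), collapse = "")
}
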