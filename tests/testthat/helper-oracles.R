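# Independent reference implementations used to cross-check the package.
# Each deliberately uses a different algorithm than the implementation it
# verifies.

# Brute-force PROSITE matcher: expand every combination of repeat counts
# into a flat list of fixed single-position element specs, then test each
# window of the right length position by position. No backtracking.
oracle_scan <- function(seq, pattern) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  counts <- lapply(pattern$elements, function(el) seq(el$min, el$max))
  combos <- expand.grid(counts, KEEP.OUT.ATTRS = FALSE)
  hits <- list()
  for (ci in seq_len(nrow(combos))) {
    flat <- list()
    for (k in seq_along(pattern$elements)) {
      reps <- combos[ci, k]
      if (reps > 0) {
        flat <- c(flat, rep(pattern$elements[k], reps))
      }
    }
    len <- length(flat)
    starts <- if (pattern$n_anchor) 1L else seq_len(max(n - len + 1L, 0L))
    if (len == 0L) next
    for (s in starts) {
      e <- s + len - 1L
      if (e > n) next
      if (pattern$c_anchor && e != n) next
      ok <- TRUE
      for (k in seq_len(len)) {
        el <- flat[[k]]
        r <- chars[s + k - 1L]
        good <- switch(el$type,
          any = TRUE,
          set = r %in% el$residues,
          negset = !(r %in% el$residues)
        )
        if (!good) {
          ok <- FALSE
          break
        }
      }
      if (ok) hits[[length(hits) + 1L]] <- c(s, e)
    }
  }
  if (!length(hits)) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  m <- unique(do.call(rbind, hits))
  tibble::tibble(start = m[, 1], end = m[, 2]) |>
    dplyr::arrange(start, end)
}

# Random PROSITE pattern over the 20-letter alphabet, for property tests.
random_prosite_pattern <- function(n_elements = sample(2:6, 1)) {
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  el <- replicate(n_elements, {
    core <- switch(sample(4, 1),
      "x",
      sample(aas, 1),
      paste0("[", paste(sample(aas, sample(2:4, 1)), collapse = ""), "]"),
      paste0("{", paste(sample(aas, sample(1:3, 1)), collapse = ""), "}")
    )
    rep <- switch(sample(3, 1),
      "",
      sprintf("(%d)", sample(1:3, 1)),
      sprintf("(%d,%d)", sample(0:2, 1), sample(2:4, 1))
    )
    paste0(core, rep)
  })
  paste(el, collapse = "-")
}

random_aa_seq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
    collapse = ""
  )
}

# Grid-search pI oracle: argmin of |net charge| over a fine pH grid, with
# the charge assembled residue-by-residue in plain loops.
oracle_pI <- function(seq, pka = pka_sets()$bjellqvist, step = 0.001) {
  chars <- strsplit(toupper(seq), "")[[1]]
  grid <- seq(0, 14, by = step)
  q <- rep(0, length(grid))
  for (r in chars) {
    if (r %in% names(pka$acidic)) {
      q <- q - 1 / (1 + 10^(pka$acidic[[r]] - grid))
    } else if (r %in% names(pka$basic)) {
      q <- q + 1 / (1 + 10^(grid - pka$basic[[r]]))
    }
  }
  q <- q + 1 / (1 + 10^(grid - pka$nterm)) - 1 / (1 + 10^(pka$cterm - grid))
  grid[which.min(abs(q))]
}

# Scalar, clause-by-clause statement of the variant acceptance rule.
oracle_filter_pass <- function(alt_depth, depth, alt_fwd,
                               min_freq = 0.10, high = 0.80, max_bias = 0.70) {
  freq <- alt_depth / depth
  if (freq < min_freq) {
    return(FALSE)
  }
  if (freq >= high) {
    return(TRUE)
  }
  if (alt_depth == 0) {
    return(FALSE)
  }
  bias <- max(alt_fwd, alt_depth - alt_fwd) / alt_depth
  bias < max_bias
}
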