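# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed when `seed` is non-NULL, leaving the
# caller's RNG state untouched; otherwise run as-is (caller manages RNG).
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

assert_scalar_number <- function(x, name, positive = FALSE, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be strictly positive.", name))
  if (x < min || x > max) {
    abort(sprintf("`%s` must lie in [%s, %s].", name, format(min), format(max)))
  }
  invisible(x)
}

# Two-significant-figure string, mirroring how founder estimates are usually
# quoted (e.g. "1.6e+04").
format_sig2 <- function(x) formatC(signif(x, 2), format = "g", digits = 2)

# Merge a sorted set of 1-based inclusive intervals, joining touching runs.
merge_intervals <- function(start, end) {
  if (length(start) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- integer()
  out_e <- integer()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1L) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  tibble::tibble(start = c(out_s, ms), end = c(out_e, me))
}

# Header comment lines stamped on every machine-readable output file.
output_header <- function(seed = NULL, config_digest = NULL) {
  c(
    sprintf("# straindrift %s", as.character(packageVersion("straindrift"))),
    sprintf("# seed=%s", if (is.null(seed)) "NA" else format(seed)),
    sprintf("# config=%s", config_digest %||% "default")
  )
}

# Stable short digest of an R object (no external digest dependency):
# serialize deterministically and fold bytes into a hex string.
config_digest <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2L)
  # drop the serialization header (holds R version numbers)
  raw <- raw[-seq_len(14L)]
  acc <- rep(0L, 8L)
  idx <- (seq_along(raw) - 1L) %% 8L + 1L
  for (k in 1:8) {
    b <- as.integer(raw[idx == k])
    if (length(b)) acc[k] <- sum(b * (seq_along(b) %% 251L + 1L)) %% 4093L
  }
  paste(sprintf("%03x", acc), collapse = "")
}
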