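# Internal string / sequence helpers shared across modules.

#' @importFrom Biostrings DNAString DNAStringSet readBStringSet writeXStringSet
#' @importFrom IRanges IRanges
NULL

# Reverse-complement of an ACGTN string (plain character, not XString).
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

# Split a sequence string into single characters.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Split a nucleotide string into consecutive triplets; trailing 1-2 bases
# are returned as a short final element.
codon_split <- function(x) {
  n <- nchar(x)
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  substring(x, starts, pmin(starts + 2L, n))
}

# Rotate a character vector so that it starts at index i (1-based).
rotate_vec <- function(x, i) {
  n <- length(x)
  if (n == 0L || i == 1L) return(x)
  x[c(i:n, seq_len(i - 1L))]
}

# Round half up to `digits` decimals (display convention for BDn and
# percentage tables; base round() is round-half-even).
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so generators are deterministic without
# clobbering the session seed.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Clamp a numeric value into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
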