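#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a child RNG seed from a root seed and a label
#'
#' One root seed fans out to per-module child seeds through a fixed
#' polynomial string hash, so a module re-run in isolation reproduces the
#' stream it would see inside a full pipeline run.
#'
#' @param seed Integer root seed.
#' @param label Character label of the consuming module or stage.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# Run `expr` under a locally-set seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Split a character vector of sequences into a list of single-base vectors.
seq_to_chars <- function(x) strsplit(x, "", fixed = TRUE)

chars_to_seq <- function(x) paste(x, collapse = "")

# Count N characters per sequence, vectorized.
count_n <- function(sequences) {
  nchar(sequences) - nchar(gsub("N", "", sequences, fixed = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
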