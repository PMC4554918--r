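# Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")
BASES <- c("A", "C", "G", "T")

#' Run code with a temporary RNG seed
#'
#' Evaluates `code` under `set.seed(seed)` without disturbing the caller's
#' RNG state. All stochastic generators in the package route through this,
#' which is what makes them pure functions of their arguments and seed.
#'
#' @param seed Integer seed (must be < 2^31).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Validate a sequence against an alphabet; errors name the record and the
# 1-based position of the first offending character.
check_alphabet <- function(seq, alphabet, id = "<sequence>") {
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad) > 0) {
    abort(sprintf(
      "record '%s': illegal character '%s' at position %d for alphabet [%s]",
      id, chars[bad[1]], bad[1], paste(alphabet, collapse = "")
    ))
  }
  invisible(seq)
}

# Vectorised reverse complement for plain character DNA.
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

# stringr-free fixed substring by 0-based half-open coordinates.
substr0 <- function(seq, start, end) {
  substring(seq, start + 1L, end)
}

# Split a string into single characters.
chars <- function(seq) strsplit(seq, "")[[1]]

stopifnot_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("%s must be a single string", what))
  }
}
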