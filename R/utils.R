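# Canonical one-letter amino-acid alphabet, alphabetical by letter.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

WINDOW_SIZE <- 6L
N_FEATURES <- 36L

# Evaluate `expr` under a temporary, seeded RNG state; the caller's RNG
# stream is untouched.  All stochastic operations in the package route
# through this so runs are reproducible under a single integer seed.
with_run_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr, .rng_kind = "Mersenne-Twister")
}

# Split a string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

stop_input <- function(...) abort(sprintf(...), class = "aprscan_error")

# Validate one peptide/protein sequence against an alphabet; returns the
# uppercased sequence or errors naming the first offending position.
check_sequence <- function(sequence, alphabet = AA_ALPHABET,
                           what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence)) {
    stop_input("%s must be a single character string", what)
  }
  sequence <- toupper(sequence)
  cs <- chars(sequence)
  bad <- which(!cs %in% alphabet)
  if (length(bad) > 0) {
    stop_input("non-canonical residue '%s' at position %d of %s",
               cs[bad[1]], bad[1], what)
  }
  sequence
}
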