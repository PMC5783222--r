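# misc internal helpers

# Run code under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# \x1f-delimited rendering used for exact contiguous-subsequence tests
.tok_string <- function(tokens) {
  paste0("\x1f", paste(tokens, collapse = "\x1f"), "\x1f")
}

.is_subsequence <- function(needle, haystack) {
  grepl(.tok_string(needle), .tok_string(haystack), fixed = TRUE)
}
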