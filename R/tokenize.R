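#' Normalize text
#'
#' Unicode NFC normalization and collapsing of whitespace runs to a
#' single space. Applied to every title, abstract and lexicon surface at
#' read time so that downstream tokenization is stable.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
normalizeText <- function(x) {
  x <- stringi::stri_trans_nfc(x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

#' Tokenize text
#'
#' Deterministic whitespace tokenization with punctuation detachment:
#' brackets, commas, semicolons, colons, quotes, `!` and `?` become their
#' own tokens; slashes split joined terms (`"NCOA1/AP-1"` gives three
#' tokens, the slash kept); periods are detached only at the end of a
#' whitespace-delimited chunk, so abbreviations (`"i.e"`) and decimal
#' numbers survive. Hyphenated terms are preserved as single tokens.
#' Tokenizing the space-join of a token sequence reproduces the sequence.
#'
#' Matching against the lexicon lowercases tokens; the original spelling
#' is what this function returns.
#'
#' @param text a single character string.
#' @return character vector of tokens (length 0 for empty input).
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- normalizeText(text)
  if (!nzchar(s)) return(character(0))
  s <- gsub("/", " / ", s, fixed = TRUE)
  s <- gsub('([][(){},;:!?"])', " \\1 ", s)
  # sentence-final (chunk-final) periods become tokens; repeat for "..."
  s <- trimws(gsub("\\s+", " ", s))
  repeat {
    s2 <- trimws(gsub("\\s+", " ", gsub("\\.(\\s|$)", " .\\1", s)))
    if (identical(s2, s)) break
    s <- s2
  }
  strsplit(s, " ", fixed = TRUE)[[1]]
}

# Abbreviations whose trailing period does not end a sentence.
.sentence_abbrev <- c("al", "Fig", "Figs", "fig", "i.e", "e.g", "cf", "vs",
                      "Dr", "No", "approx", "ca", LETTERS)

#' Split a token sequence into sentence spans
#'
#' A sentence boundary falls after every `"."`, `"!"` or `"?"` token,
#' except when the token preceding a period is in a closed abbreviation
#' list (`"al"`, `"Fig"`, `"i.e"`, `"e.g"`, single capitals, ...). Spans
#' are contiguous, exhaustive and ordered, so concatenating them
#' reproduces the input; an abstract without boundaries yields one span.
#'
#' @param tokens character vector of tokens.
#' @return list of integer vectors, each the token indices of one sentence.
#' @export
splitSentences <- function(tokens) {
  stopifnot(length(tokens) > 0L)
  n <- length(tokens)
  ends <- integer(0)
  for (i in seq_len(n)) {
    tok <- tokens[i]
    if (tok %in% c("!", "?")) {
      ends <- c(ends, i)
    } else if (tok == ".") {
      prev <- if (i > 1L) tokens[i - 1L] else ""
      if (!prev %in% .sentence_abbrev) ends <- c(ends, i)
    }
  }
  if (length(ends) == 0L || ends[length(ends)] != n) ends <- c(ends, n)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  keep <- starts <= ends
  mapply(function(s, e) s:e, starts[keep], ends[keep], SIMPLIFY = FALSE)
}
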