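# Entity lexicon: MeSH-style resolution of surface forms to canonical
# ids, merged type labels, and greedy longest-match tagging.

.best_types <- c("Gene", "Drug", "Chemical Compounds", "Target", "Disease",
                 "Toxin", "Transcription Factor", "miRNA", "Pathway",
                 "Mutation")
.mesh_types <- c(
  "Anatomy [A]", "Organisms [B]", "Diseases [C]", "Chemicals and Drugs [D]",
  "Analytical, Diagnostic and Therapeutic Techniques, and Equipment [E]",
  "Psychiatry and Psychology [F]", "Phenomena and Processes [G]",
  "Disciplines and Occupations [H]",
  "Anthropology, Education, Sociology, and Social Phenomena [I]",
  "Technology, Industry, and Agriculture [J]", "Humanities [K]",
  "Information Science [L]", "Named Groups [M]", "Health Care [N]",
  "Publication Characteristics [V]", "Geographicals [Z]")

.merge_map <- c(
  "Gene" = "Gene", "Target" = "Gene", "Transcription Factor" = "Gene",
  "Drug" = "Chemicals and Drugs [D]", "Toxin" = "Chemicals and Drugs [D]",
  "Chemical Compounds" = "Chemicals and Drugs [D]",
  "Chemicals and Drugs [D]" = "Chemicals and Drugs [D]",
  "Disease" = "Diseases [C]", "Diseases [C]" = "Diseases [C]")

#' Merged entity-type vocabulary
#'
#' The closed set of type labels a token can carry after merging:
#' semantically close raw labels collapse onto one representative
#' (gene-like labels onto `Gene`, drug/chemical labels onto
#' `Chemicals and Drugs [D]`, disease labels onto `Diseases [C]`), every
#' other raw label maps to itself, and untyped tokens are `Unknown`.
#'
#' @return character vector of merged type labels, `Unknown` last.
#' @export
typeVocabulary <- function() {
  raw <- c(.best_types, .mesh_types)
  merged <- unique(unname(vapply(raw, mergeType, character(1))))
  c(setdiff(merged, "Unknown"), "Unknown")
}

#' Merge a raw entity-type label into its representative type
#'
#' Total and deterministic: `Gene`, `Target` and `Transcription Factor`
#' merge into `Gene`; `Drug`, `Toxin`, `Chemical Compounds` and
#' `Chemicals and Drugs [D]` merge into `Chemicals and Drugs [D]`;
#' `Disease` merges into `Diseases [C]`; any other known label maps to
#' itself; a missing or unrecognized label maps to `Unknown`. Idempotent
#' by construction.
#'
#' @param rawType a single label or `NA`.
#' @return a single merged type label.
#' @export
mergeType <- function(rawType) {
  if (length(rawType) != 1L || is.na(rawType) || !nzchar(rawType))
    return("Unknown")
  if (rawType %in% names(.merge_map)) return(unname(.merge_map[[rawType]]))
  if (rawType %in% c(.best_types, .mesh_types)) return(rawType)
  "Unknown"
}

.surface_key <- function(surface) {
  tolower(paste(tokenize(surface), collapse = " "))
}

#' Build an indexed entity lexicon
#'
#' Groups surface forms by canonical entity id (entity resolution) and
#' derives one merged type per entity. A surface mapped to two different
#' entity ids is a build-time error. When the raw labels of one entity
#' merge to contradictory types, a label from the curated (BEST-style)
#' inventory outranks a MeSH category label, since it is the more
#' specific source; a remaining contradiction is an error.
#'
#' @param entries data.frame with columns `surface`, `entity_id` and
#'   optionally `raw_type` (`NA` for untyped).
#' @param maxNgram longest surface length, in tokens, indexed for lookup.
#' @return a [Lexicon-class] object.
#' @export
buildLexicon <- function(entries, maxNgram = 6L) {
  stopifnot(is.data.frame(entries), nrow(entries) > 0L,
            all(c("surface", "entity_id") %in% names(entries)))
  if (is.null(entries$raw_type)) entries$raw_type <- NA_character_
  surface <- normalizeText(as.character(entries$surface))
  if (any(!nzchar(surface))) stop("empty surface form in lexicon entries")
  key <- vapply(surface, .surface_key, character(1), USE.NAMES = FALSE)
  ids <- as.character(entries$entity_id)

  # surface -> entity conflicts
  agg <- tapply(ids, key, function(v) unique(v))
  bad <- names(agg)[vapply(agg, length, integer(1)) > 1L]
  if (length(bad))
    stop(sprintf("surface %s maps to multiple entity ids: %s",
                 sQuote(bad[1]), paste(agg[[bad[1]]], collapse = ", ")))

  # de-duplicate identical (surface, entity) rows, first occurrence wins
  first <- !duplicated(key)
  df <- data.frame(surface = surface[first], surface_key = key[first],
                   ntok = lengths(strsplit(key[first], " ", fixed = TRUE)),
                   entity_id = ids[first],
                   raw_type = as.character(entries$raw_type)[first],
                   stringsAsFactors = FALSE)
  if (any(df$ntok > maxNgram))
    warning("some surfaces exceed maxNgram tokens and will never match")

  # one merged type per entity; BEST-style label outranks a MeSH label
  entityType <- vapply(split(df$raw_type, df$entity_id), function(raws) {
    merged <- unique(vapply(raws, mergeType, character(1)))
    merged <- setdiff(merged, "Unknown")
    if (length(merged) == 0L) return("Unknown")
    if (length(merged) == 1L) return(merged)
    fromBest <- unique(vapply(raws[raws %in% .best_types], mergeType,
                              character(1)))
    if (length(fromBest) == 1L) {
      message(sprintf("type conflict resolved in favour of %s", fromBest))
      return(fromBest)
    }
    stop(sprintf("entity has contradictory merged types: %s",
                 paste(merged, collapse = " vs ")))
  }, character(1))

  index <- new.env(parent = emptyenv(), hash = TRUE)
  firstTok <- new.env(parent = emptyenv(), hash = TRUE)
  splitKeys <- strsplit(df$surface_key, " ", fixed = TRUE)
  for (i in seq_len(nrow(df))) {
    assign(df$surface_key[i], df$entity_id[i], index)
    f <- splitKeys[[i]][1]
    prev <- get0(f, envir = firstTok, inherits = FALSE)
    if (is.null(prev) || prev < df$ntok[i]) assign(f, df$ntok[i], firstTok)
  }

  new("Lexicon", entries = df, entityType = entityType, index = index,
      firstTokenIndex = firstTok, maxNgram = as.integer(maxNgram))
}

#' Read / write a lexicon file
#'
#' Tab-separated columns (surface, entity_id, raw_type); lines starting
#' with `#` are comments; a missing third column means untyped.
#'
#' @param path file path.
#' @param maxNgram passed to [buildLexicon()].
#' @return `readLexicon` returns a [Lexicon-class]; `writeLexiconEntries`
#'   writes its entries back and returns `path` invisibly.
#' @export
readLexicon <- function(path, maxNgram = 6L) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("lexicon line with fewer than 2 fields")
  entries <- data.frame(
    surface = vapply(parts, `[`, character(1), 1L),
    entity_id = vapply(parts, `[`, character(1), 2L),
    raw_type = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else
      NA_character_, character(1)),
    stringsAsFactors = FALSE)
  buildLexicon(entries, maxNgram = maxNgram)
}

#' @rdname readLexicon
#' @param lexicon a [Lexicon-class] object.
#' @export
writeLexiconEntries <- function(lexicon, path) {
  e <- lexicon@entries
  lines <- sprintf("%s\t%s\t%s", e$surface, e$entity_id,
                   ifelse(is.na(e$raw_type), "", e$raw_type))
  writeLines(lines, path)
  invisible(path)
}

#' Tag entity mentions in a token sequence
#'
#' Greedy left-to-right longest-match of lexicon surfaces over token
#' n-grams (up to the lexicon's `maxNgram`). Matching is case-insensitive
#' and token-boundary-anchored: a surface can never match inside a
#' token. Returned mentions are sorted and non-overlapping.
#'
#' @param tokens character vector (from [tokenize()]).
#' @param lexicon a [Lexicon-class] object.
#' @return data.frame with columns `entity_id`, `type`, `start`, `end`
#'   (1-based inclusive token indices).
#' @export
tagText <- function(tokens, lexicon) {
  stopifnot(is(lexicon, "Lexicon"))
  n <- length(tokens)
  out_id <- character(0); out_start <- integer(0); out_end <- integer(0)
  if (n > 0L) {
    low <- tolower(tokens)
    i <- 1L
    while (i <= n) {
      hit <- NULL
      maxn <- get0(low[i], envir = lexicon@firstTokenIndex,
                   inherits = FALSE)
      if (is.null(maxn)) { i <- i + 1L; next }
      for (len in seq.int(min(maxn, lexicon@maxNgram, n - i + 1L), 1L)) {
        key <- if (len == 1L) low[i] else
          paste(low[i:(i + len - 1L)], collapse = " ")
        id <- get0(key, envir = lexicon@index, inherits = FALSE)
        if (!is.null(id)) { hit <- list(id = id, len = len); break }
      }
      if (is.null(hit)) {
        i <- i + 1L
      } else {
        out_id <- c(out_id, hit$id)
        out_start <- c(out_start, i)
        out_end <- c(out_end, i + hit$len - 1L)
        i <- i + hit$len
      }
    }
  }
  data.frame(entity_id = out_id,
             type = if (length(out_id))
               unname(lexicon@entityType[out_id]) else character(0),
             start = out_start, end = out_end, stringsAsFactors = FALSE)
}
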