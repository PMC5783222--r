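# Article record and word-vector I/O.

.article_ok <- function(id, title, abstract) {
  !is.null(id) && !is.na(id) && nzchar(id) &&
    !is.null(title) && !is.na(title) && nzchar(normalizeText(title)) &&
    !is.null(abstract) && !is.na(abstract) && nzchar(normalizeText(abstract))
}

#' Read article records from a JSONL file
#'
#' One JSON object per line with fields `article_id`, `title`,
#' `abstract` and optional `year`. Title and abstract are normalized
#' (NFC, collapsed whitespace) at read time. Records failing the
#' invariants (empty title/abstract, missing or duplicate id) are
#' skipped with a warning; the skip count is attached as attribute
#' `"skipped"`.
#'
#' @param path file path.
#' @return data.frame with columns `article_id`, `title`, `abstract`,
#'   `year` (NA when absent), in file order.
#' @export
readArticlesJsonl <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  skipped <- 0L
  seen <- character(0)
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(rec) || !.article_ok(rec$article_id, rec$title, rec$abstract) ||
        rec$article_id %in% seen) {
      warning(sprintf("skipping malformed article record on line %d", i),
              call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    seen <- c(seen, rec$article_id)
    recs[[i]] <- data.frame(
      article_id = as.character(rec$article_id),
      title = normalizeText(rec$title),
      abstract = normalizeText(rec$abstract),
      year = if (!is.null(rec$year) && !is.na(rec$year))
        as.integer(rec$year) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(article_id = character(0), title = character(0),
                      abstract = character(0), year = integer(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' @rdname readArticlesJsonl
#' @param articles data.frame as returned by `readArticlesJsonl`.
#' @export
writeArticlesJsonl <- function(articles, path) {
  lines <- vapply(seq_len(nrow(articles)), function(i) {
    rec <- list(article_id = articles$article_id[i],
                title = articles$title[i],
                abstract = articles$abstract[i])
    if (!is.na(articles$year[i])) rec$year <- articles$year[i]
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.first_year <- function(node, xpath) {
  y <- xml2::xml_text(xml2::xml_find_first(node, xpath))
  m <- regmatches(y, regexpr("[0-9]{4}", y))
  if (length(m) && nzchar(m)) as.integer(m) else NA_integer_
}

#' Read articles from a MEDLINE-style XML file
#'
#' Parses `PubmedArticle`/`MedlineCitation` elements carrying a PMID, an
#' `ArticleTitle` and one or more `AbstractText` sections. Structured
#' abstracts are concatenated with a single space, in document order.
#' The year is the first 4-digit year found in `DateCompleted`, falling
#' back to `PubDate`; citations without both title and abstract are
#' skipped with a warning.
#'
#' @param path path to the XML file.
#' @return data.frame as for [readArticlesJsonl()].
#' @export
readMedlineXml <- function(path) {
  doc <- xml2::read_xml(path)
  cites <- xml2::xml_find_all(doc, "//MedlineCitation")
  if (length(cites) == 0L) cites <- xml2::xml_find_all(doc, "//PubmedArticle")
  recs <- list()
  skipped <- 0L
  for (node in cites) {
    pmid <- xml2::xml_text(xml2::xml_find_first(node, ".//PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(node, ".//ArticleTitle"))
    absx <- xml2::xml_find_all(node, ".//Abstract/AbstractText")
    abstract <- paste(vapply(absx, xml2::xml_text, character(1)),
                      collapse = " ")
    if (!.article_ok(pmid, title, abstract)) {
      warning("skipping citation without title or abstract", call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    year <- .first_year(node, ".//DateCompleted/Year")
    if (is.na(year)) year <- .first_year(node, ".//PubDate")
    recs[[length(recs) + 1L]] <- data.frame(
      article_id = pmid, title = normalizeText(title),
      abstract = normalizeText(abstract), year = year,
      stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(article_id = character(0), title = character(0),
               abstract = character(0), year = integer(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Read word vectors in word2vec text format
#'
#' Expects the standard header line `"<count> <dimension>"` followed by
#' one token and its components per line. On duplicate tokens the first
#' occurrence wins with a warning; a row whose component count differs
#' from the header dimension is a format error naming the line.
#'
#' @param path file path.
#' @return a [WordVectorTable-class] object.
#' @export
readWordVectors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("word-vector file is empty (missing header)")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr))))
    stop("missing or malformed word2vec header line")
  dim <- as.integer(hdr[2])
  body <- lines[-1][nzchar(trimws(lines[-1]))]
  toks <- character(length(body))
  mat <- matrix(NA_real_, nrow = length(body), ncol = dim)
  for (i in seq_along(body)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(parts) != dim + 1L)
      stop(sprintf("line %d has %d components, expected %d",
                   i + 1L, length(parts) - 1L, dim))
    toks[i] <- parts[1]
    mat[i, ] <- as.numeric(parts[-1])
  }
  dup <- duplicated(toks)
  if (any(dup)) {
    warning(sprintf("%d duplicate token(s); first occurrence wins", sum(dup)),
            call. = FALSE)
    mat <- mat[!dup, , drop = FALSE]
    toks <- toks[!dup]
  }
  rownames(mat) <- toks
  new("WordVectorTable", dim = dim, vectors = mat)
}
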