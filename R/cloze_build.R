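# Construction of cloze instances from tagged articles.

.entity_prefix <- "@@"

.is_entity_token <- function(tokens) startsWith(tokens, .entity_prefix)

# Collapse each tagged mention to a single canonical-id token and carry
# the merged type along; returns parallel token/type vectors.
.anonymize <- function(tokens, mentions) {
  n <- length(tokens)
  if (nrow(mentions) == 0L)
    return(list(tokens = tokens, types = rep("Unknown", n)))
  mentions <- mentions[order(mentions$start), , drop = FALSE]
  out_tok <- character(0); out_type <- character(0)
  pos <- 1L
  for (i in seq_len(nrow(mentions))) {
    s <- mentions$start[i]; e <- mentions$end[i]
    if (s > pos) {
      out_tok <- c(out_tok, tokens[pos:(s - 1L)])
      out_type <- c(out_type, rep("Unknown", s - pos))
    }
    out_tok <- c(out_tok, paste0(.entity_prefix, mentions$entity_id[i]))
    out_type <- c(out_type, mentions$type[i])
    pos <- e + 1L
  }
  if (pos <= n) {
    out_tok <- c(out_tok, tokens[pos:n])
    out_type <- c(out_type, rep("Unknown", n - pos + 1L))
  }
  list(tokens = out_tok, types = out_type)
}

#' Test the dataset inclusion filters
#'
#' An instance is kept iff the answer occurs among the document's
#' candidate entities, the answer occurred in the question, and the
#' number of candidate answers exceeds 20 (i.e. at least
#' `minCandidates = 21`). Returns a logical with a `"reason"` attribute
#' naming the first failed condition.
#'
#' @param answer entity token selected as the answer.
#' @param candidates entity tokens occurring in the document.
#' @param questionEntities entity tokens occurring in the question
#'   (before masking).
#' @param minCandidates minimum admissible candidate count.
#' @return `TRUE`, or `FALSE` with attribute `reason`.
#' @export
passesFilters <- function(answer, candidates, questionEntities,
                          minCandidates = 21L) {
  if (!(answer %in% candidates) || !(answer %in% questionEntities)) {
    out <- FALSE
    attr(out, "reason") <- "answer not in both"
    return(out)
  }
  if (length(unique(candidates)) < minCandidates) {
    out <- FALSE
    attr(out, "reason") <- "candidate count"
    return(out)
  }
  TRUE
}

.rejection <- function(articleId, reason) {
  structure(list(articleId = articleId, reason = reason),
            class = "clozeRejection")
}

#' @rdname buildInstance
#' @param x any object.
#' @export
isRejection <- function(x) inherits(x, "clozeRejection")

#' Build one cloze instance from an article
#'
#' For the title variant (`BMKC_T`) the document is the tagged,
#' anonymized abstract and the question is the tagged title; for the
#' last-sentence variant (`BMKC_LS`) the abstract's last sentence is the
#' question and is removed from the document. The answer is an entity
#' occurring in both document and question (the one occurring earliest
#' in the question under the default rule, or drawn seeded under
#' `answerRule = "random"`); all its question occurrences become the
#' `"@placeholder"` token. Candidates are the entities occurring in the
#' document, with their 1-based post-anonymization position sets.
#'
#' Articles with no shared entity, a one-sentence abstract (LS), or
#' fewer than `minCandidates` candidates yield a rejection object
#' carrying the reason rather than an instance.
#'
#' @param article list or single-row data.frame with `article_id`,
#'   `title`, `abstract`.
#' @param lexicon a [Lexicon-class].
#' @param variant `"BMKC_T"` or `"BMKC_LS"`.
#' @param answerRule `"first"` or `"random"`.
#' @param seed integer; required for `answerRule = "random"`.
#' @param minCandidates filter threshold, default 21 (strictly more than
#'   20 candidates).
#' @return a [ClozeInstance-class] (entity tokens still canonical, see
#'   [assignIds()]) or a rejection; test with [isRejection()].
#' @export
buildInstance <- function(article, lexicon,
                          variant = c("BMKC_T", "BMKC_LS"),
                          answerRule = c("first", "random"), seed = NULL,
                          minCandidates = 21L) {
  variant <- match.arg(variant)
  answerRule <- match.arg(answerRule)
  id <- as.character(article$article_id)

  abs_tokens <- tokenize(article$abstract)
  if (variant == "BMKC_T") {
    d_raw <- abs_tokens
    q_raw <- tokenize(article$title)
  } else {
    spans <- splitSentences(abs_tokens)
    if (length(spans) < 2L) return(.rejection(id, "empty context"))
    last <- spans[[length(spans)]]
    d_raw <- abs_tokens[seq_len(last[1] - 1L)]
    q_raw <- abs_tokens[last]
  }
  if (length(q_raw) == 0L || length(d_raw) == 0L)
    return(.rejection(id, "empty context"))

  d <- .anonymize(d_raw, tagText(d_raw, lexicon))
  q <- .anonymize(q_raw, tagText(q_raw, lexicon))

  d_entities <- unique(d$tokens[.is_entity_token(d$tokens)])
  q_entity_pos <- which(.is_entity_token(q$tokens))
  shared_pos <- q_entity_pos[q$tokens[q_entity_pos] %in% d_entities]
  if (length(shared_pos) == 0L) return(.rejection(id, "no shared entity"))

  answer <- if (answerRule == "first") {
    q$tokens[shared_pos[1]]
  } else {
    if (is.null(seed)) stop("answerRule 'random' requires a seed")
    withSeed(seed, sample(unique(q$tokens[shared_pos]), 1L))
  }

  ok <- passesFilters(answer, d_entities, q$tokens[q_entity_pos],
                      minCandidates)
  if (!isTRUE(ok)) return(.rejection(id, attr(ok, "reason")))

  q_tokens <- q$tokens
  q_types <- q$types
  mask <- q_tokens == answer
  q_tokens[mask] <- "@placeholder"
  q_types[mask] <- "Unknown"

  positions <- lapply(d_entities, function(ent) which(d$tokens == ent))
  names(positions) <- d_entities

  new("ClozeInstance",
      documentTokens = d$tokens, documentTypes = d$types,
      questionTokens = q_tokens, questionTypes = q_types,
      answer = answer, candidates = d_entities, positions = positions,
      variant = variant, sourceArticleId = id)
}

#' Build a full cloze dataset from articles
#'
#' Runs [buildInstance()] over every article (at most one instance per
#' article per variant), applies the inclusion filters, and assigns
#' anonymized entity-ID tokens via [assignIds()]. The rejection tally is
#' kept in the dataset's `meta`.
#'
#' @param articles data.frame of articles ([readArticlesJsonl()]).
#' @param lexicon a [Lexicon-class].
#' @inheritParams buildInstance
#' @param idMode `"global"` or `"local"` entity-ID assignment.
#' @param seed integer driving the ID assignment (and random answer
#'   selection if requested).
#' @return a [ClozeDataset-class].
#' @export
buildClozeDataset <- function(articles, lexicon,
                              variant = c("BMKC_T", "BMKC_LS"),
                              idMode = c("global", "local"),
                              answerRule = c("first", "random"),
                              minCandidates = 21L, seed = 1L) {
  variant <- match.arg(variant)
  idMode <- match.arg(idMode)
  answerRule <- match.arg(answerRule)
  built <- vector("list", nrow(articles))
  rej <- list()
  for (i in seq_len(nrow(articles))) {
    res <- buildInstance(articles[i, ], lexicon, variant = variant,
                         answerRule = answerRule,
                         seed = if (answerRule == "random") seed + i else NULL,
                         minCandidates = minCandidates)
    if (isRejection(res)) {
      rej[[length(rej) + 1L]] <- data.frame(article_id = res$articleId,
                                            reason = res$reason,
                                            stringsAsFactors = FALSE)
    } else {
      built[[i]] <- res
    }
  }
  built <- built[!vapply(built, is.null, logical(1))]
  rejections <- if (length(rej)) do.call(rbind, rej) else
    data.frame(article_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  assignIds(built, mode = idMode, seed = seed,
            meta = list(rejections = rejections,
                        minCandidates = as.integer(minCandidates)))
}

#' Validate cloze instances against an independent checker
#'
#' Re-derives every dataset invariant from scratch: structural validity,
#' answer membership in both document candidates and question (via the
#' placeholder), the candidate-count floor, exact agreement of every
#' position set with a brute-force rescan of the document, and — for the
#' last-sentence variant — that the question tokens never occur as a
#' contiguous block of the document.
#'
#' @param x a [ClozeDataset-class] or list of instances.
#' @param minCandidates candidate-count floor to enforce.
#' @return data.frame with columns `sourceArticleId`, `valid`, `reason`.
#' @export
validateInstances <- function(x, minCandidates = 21L) {
  insts <- if (is(x, "ClozeDataset")) x@instances else x
  check_one <- function(inst) {
    msg <- tryCatch({ validObject(inst); NA_character_ },
                    error = function(e) conditionMessage(e))
    if (!is.na(msg)) return(msg)
    d <- inst@documentTokens
    if (!inst@answer %in% inst@candidates) return("answer not in candidates")
    if (!"@placeholder" %in% inst@questionTokens)
      return("answer absent from question")
    if (length(unique(inst@candidates)) < minCandidates)
      return("candidate count")
    for (cand in inst@candidates) {
      if (!identical(sort(unique(as.integer(inst@positions[[cand]]))),
                     which(d == cand)))
        return("position set differs from rescan")
    }
    ent_in_d <- unique(d[.is_entity_token(d) | grepl("^@entity[0-9]+$", d)])
    if (!setequal(ent_in_d, inst@candidates))
      return("candidates differ from entities in document")
    if (inst@variant == "BMKC_LS" &&
        .is_subsequence(inst@questionTokens, d))
      return("question is a contiguous block of the document")
    NA_character_
  }
  reasons <- vapply(insts, check_one, character(1))
  data.frame(
    sourceArticleId = vapply(insts, function(i) i@sourceArticleId,
                             character(1)),
    valid = is.na(reasons),
    reason = reasons, stringsAsFactors = FALSE)
}
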