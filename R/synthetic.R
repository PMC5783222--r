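# Synthetic corpus generator: articles and lexicons with the statistical
# shape of the real dataset (about 25 candidate entities per question and
# a few hundred tokens per abstract), plus an optional planted answer cue
# that makes the comprehension task learnable by construction.

.cue_token <- "cuemark"

#' Configuration for the synthetic corpus generator
#'
#' Defaults emulate the corpus shape reported for the full-scale
#' datasets: a mean of about 25.6 candidate entities per document (with
#' a floor of 21 so the candidate-count filter passes by construction)
#' and a mean abstract length of about 291 tokens. `cueStrength` is the
#' probability that an occurrence of the answer entity in the abstract
#' is immediately preceded by a fixed cue token; at 1 the rule "the
#' entity after the cue" identifies the answer perfectly, at 0 the
#' answer is unidentifiable from the document.
#'
#' @param nArticles number of articles to generate.
#' @param vocabSize filler-word vocabulary size (Zipf-distributed use).
#' @param nEntities number of distinct entities in the lexicon.
#' @param entitiesPerDocMean,entitiesPerDocMin mean / minimum distinct
#'   entities per document.
#' @param tokensPerDocMean mean raw abstract length in tokens.
#' @param cueStrength cue co-occurrence probability in `[0, 1]`.
#' @param seed integer; the generator is fully deterministic given it.
#' @return a list of class `synthConfig`.
#' @export
synthConfig <- function(nArticles = 500L, vocabSize = 5000L,
                        nEntities = 400L, entitiesPerDocMean = 25.6,
                        entitiesPerDocMin = 21L, tokensPerDocMean = 291,
                        cueStrength = 1.0, seed = 1L) {
  stopifnot(nArticles > 0, vocabSize > 0, nEntities >= entitiesPerDocMin,
            entitiesPerDocMean >= entitiesPerDocMin,
            tokensPerDocMean > 0, cueStrength >= 0, cueStrength <= 1)
  structure(list(nArticles = as.integer(nArticles),
                 vocabSize = as.integer(vocabSize),
                 nEntities = as.integer(nEntities),
                 entitiesPerDocMean = entitiesPerDocMean,
                 entitiesPerDocMin = as.integer(entitiesPerDocMin),
                 tokensPerDocMean = tokensPerDocMean,
                 cueStrength = cueStrength, seed = as.integer(seed)),
            class = "synthConfig")
}

#' Preset generator configurations
#'
#' `"bmkc-like"` keeps the full corpus shape at 500 articles;
#' `"cue-train"` is a scaled-down corpus (about 80 raw tokens per
#' abstract) sized for desk-scale reader training; `"tiny"` is for fast
#' unit tests.
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @return a `synthConfig`.
#' @export
synthPreset <- function(preset = c("bmkc-like", "cue-train", "tiny"),
                        seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    "bmkc-like" = synthConfig(seed = seed),
    "cue-train" = synthConfig(nArticles = 2000L, vocabSize = 1500L,
                              nEntities = 300L, tokensPerDocMean = 80,
                              seed = seed),
    "tiny" = synthConfig(nArticles = 60L, vocabSize = 300L, nEntities = 80L,
                         entitiesPerDocMean = 24, tokensPerDocMean = 90,
                         seed = seed))
}

.filler_vocab <- function(config) sprintf("w%d", seq_len(config$vocabSize))

#' Generate a synthetic entity lexicon
#'
#' Each of `nEntities` entities gets 1–3 surface forms (a base token, a
#' two-token variant and a hyphenated variant, exercising longest-match
#' and entity resolution) and one raw type label sampled over the
#' curated and MeSH-category inventories (some entities are left
#' untyped).
#'
#' @param config a [synthConfig()].
#' @return data.frame of lexicon entries (`surface`, `entity_id`,
#'   `raw_type`), suitable for [buildLexicon()].
#' @export
generateLexicon <- function(config) {
  withSeed(config$seed, {
    types <- c(.best_types, .mesh_types, NA_character_)
    rows <- lapply(seq_len(config$nEntities), function(i) {
      id <- sprintf("D%06d", i)
      base <- sprintf("bm%04dx", i)
      nsurf <- sample(1:3, 1)
      surfs <- c(base, paste(base, "complex"), sprintf("%s-var", base))[
        seq_len(nsurf)]
      data.frame(surface = surfs, entity_id = id,
                 raw_type = sample(types, 1), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# One article: body interleaving filler tokens and entity mentions with
# sentence periods every 8-15 tokens, a final sentence containing the
# answer, and a title containing exactly the answer entity.
.generate_article <- function(i, config, surf_by_entity, fillers, fprob) {
  k <- min(config$entitiesPerDocMin +
             stats::rpois(1, config$entitiesPerDocMean -
                            config$entitiesPerDocMin),
           config$nEntities)
  ents <- sample(names(surf_by_entity), k)
  answer <- sample(ents, 1)

  pick_surface <- function(ent) {
    ss <- surf_by_entity[[ent]]
    tokenize(if (length(ss) > 1L) sample(ss, 1) else ss)
  }
  # mention units; occurrence count independent of answer status
  units <- list()
  for (ent in ents) {
    for (rep in seq_len(1L + stats::rbinom(1, 1, 0.3))) {
      toks <- pick_surface(ent)
      cued <- ent == answer && stats::runif(1) < config$cueStrength
      units[[length(units) + 1L]] <-
        list(tokens = if (cued) c(.cue_token, toks) else toks,
             entity = ent, cued = cued,
             mention_at = if (cued) 2L else 1L,
             mention_len = length(toks))
    }
  }
  mention_tokens <- sum(vapply(units, function(u) length(u$tokens),
                               integer(1)))
  target <- max(mention_tokens + 10,
                round(stats::rnorm(1, config$tokensPerDocMean,
                                   0.04 * config$tokensPerDocMean)))
  n_filler <- max(0L, round(target - mention_tokens - target / 12 - 10))
  for (f in sample(fillers, n_filler, replace = TRUE, prob = fprob))
    units[[length(units) + 1L]] <- list(tokens = f, entity = NA_character_)
  units <- units[sample.int(length(units))]

  body <- character(0)
  truth <- list()
  since_period <- 0L
  period_gap <- sample(8:15, 1)
  for (u in units) {
    if (!is.na(u$entity)) {
      s <- length(body) + u$mention_at
      truth[[length(truth) + 1L]] <-
        data.frame(entity_id = u$entity, start = s,
                   end = s + u$mention_len - 1L, stringsAsFactors = FALSE)
    }
    body <- c(body, u$tokens)
    since_period <- since_period + length(u$tokens)
    if (since_period >= period_gap) {
      body <- c(body, ".")
      since_period <- 0L
      period_gap <- sample(8:15, 1)
    }
  }
  if (length(body) == 0L || body[length(body)] != ".") body <- c(body, ".")

  # final sentence: fillers + (cue) + answer mention + "."
  last <- sample(fillers, sample(4:7, 1), replace = TRUE, prob = fprob)
  cued_last <- stats::runif(1) < config$cueStrength
  ans_toks <- pick_surface(answer)
  s <- length(body) + length(last) + (if (cued_last) 1L else 0L) + 1L
  truth[[length(truth) + 1L]] <-
    data.frame(entity_id = answer, start = s,
               end = s + length(ans_toks) - 1L, stringsAsFactors = FALSE)
  abstract <- c(body, last, if (cued_last) .cue_token, ans_toks, ".")

  title <- c(sample(fillers, sample(3:6, 1), replace = TRUE, prob = fprob),
             if (stats::runif(1) < config$cueStrength) .cue_token,
             pick_surface(answer))

  list(article = data.frame(article_id = sprintf("SYN%06d", i),
                            title = paste(title, collapse = " "),
                            abstract = paste(abstract, collapse = " "),
                            year = 2016L, stringsAsFactors = FALSE),
       mentions = do.call(rbind, truth), answer_id = answer)
}

#' Generate synthetic articles with known ground truth
#'
#' Abstracts interleave Zipf-distributed filler tokens with entity
#' surface forms (at least `entitiesPerDocMin` distinct entities each),
#' with sentence periods every 8–15 tokens; the title and the final
#' abstract sentence each contain exactly one abstract entity — the
#' planted answer — optionally preceded by the cue token (see
#' [synthConfig()]). The generator's own mention record is returned so
#' taggers can be checked against it.
#'
#' @param config a [synthConfig()].
#' @param lexiconEntries data.frame from [generateLexicon()].
#' @return list with `articles` (data.frame), `mentions` (list of
#'   per-article data.frames of 1-based raw token spans), and `answers`
#'   (named character of planted answer entity ids).
#' @export
generateArticles <- function(config, lexiconEntries) {
  surf_by_entity <- split(lexiconEntries$surface, lexiconEntries$entity_id)
  fillers <- .filler_vocab(config)
  fprob <- 1 / seq_along(fillers) # Zipf frequency skew
  withSeed(config$seed + 1L, {
    gen <- lapply(seq_len(config$nArticles), .generate_article,
                  config = config, surf_by_entity = surf_by_entity,
                  fillers = fillers, fprob = fprob)
    articles <- do.call(rbind, lapply(gen, `[[`, "article"))
    mentions <- lapply(gen, `[[`, "mentions")
    answers <- vapply(gen, `[[`, character(1), "answer_id")
    names(mentions) <- articles$article_id
    names(answers) <- articles$article_id
    list(articles = articles, mentions = mentions, answers = answers)
  })
}

#' Generate a complete synthetic cloze corpus
#'
#' Convenience wrapper: lexicon, articles, and the built dataset in one
#' call, returning ground truth alongside.
#'
#' @param config a [synthConfig()].
#' @param variant,idMode passed to [buildClozeDataset()].
#' @return list with `lexicon`, `lexiconEntries`, `articles`, `truth`
#'   (mentions + answers) and `dataset`.
#' @export
generateClozeCorpus <- function(config, variant = "BMKC_T",
                                idMode = "global") {
  entries <- generateLexicon(config)
  lex <- buildLexicon(entries)
  gen <- generateArticles(config, entries)
  ds <- buildClozeDataset(gen$articles, lex, variant = variant,
                          idMode = idMode, seed = config$seed)
  list(lexicon = lex, lexiconEntries = entries, articles = gen$articles,
       truth = list(mentions = gen$mentions, answers = gen$answers),
       dataset = ds)
}
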