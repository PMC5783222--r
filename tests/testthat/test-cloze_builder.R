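# A hand-written article in the style of a title/last-sentence pair:
# the title and the last sentence each share one entity with the body.
handArticle <- function() {
  list(article_id = "H1",
       title = "NCOA1 promotes breast cancer spread",
       abstract = paste(
         "Overexpression of NCOA1 is linked to breast cancer recurrence.",
         "In mice the mammary gland showed altered CSF1 signalling.",
         "Together these results define an NCOA1/AP-1/CSF1 axis in",
         "breast tumors."))
}

test_that("title-variant instance masks the shared entity in the question", {
  inst <- buildInstance(handArticle(), fixtureLexicon(), variant = "BMKC_T",
                        minCandidates = 2L)
  expect_s4_class(inst, "ClozeInstance")
  expect_equal(answerToken(inst), "@@E_NCOA1")
  expect_equal(questionTokens(inst)[1], "@placeholder")
  expect_false("@@E_NCOA1" %in% questionTokens(inst))
  # synonyms resolve: "breast cancer" and "breast tumors" are one candidate
  expect_equal(sum(candidates(inst) == "@@E_BC"), 1L)
  expect_equal(length(mentionPositions(inst)[["@@E_BC"]]), 2L)
  # entity type travels with the mention
  expect_equal(unique(inst@documentTypes[mentionPositions(inst)[["@@E_NCOA1"]]]),
               "Gene")
})

test_that("last-sentence variant removes the question sentence from the context", {
  inst <- buildInstance(handArticle(), fixtureLexicon(), variant = "BMKC_LS",
                        minCandidates = 2L)
  expect_s4_class(inst, "ClozeInstance")
  expect_equal(variantOf(inst), "BMKC_LS")
  # the question is the final sentence, with its first shared entity blanked
  expect_equal(answerToken(inst), "@@E_NCOA1")
  expect_true("@placeholder" %in% questionTokens(inst))
  # d excludes the last sentence entirely
  expect_false(any(grepl("Together", documentTokens(inst))))
  expect_false(any(grepl("axis", documentTokens(inst))))
})

test_that("articles without usable structure are rejected with a reason", {
  lex <- fixtureLexicon()
  noShared <- list(article_id = "H2", title = "Nothing relevant here",
                   abstract = "CSF1 and mice were observed. The end came.")
  r <- buildInstance(noShared, lex, variant = "BMKC_T", minCandidates = 2L)
  expect_true(isRejection(r))
  expect_equal(r$reason, "no shared entity")
  oneSentence <- list(article_id = "H3", title = "NCOA1 again",
                      abstract = "NCOA1 was measured in mice")
  r2 <- buildInstance(oneSentence, lex, variant = "BMKC_LS",
                      minCandidates = 2L)
  expect_true(isRejection(r2))
  expect_equal(r2$reason, "empty context")
  small <- buildInstance(handArticle(), lex, variant = "BMKC_T",
                         minCandidates = 21L)
  expect_true(isRejection(small))
  expect_equal(small$reason, "candidate count")
})

test_that("inclusion filters agree with an exhaustive oracle", {
  # all combinations of (answer in d, answer in q, |A| in {20, 21, 25})
  for (inD in c(TRUE, FALSE)) for (inQ in c(TRUE, FALSE))
    for (nA in c(20L, 21L, 25L)) {
      cands <- sprintf("@@C%02d", seq_len(nA))
      answer <- if (inD) cands[1] else "@@OUTSIDER"
      qEnts <- if (inQ) c("@@Q1", answer) else "@@Q1"
      got <- passesFilters(answer, cands, qEnts, minCandidates = 21L)
      oracle <- (answer %in% cands) && (answer %in% qEnts) && (nA > 20L)
      expect_equal(as.logical(got), oracle,
                   info = sprintf("inD=%s inQ=%s nA=%d", inD, inQ, nA))
      if (!oracle) {
        expected <- if (!inD || !inQ) "answer not in both" else
          "candidate count"
        expect_equal(attr(got, "reason"), expected)
      }
    }
})

test_that("global ID assignment is stable across documents", {
  corp <- tinyCorpus()
  ds <- corp$dataset
  expect_equal(idMode(ds), "global")
  map <- ds@idMap
  # injective corpus-wide map
  expect_false(anyDuplicated(map) > 0)
  expect_true(all(grepl("^@entity[0-9]+$", map)))
  # re-running the assignment reproduces the same tokens bit-identically
  cfg <- synthPreset("tiny", seed = 7)
  again <- generateClozeCorpus(cfg)
  expect_identical(lapply(instances(ds), documentTokens),
                   lapply(instances(again$dataset), documentTokens))
})

test_that("local IDs restart at 1 per instance and differ across documents", {
  cfg <- synthPreset("tiny", seed = 7)
  corpG <- generateClozeCorpus(cfg, idMode = "global")
  corpL <- generateClozeCorpus(cfg, idMode = "local")
  dsL <- corpL$dataset
  for (inst in instances(dsL)[1:5]) {
    ents <- unique(c(documentTokens(inst), questionTokens(inst)))
    nums <- sort(as.integer(sub("@entity", "",
                                ents[grepl("^@entity", ents)])))
    expect_equal(nums, seq_along(nums)) # numbering restarts at 1
  }
  expect_s4_class(corpG$dataset, "ClozeDataset")
  # the same underlying entity may get different tokens in different docs
  gmaps <- dsL@idMap
  sharedTokens <- unlist(lapply(gmaps, names))
  dup <- names(which(table(sharedTokens) > 1))[1]
  if (!is.na(dup)) {
    toks <- unlist(lapply(gmaps, function(m) unname(m[dup])), use.names = FALSE)
    toks <- toks[!is.na(toks)]
    expect_gt(length(unique(toks)), 1L)
  }
  # determinism under the seed
  corpL2 <- generateClozeCorpus(cfg, idMode = "local")
  expect_identical(lapply(instances(dsL), documentTokens),
                   lapply(instances(corpL2$dataset), documentTokens))
})

test_that("corpus splitting is exhaustive, disjoint and group-preserving", {
  corp <- tinyCorpus()
  ds <- corp$dataset
  n <- nInstances(ds)
  sp <- splitCorpus(ds, c(train = 0.8, validation = 0.1, test = 0.1),
                    seed = 3)
  sizes <- vapply(sp, nInstances, integer(1))
  expect_equal(sum(sizes), n)
  expect_true(all(abs(sizes - n * c(0.8, 0.1, 0.1)) <= 1))
  ids <- lapply(sp, function(d)
    vapply(instances(d), function(i) i@sourceArticleId, character(1)))
  expect_equal(length(unique(unlist(ids))), n)
  # grouping keeps all instances of one key together
  groups <- rep(sprintf("file%d", 1:4), length.out = n)
  spg <- splitCorpus(ds, c(train = 0.5, validation = 0.25, test = 0.25),
                     groups = groups, seed = 3)
  dsIds <- vapply(instances(ds), function(i) i@sourceArticleId, character(1))
  allg <- lapply(spg, function(part)
    unique(groups[match(
      vapply(instances(part), function(i) i@sourceArticleId, character(1)),
      dsIds)]))
  expect_equal(sum(lengths(allg)), 4L) # no file spans partitions
  # determinism
  sp2 <- splitCorpus(ds, c(train = 0.8, validation = 0.1, test = 0.1),
                     seed = 3)
  expect_identical(lapply(sp$train@instances, documentTokens),
                   lapply(sp2$train@instances, documentTokens))
  expect_error(splitCorpus(ds, c(a = 0.999, b = 0.001)), "empty partition")
})

test_that("datasets round-trip through the line-delimited format", {
  corp <- tinyCorpus()
  ds <- corp$dataset
  small <- new("ClozeDataset", instances = instances(ds)[1:5],
               idMode = ds@idMode, idMap = list(), seed = ds@seed,
               meta = list())
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeClozeDataset(small, path)
  back <- readClozeDataset(path)
  expect_equal(nInstances(back), 5L)
  for (k in 1:5) {
    a <- instances(small)[[k]]; b <- instances(back)[[k]]
    expect_identical(documentTokens(a), documentTokens(b))
    expect_identical(questionTokens(a), questionTokens(b))
    expect_identical(answerToken(a), answerToken(b))
    expect_identical(mentionPositions(a)[candidates(a)],
                     mentionPositions(b)[candidates(b)])
  }
})

test_that("question-file export carries the full tuple", {
  corp <- tinyCorpus()
  inst <- instances(corp$dataset)[[1]]
  dir <- withr::local_tempdir()
  path <- exportQuestionFile(inst, dir)
  lines <- readLines(path)
  expect_equal(lines[1], inst@sourceArticleId)
  expect_equal(lines[3], paste(documentTokens(inst), collapse = " "))
  expect_equal(lines[5], paste(questionTokens(inst), collapse = " "))
  expect_equal(lines[7], answerToken(inst))
  expect_equal(length(lines), 8L + length(candidates(inst)))
})

test_that("emitted instances satisfy every invariant on a seeded corpus", {
  for (variant in c("BMKC_T", "BMKC_LS")) {
    corp <- tinyCorpus(variant)
    v <- validateInstances(corp$dataset)
    expect_true(all(v$valid),
                info = paste(variant, unique(stats::na.omit(v$reason))))
    # one instance per article per variant
    ids <- vapply(instances(corp$dataset), function(i) i@sourceArticleId,
                  character(1))
    expect_false(anyDuplicated(ids) > 0)
  }
})
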