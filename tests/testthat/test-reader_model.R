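toyTokens <- function() c("@entity1", "@entity2", "@entity3", "the", "cue",
                          "binds", "@placeholder", ".")

test_that("embedding initialization copies pretrained rows and bounds the rest", {
  wvPath <- withr::local_tempfile(fileext = ".vec")
  writeWordVecFixture(wvPath, list(the = c(0.5, -0.5, 0.25, 0.125, 1),
                                   BINDS = c(1, 2, 3, 4, 5)))
  wv <- readWordVectors(wvPath)
  emb <- initEmbeddings(c("the", "binds", "@entity1"), wordVectors = wv,
                        wordDim = 5L, typeDim = 4L, seed = 2L)
  expect_identical(unname(emb$Wword["the", ]), c(0.5, -0.5, 0.25, 0.125, 1))
  # case-insensitive match against the pretrained table
  expect_identical(unname(emb$Wword["binds", ]), c(1, 2, 3, 4, 5))
  expect_true(all(abs(emb$Wword["@entity1", ]) < 0.25))
  expect_true(all(abs(emb$Wtype) < 0.25))
  expect_equal(rownames(emb$Wtype), typeVocabulary())
  expect_error(initEmbeddings("x", wordVectors = wv, wordDim = 3L),
               "dimension")
})

test_that("encoders produce the contracted shapes and obey reversal symmetry", {
  m <- makeToyReader(toyTokens(), hiddenSize = 4L)
  toks <- c("@entity1", "binds", "@entity2", "the")
  F <- encodeContext(m, toks)
  expect_equal(dim(F), c(8L, 4L))
  g <- encodeQuery(m, c("cue", "@placeholder", "."))
  expect_length(g, 8L)
  expect_error(encodeContext(m, character(0)), "empty")
  # distinct questions get distinct encodings under random weights
  g2 <- encodeQuery(m, c("binds", "@placeholder"))
  expect_gt(max(abs(g - g2)), 0)

  # with backward weights tied to forward weights, reversing the document
  # swaps the forward/backward halves at mirrored positions
  w <- m@weights
  w$cb_Wx <- w$cf_Wx; w$cb_Wh <- w$cf_Wh; w$cb_b <- w$cf_b
  mt <- m; mt@weights <- w
  Fw <- encodeContext(mt, toks)
  Rv <- encodeContext(mt, rev(toks))
  n <- length(toks)
  for (i in seq_len(n)) {
    expect_equal(unname(Fw[1:4, i]), unname(Rv[5:8, n + 1 - i]),
                 tolerance = 1e-12)
    expect_equal(unname(Fw[5:8, i]), unname(Rv[1:4, n + 1 - i]),
                 tolerance = 1e-12)
  }
})

test_that("a single recurrence step matches the hand-computed gate equations", {
  set.seed(5)
  H <- 3L; D <- 2L
  Wx <- matrix(rnorm(3 * H * D), 3 * H, D)
  Wh <- matrix(rnorm(3 * H * H), 3 * H, H)
  b <- rnorm(3 * H)
  x <- c(0.3, -0.7)
  got <- biocloze:::cpp_gru_step(x, Wx, Wh, b, H)
  sig <- function(v) 1 / (1 + exp(-v))
  pre <- drop(Wx %*% x + b) # previous state is zero
  z <- sig(pre[(H + 1):(2 * H)])
  n <- tanh(pre[(2 * H + 1):(3 * H)])
  expect_equal(drop(got), (1 - z) * n, tolerance = 1e-12)
})

test_that("attention softmax matches closed forms and normalizes", {
  # via the exported pure function
  expect_equal(attentionDistribution(matrix(1, 1, 1), 1), 1)
  F <- matrix(0, 2, 4) # all dot products equal -> uniform
  expect_equal(attentionDistribution(F, c(1, 1)), rep(0.25, 4))
  F2 <- rbind(c(log(2), 0, 0), c(0, 0, 0))
  expect_equal(attentionDistribution(F2, c(1, 0)), c(0.5, 0.25, 0.25))
  expect_error(attentionDistribution(matrix(0, 3, 2), c(1, 1)), "width")
  # full forward pass normalizes
  m <- makeToyReader(toyTokens())
  inst <- makeInstance(
    d = c("@entity1", "binds", "@entity2", "the", "@entity1", "."),
    q = c("cue", "@placeholder", "."), answer = "@entity2")
  res <- predictReader(m, inst)
  expect_equal(sum(res$positionProbs), 1, tolerance = 1e-6)
  expect_true(all(res$positionProbs >= 0))
})

test_that("pointer-sum aggregates mention probabilities and breaks ties", {
  ps <- pointerSum(c(0.5, 0.3, 0.2), list(A = c(1L, 3L), B = 2L))
  expect_equal(unname(ps$candidateProbs["A"]), 0.7)
  expect_equal(unname(ps$candidateProbs["B"]), 0.3)
  expect_equal(ps$predicted, "A")
  expect_error(pointerSum(c(0.5, 0.5), list(A = 3L)), "out of range")
  # exact tie resolves to the earliest first occurrence
  tie <- pointerSum(c(0.25, 0.25, 0.25, 0.25), list(B = c(2L, 4L),
                                                    A = c(1L, 3L)))
  expect_equal(tie$predicted, "A")
  # brute-force double loop oracle on random batteries
  set.seed(8)
  for (rep in 1:50) {
    n <- sample(3:30, 1)
    s <- stats::runif(n); s <- s / sum(s)
    k <- sample(2:6, 1)
    pos <- lapply(seq_len(k), function(i)
      sort(sample(n, sample(seq_len(min(4, n)), 1))))
    names(pos) <- sprintf("C%d", seq_len(k))
    got <- pointerSum(s, pos)$candidateProbs
    oracle <- vapply(pos, function(idx) {
      tot <- 0
      for (i in idx) tot <- tot + s[i]
      tot
    }, numeric(1))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("untrained reader prediction is deterministic and well-defined", {
  m <- makeToyReader(toyTokens())
  inst <- makeInstance(
    d = c("@entity1", "binds", "@entity2", "the", "@entity3", "."),
    q = c("cue", "@placeholder", "."), answer = "@entity2")
  r1 <- predictReader(m, inst, n = 2L)
  r2 <- predictReader(m, inst, n = 10L)
  expect_identical(r1$ranked, r2$ranked)
  expect_equal(length(r2$topN), 3L) # n beyond |A| yields the full ranking
  expect_equal(r1$topN, r1$ranked[1:2])
  # out-of-vocabulary tokens fall back to the unk row without error
  inst2 <- makeInstance(d = c("@entity1", "neverseen", "@entity2", "."),
                        q = c("@placeholder", "unknownword"),
                        answer = "@entity1")
  expect_no_error(predictReader(m, inst2))
})

test_that("type embeddings are inert when disabled and widen input when on", {
  toks <- toyTokens()
  mOn <- makeToyReader(toks, useType = TRUE, typeDim = 3L, seed = 4L)
  expect_equal(nrow(biocloze:::.embed_matrix(mOn, "the")),
               mOn@config$wordDim + 3L)
  mOff <- makeToyReader(toks, useType = FALSE, typeDim = 3L, seed = 4L)
  expect_equal(nrow(biocloze:::.embed_matrix(mOff, "the")),
               mOff@config$wordDim)
  # corrupting the (absent) type rows cannot change a no-type forward pass
  inst <- makeInstance(d = c("@entity1", "the", "@entity2", "."),
                       q = c("@placeholder", "binds"), answer = "@entity1")
  base <- predictReader(mOff, inst)
  mOff2 <- mOff
  mOff2@weights$Wtype <- matrix(999, 5, 3)
  expect_identical(predictReader(mOff2, inst)$candidateProbs,
                   base$candidateProbs)
})

test_that("consistent entity relabeling leaves probabilities unchanged", {
  toks <- toyTokens()
  m <- makeToyReader(toks, seed = 9L)
  inst <- makeInstance(
    d = c("@entity1", "binds", "@entity2", "the", "@entity3", "@entity1"),
    q = c("cue", "@placeholder", "."), answer = "@entity2")
  res <- predictReader(m, inst)
  # swap entity1 <-> entity3 in the instance and in the embedding rows
  relab <- c("@entity1" = "@entity3", "@entity3" = "@entity1",
             "@entity2" = "@entity2")
  sw <- function(x) ifelse(x %in% names(relab), relab[x], x)
  inst2 <- makeInstance(d = unname(sw(documentTokens(inst))),
                        q = unname(sw(questionTokens(inst))),
                        answer = "@entity2")
  m2 <- m
  rn <- rownames(m2@weights$Wword)
  i1 <- match("@entity1", rn); i3 <- match("@entity3", rn)
  m2@weights$Wword[c(i1, i3), ] <- m2@weights$Wword[c(i3, i1), ]
  res2 <- predictReader(m2, inst2)
  p1 <- res$candidateProbs
  p2 <- res2$candidateProbs[unname(sw(names(p1)))]
  expect_equal(unname(p2), unname(p1), tolerance = 1e-12)
})

test_that("training overfits one instance and is seed-reproducible", {
  corp <- tinyCorpus()
  inst <- instances(corp$dataset)[[1]]
  cfg <- readerConfig(hiddenSize = 6L, wordDim = 8L, typeDim = 3L,
                      maxEpochs = 5L, patience = 5L, batchSize = 1L,
                      learningRate = 0.01, seed = 2L)
  m <- trainReader(list(inst), list(inst), cfg)
  losses <- epochLog(m)$trainLoss
  expect_length(losses, 5L)
  expect_true(all(diff(losses) < 0)) # strictly decreasing
  m2 <- trainReader(list(inst), list(inst), cfg)
  expect_identical(epochLog(m), epochLog(m2))
  expect_identical(m@weights, m2@weights)
})

test_that("analytic gradients match finite differences on a toy model", {
  corp <- tinyCorpus()
  insts <- instances(corp$dataset)[1:2]
  cfg <- readerConfig(hiddenSize = 3L, wordDim = 4L, typeDim = 2L, seed = 3L)
  typeLevels <- typeVocabulary()
  vocab <- c("<unk>", sort(unique(unlist(lapply(insts, function(i)
    c(documentTokens(i), questionTokens(i)))))))
  w <- biocloze:::.init_weights(vocab, cfg, NULL, typeLevels)
  ix <- lapply(insts, biocloze:::.index_instance, vocab = vocab,
               typeLevels = typeLevels)
  lossOf <- function(w) biocloze:::.batch_grad(ix, w, 3L, TRUE)$loss
  res <- biocloze:::.batch_grad(ix, w, 3L, TRUE)
  set.seed(42)
  h <- 1e-5
  for (nm in biocloze:::.grad_names(TRUE)) {
    for (k in sample(length(w[[nm]]), min(5, length(w[[nm]])))) {
      wp <- w; wp[[nm]][k] <- wp[[nm]][k] + h
      wm <- w; wm[[nm]][k] <- wm[[nm]][k] - h
      fd <- (lossOf(wp) - lossOf(wm)) / (2 * h)
      an <- res$grads[[nm]][k]
      rel <- abs(fd - an) / max(1e-8, abs(fd) + abs(an))
      expect_lt(rel, 1e-4)
    }
  }
})

test_that("checkpoints round-trip through save/load", {
  m <- makeToyReader(toyTokens())
  path <- withr::local_tempfile(fileext = ".rds")
  saveReaderModel(m, path)
  m2 <- loadReaderModel(path)
  expect_identical(m@weights, m2@weights)
  expect_identical(m@vocab, m2@vocab)
  expect_identical(m@config, m2@config)
})
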