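# Training loop: Adam on the negative log pointer-sum probability.

.grad_names <- function(useType) {
  nm <- c("Wword", "cf_Wx", "cf_Wh", "cf_b", "cb_Wx", "cb_Wh", "cb_b",
          "qf_Wx", "qf_Wh", "qf_b", "qb_Wx", "qb_Wh", "qb_b")
  if (useType) c(nm, "Wtype") else nm
}

# initial full weight set for a vocabulary
.init_weights <- function(vocab, config, wordVectors, typeLevels) {
  emb <- initEmbeddings(vocab, wordVectors, wordDim = config$wordDim,
                        typeDim = if (config$useTypeEmbedding)
                          config$typeDim else 0L,
                        typeLevels = typeLevels, seed = config$seed)
  D <- config$wordDim +
    if (config$useTypeEmbedding) config$typeDim else 0L
  H <- config$hiddenSize
  gru <- withSeed(config$seed + 1L, list(
    cf = .init_gru(H, D), cb = .init_gru(H, D),
    qf = .init_gru(H, D), qb = .init_gru(H, D)))
  w <- list(Wword = emb$Wword)
  if (config$useTypeEmbedding) w$Wtype <- emb$Wtype
  for (enc in c("cf", "cb", "qf", "qb")) {
    w[[paste0(enc, "_Wx")]] <- gru[[enc]]$Wx
    w[[paste0(enc, "_Wh")]] <- gru[[enc]]$Wh
    w[[paste0(enc, "_b")]] <- gru[[enc]]$b
  }
  w
}

#' Initialize an untrained reader
#'
#' Builds a [ReaderModel-class] with freshly initialized weights over a
#' given vocabulary, without training. Useful for forward-pass
#' inspection and as the starting point [trainReader()] optimizes.
#'
#' @param vocab token vocabulary (the `"<unk>"` row is added if absent).
#' @param config a [readerConfig()].
#' @param wordVectors optional [WordVectorTable-class] for row
#'   initialization.
#' @return an untrained [ReaderModel-class] (`validationAccuracy` is
#'   `NA`).
#' @export
initReader <- function(vocab, config, wordVectors = NULL) {
  stopifnot(inherits(config, "readerConfig"))
  if (!.unk_token %in% vocab) vocab <- c(.unk_token, vocab)
  typeLevels <- typeVocabulary()
  weights <- .init_weights(vocab, config, wordVectors, typeLevels)
  new("ReaderModel", config = unclass(config), vocab = vocab,
      typeLevels = typeLevels, weights = weights,
      epochLog = data.frame(), valAccuracy = NA_real_,
      seed = config$seed)
}

.as_instance_list <- function(x) {
  if (is(x, "ClozeDataset")) x@instances
  else if (is.list(x)) x
  else stop("expected a ClozeDataset or a list of instances")
}

# loss/gradient evaluation for a set of index-form instances
.batch_grad <- function(ix, weights, H, useType) {
  cpp_asr_batch(lapply(ix, `[[`, "doc"), lapply(ix, `[[`, "dtype"),
                lapply(ix, `[[`, "qry"), lapply(ix, `[[`, "qtype"),
                lapply(ix, `[[`, "anspos"),
                weights$Wword,
                if (useType) weights$Wtype else .empty_type_mat,
                weights, H, useType)
}

.val_accuracy <- function(model, valInstances) {
  if (length(valInstances) == 0L) return(NA_real_)
  ok <- vapply(valInstances, function(inst)
    predictReader(model, inst)$predicted == inst@answer, logical(1))
  mean(ok)
}

#' Train an attention-sum reader
#'
#' Minimizes `-log P(a|d,q)` of the pointer-sum probability of the
#' correct candidate, averaged per minibatch, by Adam with global
#' gradient-norm clipping. The vocabulary is built from the training
#' instances plus a dedicated `"<unk>"` row. After every epoch the
#' validation accuracy is measured; the epoch snapshot with the best
#' validation accuracy is returned, and training stops early after
#' `patience` epochs without improvement. Fully reproducible under the
#' config seed.
#'
#' @param train,validation [ClozeDataset-class] objects or instance
#'   lists; instances are validated structurally before training.
#' @param config a [readerConfig()].
#' @param wordVectors optional [WordVectorTable-class] used to
#'   initialize word rows ([initEmbeddings()]).
#' @param verbose print per-epoch progress.
#' @return a trained [ReaderModel-class] with its per-epoch log.
#' @export
trainReader <- function(train, validation, config, wordVectors = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(config, "readerConfig"))
  trainI <- .as_instance_list(train)
  valI <- .as_instance_list(validation)
  if (length(trainI) == 0L || length(valI) == 0L)
    stop("empty training or validation split")
  for (inst in trainI) validObject(inst)

  typeLevels <- typeVocabulary()
  vocab <- c(.unk_token,
             sort(unique(unlist(lapply(trainI, function(i)
               c(i@documentTokens, i@questionTokens))))))
  weights <- .init_weights(vocab, config, wordVectors, typeLevels)
  useType <- isTRUE(config$useTypeEmbedding)
  H <- config$hiddenSize
  nm <- .grad_names(useType)

  ixTrain <- lapply(trainI, .index_instance, vocab = vocab,
                    typeLevels = typeLevels)

  mkModel <- function(w, log, best) {
    new("ReaderModel", config = unclass(config), vocab = vocab,
        typeLevels = typeLevels, weights = w, epochLog = log,
        valAccuracy = best, seed = config$seed)
  }

  m1 <- lapply(weights[nm], function(w) w * 0)
  m2 <- m1
  stepCount <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  log <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                    valAccuracy = numeric(0))
  bestAcc <- -Inf
  bestW <- weights
  sinceBest <- 0L

  withSeed(config$seed + 2L, {
    for (epoch in seq_len(config$maxEpochs)) {
      ord <- sample.int(length(ixTrain))
      epochLoss <- 0
      for (start in seq(1L, length(ord), by = config$batchSize)) {
        idx <- ord[start:min(start + config$batchSize - 1L, length(ord))]
        B <- length(idx)
        res <- .batch_grad(ixTrain[idx], weights, H, useType)
        epochLoss <- epochLoss + res$loss
        g <- lapply(res$grads[nm], function(x) x / B)
        gn <- sqrt(sum(vapply(g, function(x) sum(x * x), numeric(1))))
        if (is.finite(gn) && gn > config$clipNorm)
          g <- lapply(g, function(x) x * (config$clipNorm / gn))
        stepCount <- stepCount + 1L
        c1 <- 1 - beta1^stepCount
        c2 <- 1 - beta2^stepCount
        for (k in nm) {
          m1[[k]] <- beta1 * m1[[k]] + (1 - beta1) * g[[k]]
          m2[[k]] <- beta2 * m2[[k]] + (1 - beta2) * g[[k]]^2
          weights[[k]] <- weights[[k]] -
            config$learningRate * (m1[[k]] / c1) /
            (sqrt(m2[[k]] / c2) + eps)
        }
      }
      acc <- .val_accuracy(mkModel(weights, log, NA_real_), valI)
      log <- rbind(log, data.frame(epoch = epoch,
                                   trainLoss = epochLoss / length(ixTrain),
                                   valAccuracy = acc))
      if (verbose)
        message(sprintf("epoch %d: loss %.4f, val acc %.3f", epoch,
                        epochLoss / length(ixTrain), acc))
      if (!is.na(acc) && acc > bestAcc) {
        bestAcc <- acc
        bestW <- weights
        sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= config$patience) break
      }
    }
  })
  mkModel(bestW, log, bestAcc)
}
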