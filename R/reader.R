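# Attention-sum reader: embeddings, encoders, attention, pointer-sum.

.unk_token <- "<unk>"

#' Reader hyper-parameters
#'
#' @param hiddenSize GRU hidden units per direction.
#' @param wordDim word-embedding dimension (200 matches common
#'   biomedical pretrained vectors).
#' @param typeDim entity-type embedding dimension, concatenated to the
#'   word vector when `useTypeEmbedding` is on.
#' @param useTypeEmbedding concatenate a learned type vector per token.
#' @param learningRate Adam step size (0.001 or 0.0005 are the usual
#'   choices for this model family).
#' @param batchSize minibatch size.
#' @param maxEpochs epoch budget.
#' @param patience epochs without validation improvement before stopping.
#' @param clipNorm global gradient-norm clip.
#' @param seed seed for initialization and batch order.
#' @return list of class `readerConfig`.
#' @export
readerConfig <- function(hiddenSize = 128L, wordDim = 200L, typeDim = 20L,
                         useTypeEmbedding = TRUE, learningRate = 0.001,
                         batchSize = 32L, maxEpochs = 20L, patience = 3L,
                         clipNorm = 10, seed = 1L) {
  stopifnot(hiddenSize > 0, wordDim > 0, typeDim >= 0, learningRate > 0,
            batchSize > 0, maxEpochs > 0, patience > 0)
  structure(list(hiddenSize = as.integer(hiddenSize),
                 wordDim = as.integer(wordDim),
                 typeDim = as.integer(typeDim),
                 useTypeEmbedding = isTRUE(useTypeEmbedding) && typeDim > 0,
                 learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience),
                 clipNorm = clipNorm, seed = as.integer(seed)),
            class = "readerConfig")
}

#' Initialize the embedding matrices
#'
#' Tokens found (case-insensitively) in the pretrained table copy their
#' vector; every other word row — and every type row — is drawn
#' uniformly from the open interval (-0.25, 0.25) under `seed`. All rows
#' remain trainable.
#'
#' @param vocab character vector of tokens.
#' @param wordVectors optional [WordVectorTable-class]; its dimension
#'   must equal `wordDim`.
#' @param wordDim,typeDim embedding widths (`typeDim = 0` disables the
#'   type rows).
#' @param typeLevels merged type vocabulary.
#' @param seed integer.
#' @return list with `Wword` (rownames `vocab`) and `Wtype` (rownames
#'   `typeLevels`, or `NULL` when `typeDim` is 0).
#' @export
initEmbeddings <- function(vocab, wordVectors = NULL, wordDim = 200L,
                           typeDim = 20L, typeLevels = typeVocabulary(),
                           seed = 1L) {
  if (!is.null(wordVectors)) {
    stopifnot(is(wordVectors, "WordVectorTable"))
    if (wordVectors@dim != wordDim)
      stop(sprintf("pretrained dimension %d does not match wordDim %d",
                   wordVectors@dim, wordDim))
  }
  withSeed(seed, {
    V <- length(vocab)
    Wword <- matrix(stats::runif(V * wordDim, -0.25, 0.25), nrow = V,
                    dimnames = list(vocab, NULL))
    Wtype <- if (typeDim > 0)
      matrix(stats::runif(length(typeLevels) * typeDim, -0.25, 0.25),
             nrow = length(typeLevels), dimnames = list(typeLevels, NULL))
    else NULL
    if (!is.null(wordVectors)) {
      hit <- match(tolower(vocab), tolower(rownames(wordVectors@vectors)))
      found <- which(!is.na(hit))
      if (length(found))
        Wword[found, ] <- wordVectors@vectors[hit[found], , drop = FALSE]
    }
    list(Wword = Wword, Wtype = Wtype)
  })
}

# Glorot-uniform GRU parameter block (3 stacked gates).
.init_gru <- function(H, D) {
  lim_x <- sqrt(6 / (D + H))
  lim_h <- sqrt(6 / (H + H))
  list(Wx = matrix(stats::runif(3 * H * D, -lim_x, lim_x), nrow = 3 * H),
       Wh = matrix(stats::runif(3 * H * H, -lim_h, lim_h), nrow = 3 * H),
       b = numeric(3 * H))
}

.empty_type_mat <- matrix(0, 1, 1)

.model_type_mat <- function(model) {
  if (isTRUE(model@config$useTypeEmbedding)) model@weights$Wtype
  else .empty_type_mat
}

.lookup_tokens <- function(tokens, vocab) {
  idx <- match(tokens, vocab)
  idx[is.na(idx)] <- match(.unk_token, vocab)
  as.integer(idx)
}

.lookup_types <- function(types, typeLevels) {
  idx <- match(types, typeLevels)
  idx[is.na(idx)] <- match("Unknown", typeLevels)
  as.integer(idx)
}

# token/type index representation of one instance under a model
.index_instance <- function(inst, vocab, typeLevels) {
  list(doc = .lookup_tokens(inst@documentTokens, vocab),
       dtype = .lookup_types(inst@documentTypes, typeLevels),
       qry = .lookup_tokens(inst@questionTokens, vocab),
       qtype = .lookup_types(inst@questionTypes, typeLevels),
       anspos = as.integer(inst@positions[[inst@answer]]))
}

.embed_matrix <- function(model, tokens, types = NULL) {
  w <- model@weights
  idx <- .lookup_tokens(tokens, model@vocab)
  X <- t(w$Wword[idx, , drop = FALSE])
  if (isTRUE(model@config$useTypeEmbedding)) {
    if (is.null(types)) types <- rep("Unknown", length(tokens))
    tidx <- .lookup_types(types, model@typeLevels)
    X <- rbind(X, t(w$Wtype[tidx, , drop = FALSE]))
  }
  dimnames(X) <- NULL
  X
}

#' Encode a document with the bidirectional context encoder
#'
#' Position `i` of the result stacks the forward GRU state after reading
#' tokens `1..i` over the backward state after reading `n..i`; width
#' `2 * hiddenSize` per position.
#'
#' @param model a [ReaderModel-class].
#' @param tokens document tokens.
#' @param types optional per-token type labels.
#' @return numeric matrix, `2 * hiddenSize` rows by `length(tokens)`
#'   columns.
#' @export
encodeContext <- function(model, tokens, types = NULL) {
  if (length(tokens) == 0L) stop("empty document")
  w <- model@weights
  X <- .embed_matrix(model, tokens, types)
  cpp_bigru(X, w$cf_Wx, w$cf_Wh, w$cf_b, w$cb_Wx, w$cb_Wh, w$cb_b,
            model@config$hiddenSize)
}

#' Encode a question with the bidirectional query encoder
#'
#' Returns the concatenation of the forward encoder's final state and
#' the backward encoder's final state (a single vector of width
#' `2 * hiddenSize`). The placeholder participates like any token.
#'
#' @inheritParams encodeContext
#' @return numeric vector of length `2 * hiddenSize`.
#' @export
encodeQuery <- function(model, tokens, types = NULL) {
  if (length(tokens) == 0L) stop("empty question")
  w <- model@weights
  X <- .embed_matrix(model, tokens, types)
  H <- model@config$hiddenSize
  out <- cpp_bigru(X, w$qf_Wx, w$qf_Wh, w$qf_b, w$qb_Wx, w$qb_Wh, w$qb_b, H)
  Tq <- ncol(out)
  c(out[seq_len(H), Tq], out[H + seq_len(H), 1L])
}

#' Attention distribution over document positions
#'
#' `s_i = softmax_i(<f_i(d), g(q)>)`, computed with max-subtraction for
#' overflow safety.
#'
#' @param contextEncodings matrix from [encodeContext()].
#' @param queryEncoding vector from [encodeQuery()].
#' @return numeric vector summing to 1 over positions.
#' @export
attentionDistribution <- function(contextEncodings, queryEncoding) {
  if (nrow(contextEncodings) != length(queryEncoding))
    stop("encoder widths do not match")
  z <- drop(crossprod(contextEncodings, queryEncoding))
  e <- exp(z - max(z))
  e / sum(e)
}

# rank candidates by probability, ties to the earliest first occurrence
.rank_candidates <- function(p, positions) {
  firstpos <- vapply(positions[names(p)], min, numeric(1))
  names(p)[order(-p, firstpos)]
}

#' Pointer-sum aggregation of attention over candidate mentions
#'
#' `P(a|d,q) = sum_{i in I(a,d)} s_i`: multiple mentions of the same
#' candidate pool their attention mass. The prediction is the argmax,
#' with ties broken towards the candidate occurring earliest in the
#' document.
#'
#' @param positionProbs attention distribution over document positions.
#' @param positions named list of candidate position sets (1-based).
#' @return list with `candidateProbs`, `ranked` and `predicted`.
#' @export
pointerSum <- function(positionProbs, positions) {
  n <- length(positionProbs)
  bad <- vapply(positions, function(p)
    length(p) > 0L && (min(p) < 1L || max(p) > n), logical(1))
  if (any(bad)) stop("position out of range")
  # sequential double-precision accumulation (matches the compiled
  # training path bit-for-bit; base sum() accumulates in long double)
  p <- vapply(positions, function(idx) {
    tot <- 0
    for (i in idx) tot <- tot + positionProbs[i]
    tot
  }, numeric(1))
  ranked <- .rank_candidates(p, positions)
  list(candidateProbs = p, ranked = ranked, predicted = ranked[1])
}

#' Predict the answer for one instance
#'
#' Runs the full forward pass and pointer-sum aggregation. Deterministic
#' given the model weights; out-of-vocabulary tokens use the `"<unk>"`
#' row.
#'
#' @param model a [ReaderModel-class].
#' @param instance a [ClozeInstance-class].
#' @param n size of the top-N list to attach.
#' @return list of class `attentionResult` with `positionProbs`,
#'   `candidateProbs`, `ranked`, `topN`, `predicted`.
#' @export
predictReader <- function(model, instance, n = 1L) {
  ix <- .index_instance(instance, model@vocab, model@typeLevels)
  res <- cpp_asr_instance(ix$doc, ix$dtype, ix$qry, ix$qtype,
                          model@weights$Wword, .model_type_mat(model),
                          model@weights, model@config$hiddenSize,
                          isTRUE(model@config$useTypeEmbedding))
  s <- drop(res$s)
  ps <- pointerSum(s, instance@positions)
  structure(list(positionProbs = s, candidateProbs = ps$candidateProbs,
                 ranked = ps$ranked,
                 topN = utils::head(ps$ranked, max(1L, n)),
                 predicted = ps$predicted),
            class = "attentionResult")
}

#' Save / load a reader checkpoint
#'
#' The checkpoint holds the full model object: configuration,
#' vocabulary, all weight matrices and the seed.
#'
#' @param model a [ReaderModel-class].
#' @param path file path.
#' @export
saveReaderModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveReaderModel
#' @export
loadReaderModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "ReaderModel"))
  model
}
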