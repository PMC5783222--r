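#' @rdname ClozeInstance-class
#' @param x a `ClozeInstance`.
#' @export
documentTokens <- function(x) x@documentTokens

#' @rdname ClozeInstance-class
#' @export
questionTokens <- function(x) x@questionTokens

#' @rdname ClozeInstance-class
#' @export
answerToken <- function(x) x@answer

#' @rdname ClozeInstance-class
#' @export
candidates <- function(x) x@candidates

#' @rdname ClozeInstance-class
#' @export
mentionPositions <- function(x) x@positions

#' @rdname ClozeInstance-class
#' @export
variantOf <- function(x) x@variant

#' @rdname ClozeDataset-class
#' @param x a `ClozeDataset`.
#' @export
instances <- function(x) x@instances

#' @rdname ClozeDataset-class
#' @export
nInstances <- function(x) length(x@instances)

#' @rdname ClozeDataset-class
#' @export
idMode <- function(x) x@idMode

#' @rdname ReaderModel-class
#' @param x a `ReaderModel`.
#' @export
validationAccuracy <- function(x) x@valAccuracy

#' @rdname ReaderModel-class
#' @export
epochLog <- function(x) x@epochLog

#' @rdname ReaderEnsemble-class
#' @param x a `ReaderEnsemble`.
#' @export
members <- function(x) x@members

#' @rdname Lexicon-class
#' @param x a `Lexicon`.
#' @export
entityIds <- function(x) unique(x@entries$entity_id)

#' @rdname Lexicon-class
#' @export
surfaces <- function(x) x@entries$surface

#' @rdname Lexicon-class
#' @export
entityTypes <- function(x) x@entityType

#' @rdname EvalReport-class
#' @param x an `EvalReport`.
#' @export
topNAccuracy <- function(x) x@topN

setMethod("show", "Lexicon", function(object) {
  cat(sprintf("Lexicon: %d surface forms, %d entities, max %d-token match\n",
              nrow(object@entries), length(unique(object@entries$entity_id)),
              object@maxNgram))
})

setMethod("show", "WordVectorTable", function(object) {
  cat(sprintf("WordVectorTable: %d tokens x %d dimensions\n",
              nrow(object@vectors), object@dim))
})

setMethod("show", "ClozeInstance", function(object) {
  cat(sprintf("ClozeInstance [%s] from %s\n", object@variant,
              object@sourceArticleId))
  cat(sprintf("  document: %d tokens, %d candidates; answer %s\n",
              length(object@documentTokens), length(object@candidates),
              object@answer))
  q <- object@questionTokens
  cat("  question: ", paste(utils::head(q, 18), collapse = " "),
      if (length(q) > 18) " ..." else "", "\n", sep = "")
})

setMethod("show", "ClozeDataset", function(object) {
  v <- table(vapply(object@instances, variantOf, character(1)))
  cat(sprintf("ClozeDataset: %d instances (%s), id mode %s\n",
              length(object@instances),
              paste(sprintf("%s: %d", names(v), v), collapse = ", "),
              object@idMode))
})

setMethod("show", "ReaderModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "ReaderModel: hidden %d, word dim %d, type dim %d, vocab %d\n",
    cfg$hiddenSize, cfg$wordDim,
    if (isTRUE(cfg$useTypeEmbedding)) cfg$typeDim else 0L,
    length(object@vocab)))
  if (length(object@valAccuracy) && !is.na(object@valAccuracy))
    cat(sprintf("  best validation accuracy: %.3f (%d epochs trained)\n",
                object@valAccuracy, nrow(object@epochLog)))
})

setMethod("show", "ReaderEnsemble", function(object) {
  acc <- vapply(object@members, validationAccuracy, numeric(1))
  cat(sprintf("ReaderEnsemble: %d members (threshold %.2f, target %d)\n",
              length(object@members), object@threshold, object@targetSize))
  cat("  member validation accuracies:",
      paste(sprintf("%.3f", acc), collapse = ", "), "\n")
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d instances, accuracy %.3f\n",
              object@n, object@accuracy))
  cat("  top-N:", paste(sprintf("%s=%.3f", names(object@topN), object@topN),
                        collapse = ", "), "\n")
})
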