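#' @useDynLib biocloze, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Lexicon of biomedical entity surface forms
#'
#' Maps surface forms (possibly multi-token) to canonical entity
#' identifiers, with one merged type label per entity. Lookup is
#' case-insensitive and longest-match; see [tagText()].
#'
#' @slot entries data.frame with columns `surface`, `surface_key`
#'   (normalized lookup key), `ntok` (tokens in the surface),
#'   `entity_id`, `raw_type`.
#' @slot entityType named character; merged type label per entity id.
#' @slot index environment keyed by `surface_key`, holding the entity id.
#' @slot firstTokenIndex environment keyed by the first token of each
#'   surface, holding the longest surface length starting with it; lets
#'   the tagger skip non-entity tokens with one lookup.
#' @slot maxNgram longest surface length, in tokens, admitted at lookup.
#' @export
setClass("Lexicon", representation(
  entries = "data.frame",
  entityType = "character",
  index = "environment",
  firstTokenIndex = "environment",
  maxNgram = "integer"
))

setValidity("Lexicon", function(object) {
  e <- object@entries
  need <- c("surface", "surface_key", "ntok", "entity_id", "raw_type")
  if (!all(need %in% names(e))) return("entries lacks required columns")
  if (any(!nzchar(e$surface))) return("empty surface form")
  if (anyDuplicated(e$surface_key)) return("duplicate surface key")
  TRUE
})

#' Table of pretrained word vectors
#'
#' @slot dim vector dimensionality.
#' @slot vectors numeric matrix, one row per token (rownames are tokens).
#' @export
setClass("WordVectorTable", representation(
  dim = "integer",
  vectors = "matrix"
))

setValidity("WordVectorTable", function(object) {
  if (ncol(object@vectors) != object@dim)
    return("vector matrix width does not match dim")
  if (is.null(rownames(object@vectors)) || anyDuplicated(rownames(object@vectors)))
    return("tokens must be unique rownames")
  TRUE
})

#' A cloze-style comprehension instance
#'
#' The tuple (d, q, a, A): an anonymized document, a question with a
#' placeholder, the answer entity token, the candidate entity tokens
#' occurring in the document, and the document positions of every
#' candidate (1-based).
#'
#' @slot documentTokens,documentTypes tokens of d and their merged type
#'   labels (entity tokens carry their entity type, all else `Unknown`).
#' @slot questionTokens,questionTypes tokens of q; the blank is the
#'   single token `"@placeholder"`.
#' @slot answer the entity token removed from q.
#' @slot candidates entity tokens occurring in d.
#' @slot positions named list: candidate -> integer vector of 1-based
#'   positions in d.
#' @slot variant `"BMKC_T"` (title question) or `"BMKC_LS"`
#'   (last-sentence question).
#' @slot sourceArticleId id of the article the instance came from.
#' @export
setClass("ClozeInstance", representation(
  documentTokens = "character",
  documentTypes = "character",
  questionTokens = "character",
  questionTypes = "character",
  answer = "character",
  candidates = "character",
  positions = "list",
  variant = "character",
  sourceArticleId = "character"
))

setValidity("ClozeInstance", function(object) {
  d <- object@documentTokens
  if (length(d) == 0L) return("empty document")
  if (length(object@documentTypes) != length(d))
    return("documentTypes length mismatch")
  if (length(object@questionTypes) != length(object@questionTokens))
    return("questionTypes length mismatch")
  if (!object@variant %in% c("BMKC_T", "BMKC_LS"))
    return("variant must be BMKC_T or BMKC_LS")
  if (sum(object@questionTokens == "@placeholder") < 1L)
    return("question lacks a placeholder token")
  if (!object@answer %in% object@candidates)
    return("answer is not among the candidates")
  if (!identical(sort(names(object@positions)), sort(object@candidates)))
    return("positions must be named by exactly the candidates")
  for (cand in object@candidates) {
    pos <- object@positions[[cand]]
    if (length(pos) == 0L) return("empty position set")
    if (any(pos < 1L) || any(pos > length(d))) return("position out of range")
    if (!all(d[pos] == cand)) return("position does not index its candidate token")
  }
  TRUE
})

#' A collection of cloze instances with its entity-ID assignment
#'
#' @slot instances list of [ClozeInstance-class] objects.
#' @slot idMode `"global"` (one corpus-wide entity-ID map), `"local"`
#'   (IDs re-assigned per instance) or `"none"` (canonical IDs retained).
#' @slot idMap for global mode, a named character mapping canonical
#'   entity ids to `"@entityN"` tokens; for local mode, a list of such
#'   maps, one per instance.
#' @slot seed integer seed the assignment was derived from.
#' @slot meta list of bookkeeping (rejection tally etc.).
#' @export
setClass("ClozeDataset", representation(
  instances = "list",
  idMode = "character",
  idMap = "ANY",
  seed = "integer",
  meta = "list"
))

setValidity("ClozeDataset", function(object) {
  if (!object@idMode %in% c("global", "local", "none"))
    return("idMode must be global, local or none")
  ok <- vapply(object@instances, function(x) is(x, "ClozeInstance"), logical(1))
  if (!all(ok)) return("instances must all be ClozeInstance objects")
  TRUE
})

#' A trained (or initialized) attention-sum reader
#'
#' @slot config the [readerConfig()] list used to build the model.
#' @slot vocab token vocabulary; out-of-vocabulary tokens map to the
#'   dedicated `"<unk>"` entry at prediction time.
#' @slot typeLevels merged type vocabulary (see [typeVocabulary()]).
#' @slot weights named list of weight matrices (word/type embeddings and
#'   the four GRU parameter sets).
#' @slot epochLog data.frame with one row per epoch: training loss and
#'   validation accuracy.
#' @slot valAccuracy best validation accuracy observed.
#' @slot seed seed the initialization and batch order derive from.
#' @export
setClass("ReaderModel", representation(
  config = "list",
  vocab = "character",
  typeLevels = "character",
  weights = "list",
  epochLog = "data.frame",
  valAccuracy = "numeric",
  seed = "integer"
))

#' A probability-averaging ensemble of readers
#'
#' @slot members list of [ReaderModel-class] objects, all with identical
#'   vocabularies.
#' @slot threshold validation-accuracy floor applied at selection.
#' @slot targetSize maximum number of members retained.
#' @export
setClass("ReaderEnsemble", representation(
  members = "list",
  threshold = "numeric",
  targetSize = "integer"
))

setValidity("ReaderEnsemble", function(object) {
  if (length(object@members) == 0L) return("empty ensemble")
  v <- lapply(object@members, function(m) m@vocab)
  if (!all(vapply(v, identical, logical(1), y = v[[1]])))
    return("members must share one vocabulary")
  acc <- vapply(object@members, function(m) m@valAccuracy, numeric(1))
  if (any(acc < object@threshold)) return("member below the accuracy threshold")
  TRUE
})

#' Evaluation report with top-N accuracies
#'
#' @slot n number of instances evaluated.
#' @slot accuracy top-1 accuracy.
#' @slot topN named numeric of top-N accuracies.
#' @slot records per-instance data.frame: predicted, gold, goldRank.
#' @export
setClass("EvalReport", representation(
  n = "integer",
  accuracy = "numeric",
  topN = "numeric",
  records = "data.frame"
))

setValidity("EvalReport", function(object) {
  tn <- object@topN
  if (any(tn < 0 | tn > 1)) return("top-N accuracies must lie in [0, 1]")
  if (is.unsorted(tn)) return("top-N accuracy must be non-decreasing in N")
  TRUE
})
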