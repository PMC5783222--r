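# Accuracy / top-N evaluation and attention export.

.predict_any <- function(object, instance) {
  if (is(object, "ReaderEnsemble")) ensemblePredict(object, instance)
  else predictReader(object, instance)
}

#' Evaluate a reader or ensemble on a dataset
#'
#' Exact counting of top-N hits: an instance counts as correct at N when
#' the gold answer appears among the N highest-probability candidates
#' (rank 1 = highest; ties resolved by the reader's first-occurrence
#' rule before ranking, so ranks are deterministic). Invariant under
#' dataset shuffling.
#'
#' @param object a [ReaderModel-class] or [ReaderEnsemble-class].
#' @param dataset a [ClozeDataset-class] or list of instances.
#' @param ns the Ns to report top-N accuracy for.
#' @return an [EvalReport-class].
#' @export
evaluateReader <- function(object, dataset, ns = c(1L, 2L, 3L, 5L)) {
  insts <- .as_instance_list(dataset)
  if (length(insts) == 0L) stop("empty dataset")
  ns <- sort(unique(as.integer(ns)))
  recs <- lapply(insts, function(inst) {
    res <- .predict_any(object, inst)
    rank <- match(inst@answer, res$ranked)
    data.frame(sourceArticleId = inst@sourceArticleId,
               predicted = res$predicted, gold = inst@answer,
               goldRank = rank, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  topN <- vapply(ns, function(N) mean(records$goldRank <= N), numeric(1))
  names(topN) <- paste0("top", ns)
  new("EvalReport", n = length(insts),
      accuracy = mean(records$goldRank == 1L), topN = topN,
      records = records)
}

#' Export an attention heatmap record
#'
#' Writes a machine-readable, line-delimited account of one prediction:
#' one row per document position (index, token, attention weight) and
#' one row per candidate (token, aggregated probability), tab-separated.
#' Weights are printed with 17 significant digits so that re-importing
#' reproduces the in-memory values bit-for-bit.
#'
#' @param model a [ReaderModel-class].
#' @param instance a [ClozeInstance-class].
#' @param path output file path.
#' @return the attention result, invisibly.
#' @export
exportAttention <- function(model, instance, path) {
  res <- predictReader(model, instance, n = length(instance@candidates))
  d <- instance@documentTokens
  lines <- c(
    sprintf("position\t%d\t%s\t%.17g", seq_along(d), d, res$positionProbs),
    sprintf("candidate\t%d\t%s\t%.17g",
            seq_along(res$ranked), res$ranked,
            res$candidateProbs[res$ranked]))
  writeLines(lines, path)
  invisible(res)
}

#' @rdname exportAttention
#' @export
readAttention <- function(path) {
  parts <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
  kind <- vapply(parts, `[`, character(1), 1L)
  tok <- vapply(parts, `[`, character(1), 3L)
  val <- as.numeric(vapply(parts, `[`, character(1), 4L))
  pos <- kind == "position"
  list(positions = data.frame(index = as.integer(
         vapply(parts[pos], `[`, character(1), 2L)),
         token = tok[pos], weight = val[pos], stringsAsFactors = FALSE),
       candidates = data.frame(token = tok[!pos], prob = val[!pos],
                               stringsAsFactors = FALSE))
}
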