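# Probability-averaging ensembles of independently trained readers.

#' Select ensemble members by validation accuracy
#'
#' Keeps the models whose recorded validation accuracy reaches the
#' threshold (0.70 by default), sorted descending, truncated to the
#' target size (8 by default, mirroring the usual eight-member
#' ensemble). An error is raised when no model qualifies.
#'
#' @param models list of trained [ReaderModel-class] objects.
#' @param threshold validation-accuracy floor.
#' @param targetSize maximum number of members.
#' @return a [ReaderEnsemble-class].
#' @export
selectMembers <- function(models, threshold = 0.70, targetSize = 8L) {
  stopifnot(length(models) > 0L)
  acc <- vapply(models, validationAccuracy, numeric(1))
  keep <- which(acc >= threshold)
  if (length(keep) == 0L)
    stop(sprintf("empty ensemble: no model reaches accuracy %.2f",
                 threshold))
  keep <- keep[order(acc[keep], decreasing = TRUE)]
  keep <- utils::head(keep, targetSize)
  new("ReaderEnsemble", members = models[keep], threshold = threshold,
      targetSize = as.integer(targetSize))
}

#' Predict with a probability-averaging ensemble
#'
#' The candidate distribution is the unweighted arithmetic mean of the
#' members' pointer-sum candidate probabilities; ranking and argmax are
#' taken on the mean, with ties broken towards the candidate occurring
#' earliest in the document. Invariant under member order.
#'
#' @param bundle a [ReaderEnsemble-class].
#' @param instance a [ClozeInstance-class].
#' @param n size of the top-N list to attach.
#' @return list of class `attentionResult` (without position
#'   probabilities, which are member-specific).
#' @export
ensemblePredict <- function(bundle, instance, n = 1L) {
  stopifnot(is(bundle, "ReaderEnsemble"))
  preds <- lapply(bundle@members, predictReader, instance = instance)
  cand <- names(preds[[1]]$candidateProbs)
  p <- Reduce(`+`, lapply(preds, function(x) x$candidateProbs[cand])) /
    length(preds)
  ranked <- .rank_candidates(p, instance@positions)
  structure(list(positionProbs = NULL, candidateProbs = p, ranked = ranked,
                 topN = utils::head(ranked, max(1L, n)),
                 predicted = ranked[1]),
            class = "attentionResult")
}
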