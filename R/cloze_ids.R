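# Entity-ID anonymization (global/local), corpus splitting, and dataset
# serialization.

.relabel_instance <- function(inst, map) {
  relab <- function(tok) ifelse(tok %in% names(map), map[tok], tok)
  pos <- inst@positions
  names(pos) <- unname(map[names(pos)])
  new("ClozeInstance",
      documentTokens = unname(relab(inst@documentTokens)),
      documentTypes = inst@documentTypes,
      questionTokens = unname(relab(inst@questionTokens)),
      questionTypes = inst@questionTypes,
      answer = unname(map[inst@answer]),
      candidates = unname(map[inst@candidates]),
      positions = pos, variant = inst@variant,
      sourceArticleId = inst@sourceArticleId)
}

.instance_entities <- function(inst) {
  toks <- c(inst@documentTokens, inst@questionTokens, inst@answer)
  unique(toks[.is_entity_token(toks)])
}

#' Assign anonymized entity-ID tokens
#'
#' Replaces canonical entity-id tokens with `"@entityN"` tokens. In
#' global mode one injective corpus-wide map is used, numbered by first
#' appearance in corpus order (document tokens before question tokens),
#' so the same entity carries the same ID token in every instance —
#' entity IDs are deliberately not permuted per context, letting a model
#' accumulate background knowledge about recurring entities. In local
#' mode numbering restarts at `"@entity1"` within each instance and the
#' numbering order is randomized per instance from `seed`, hiding
#' entity identity across contexts.
#'
#' @param instances list of [ClozeInstance-class] objects carrying
#'   canonical ids (as built by [buildInstance()]).
#' @param mode `"global"` or `"local"`.
#' @param seed integer; drives the per-instance permutation in local
#'   mode.
#' @param meta bookkeeping list stored on the resulting dataset.
#' @return a [ClozeDataset-class].
#' @export
assignIds <- function(instances, mode = c("global", "local"), seed = 1L,
                      meta = list()) {
  mode <- match.arg(mode)
  if (mode == "global") {
    all_ids <- character(0)
    for (inst in instances) {
      ids <- .instance_entities(inst)
      all_ids <- c(all_ids, setdiff(ids, all_ids))
    }
    map <- stats::setNames(sprintf("@entity%d", seq_along(all_ids)), all_ids)
    out <- lapply(instances, .relabel_instance, map = map)
    idMap <- map
  } else {
    out <- vector("list", length(instances))
    idMap <- vector("list", length(instances))
    withSeed(seed, {
      for (i in seq_along(instances)) {
        ids <- .instance_entities(instances[[i]])
        perm <- if (length(ids) > 1L) sample(ids) else ids
        map <- stats::setNames(sprintf("@entity%d", seq_along(perm)), perm)
        out[[i]] <- .relabel_instance(instances[[i]], map)
        idMap[[i]] <- map
      }
    })
  }
  new("ClozeDataset", instances = out, idMode = mode, idMap = idMap,
      seed = as.integer(seed), meta = meta)
}

#' Split a dataset into train / validation / test
#'
#' With `fractions`, instances are shuffled under `seed` and cut into
#' disjoint, exhaustive partitions whose sizes follow the fractions
#' (remainders go to the earlier partitions). With `groups` (one key per
#' instance, e.g. a source file name), whole groups are kept together:
#' shuffled groups fill the partitions in order until each reaches its
#' target share.
#'
#' @param dataset a [ClozeDataset-class].
#' @param fractions named numeric summing to 1.
#' @param groups optional character vector, one key per instance.
#' @param seed integer shuffle seed.
#' @return named list of [ClozeDataset-class] objects.
#' @export
splitCorpus <- function(dataset,
                        fractions = c(train = 0.8, validation = 0.1,
                                      test = 0.1),
                        groups = NULL, seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions > 0))
  insts <- dataset@instances
  n <- length(insts)
  k <- length(fractions)
  sizes <- floor(n * fractions)
  rem <- n - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  if (any(sizes == 0L)) stop("requested an empty partition")

  part <- integer(n)
  if (is.null(groups)) {
    ord <- withSeed(seed, sample.int(n))
    part[ord] <- rep(seq_len(k), times = sizes)
  } else {
    stopifnot(length(groups) == n)
    gs <- withSeed(seed, sample(unique(groups)))
    filled <- numeric(k)
    for (g in gs) {
      idx <- which(groups == g)
      target <- which(filled < sizes)
      j <- if (length(target)) target[1] else k
      part[idx] <- j
      filled[j] <- filled[j] + length(idx)
    }
    if (any(tabulate(part, k) == 0L)) stop("requested an empty partition")
  }
  out <- lapply(seq_len(k), function(j) {
    new("ClozeDataset", instances = insts[part == j],
        idMode = dataset@idMode, idMap = dataset@idMap,
        seed = dataset@seed, meta = dataset@meta)
  })
  names(out) <- names(fractions)
  out
}

.instance_to_list <- function(inst) {
  list(source_article_id = inst@sourceArticleId, variant = inst@variant,
       document = inst@documentTokens, document_types = inst@documentTypes,
       question = inst@questionTokens, question_types = inst@questionTypes,
       answer = inst@answer, candidates = inst@candidates,
       positions = inst@positions)
}

.instance_from_list <- function(rec) {
  pos <- lapply(rec$positions, as.integer)
  new("ClozeInstance",
      documentTokens = as.character(rec$document),
      documentTypes = as.character(rec$document_types),
      questionTokens = as.character(rec$question),
      questionTypes = as.character(rec$question_types),
      answer = as.character(rec$answer),
      candidates = as.character(rec$candidates),
      positions = pos, variant = as.character(rec$variant),
      sourceArticleId = as.character(rec$source_article_id))
}

#' Serialize / deserialize a cloze dataset
#'
#' Line-delimited JSON: a meta record first (id mode, seed), then one
#' record per instance with document/question tokens and types, answer,
#' candidates and 1-based position sets. `readClozeDataset` inverts
#' `writeClozeDataset` exactly.
#'
#' @param dataset a [ClozeDataset-class].
#' @param path file path.
#' @return `readClozeDataset` returns the dataset; `writeClozeDataset`
#'   returns `path` invisibly.
#' @export
writeClozeDataset <- function(dataset, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  meta <- list(format = "biocloze-dataset", idMode = dataset@idMode,
               seed = dataset@seed)
  writeLines(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE)), con)
  for (inst in dataset@instances) {
    writeLines(as.character(jsonlite::toJSON(.instance_to_list(inst),
                                             auto_unbox = TRUE, digits = NA)),
               con)
  }
  invisible(path)
}

#' @rdname writeClozeDataset
#' @export
readClozeDataset <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty dataset file")
  meta <- jsonlite::fromJSON(lines[1])
  if (!identical(meta$format, "biocloze-dataset"))
    stop("not a biocloze dataset file")
  insts <- lapply(lines[-1], function(l)
    .instance_from_list(jsonlite::fromJSON(l, simplifyVector = TRUE)))
  new("ClozeDataset", instances = insts, idMode = meta$idMode,
      idMap = list(), seed = as.integer(meta$seed), meta = list())
}

#' Export an instance in the CNN/Daily-Mail question-file layout
#'
#' Writes `<id>_<variant>.question`: source id, blank line, the
#' space-joined document, blank, the question (placeholder rendered as
#' `@placeholder`), blank, the answer, blank, then one `token:token`
#' line per candidate.
#'
#' @param instance a [ClozeInstance-class].
#' @param dir output directory.
#' @return the file path, invisibly.
#' @export
exportQuestionFile <- function(instance, dir) {
  path <- file.path(dir, sprintf("%s_%s.question",
                                 instance@sourceArticleId,
                                 instance@variant))
  lines <- c(instance@sourceArticleId, "",
             paste(instance@documentTokens, collapse = " "), "",
             paste(instance@questionTokens, collapse = " "), "",
             instance@answer, "",
             sprintf("%s:%s", instance@candidates, instance@candidates))
  writeLines(lines, path)
  invisible(path)
}
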