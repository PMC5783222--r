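# Shared fixtures, all built in code.

# a small hand-written lexicon exercising synonyms, multi-token surfaces
# and both type inventories
fixtureLexiconEntries <- function() {
  data.frame(
    surface = c("breast cancer", "breast tumors", "NCOA1", "SRC-1",
                "AP-1", "CSF1", "taxol", "oxidative stress",
                "mammary gland", "mice"),
    entity_id = c("E_BC", "E_BC", "E_NCOA1", "E_NCOA1", "E_AP1", "E_CSF1",
                  "E_TAX", "E_OS", "E_MG", "E_MICE"),
    raw_type = c("Diseases [C]", "Diseases [C]", "Gene", "Gene",
                 "Transcription Factor", "Gene", "Drug",
                 "Phenomena and Processes [G]", "Anatomy [A]",
                 "Organisms [B]"),
    stringsAsFactors = FALSE)
}

fixtureLexicon <- function() buildLexicon(fixtureLexiconEntries())

# construct a ClozeInstance directly (entity tokens already assigned)
makeInstance <- function(d, q, answer, variant = "BMKC_T",
                         id = "A1", dTypes = NULL, qTypes = NULL) {
  ents <- unique(d[grepl("^@entity", d)])
  pos <- lapply(ents, function(e) which(d == e))
  names(pos) <- ents
  new("ClozeInstance",
      documentTokens = d,
      documentTypes = if (is.null(dTypes)) rep("Unknown", length(d)) else dTypes,
      questionTokens = q,
      questionTypes = if (is.null(qTypes)) rep("Unknown", length(q)) else qTypes,
      answer = answer, candidates = ents, positions = pos,
      variant = variant, sourceArticleId = id)
}

# a tiny untrained reader over a given token set
makeToyReader <- function(tokens, hiddenSize = 4L, wordDim = 5L,
                          typeDim = 3L, useType = TRUE, seed = 1L,
                          wordVectors = NULL) {
  cfg <- readerConfig(hiddenSize = hiddenSize, wordDim = wordDim,
                      typeDim = typeDim, useTypeEmbedding = useType,
                      seed = seed)
  initReader(sort(unique(tokens)), cfg, wordVectors = wordVectors)
}

# word2vec text fixture written to a temp file
writeWordVecFixture <- function(path, entries) {
  dim <- length(entries[[1]])
  lines <- c(sprintf("%d %d", length(entries), dim),
             vapply(names(entries), function(tok)
               paste(c(tok, format(entries[[tok]], trim = TRUE)),
                     collapse = " "), character(1)))
  writeLines(lines, path)
  path
}

# small cached synthetic corpora so expensive generation happens once
.fixture_env <- new.env(parent = emptyenv())

tinyCorpus <- function(variant = "BMKC_T", seed = 7) {
  key <- paste0("tiny_", variant, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    cfg <- synthPreset("tiny", seed = seed)
    .fixture_env[[key]] <- generateClozeCorpus(cfg, variant = variant)
  }
  .fixture_env[[key]]
}

# Rscript invocation of the installed CLI
runCli <- function(args) {
  rscript <- file.path(R.home("bin"), "Rscript")
  cli <- system.file("cli", "biocloze.R", package = "biocloze")
  out <- system2(rscript, c(cli, args), stdout = TRUE, stderr = TRUE,
                 env = paste0("R_LIBS=", paste(.libPaths(), collapse = ":")))
  status <- attr(out, "status")
  list(output = out, status = if (is.null(status)) 0L else status)
}
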