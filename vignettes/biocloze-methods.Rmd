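---
title: "Cloze-style biomedical machine comprehension: datasets and the attention-sum reader"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cloze-style biomedical machine comprehension: datasets and the attention-sum reader}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biocloze)
```

## The task

A cloze-style comprehension instance is a tuple `(d, q, a, A)`: a document
`d` (here, the abstract of a biomedical article), a question `q` with one
token blanked out, the answer `a` (a biomedical entity), and a candidate set
`A` — the entities occurring in `d`. The model must point to the candidate
that fills the blank. `biocloze` builds two dataset variants from article
records:

* **title variant** (`BMKC_T`): the question is the article title, the
  document is the full abstract;
* **last-sentence variant** (`BMKC_LS`): the question is the abstract's
  final sentence, which is then removed from the document so the answer
  cannot be read off verbatim.

One instance is built per article per variant. Two inclusion filters are
applied: the answer entity must occur in both the document and the
question, and the number of candidate entities must exceed 20 (at least
21). The candidate floor keeps chance performance low and instances
non-trivial; both rules are enforced by `passesFilters()` and re-checked
independently by `validateInstances()`.

## Entity handling

Candidates come from a dictionary lexicon mapping surface forms to
canonical entity identifiers (MeSH-style grouping: several synonymous
surfaces resolve to one identifier). Tagging (`tagText()`) is greedy
left-to-right longest match over token n-grams, case-insensitive and
anchored at token boundaries; ties go to the leftmost longest match. This
is deliberately a dictionary tagger, not a learned NER system: the package
consumes a lexicon, it does not produce one.

Each entity carries one merged type label. Raw labels from the curated
inventory (Gene, Drug, Target, ...) and the MeSH top-level categories are
collapsed by `mergeType()`: gene-like labels (Gene, Target, Transcription
Factor) onto **Gene**; drug/chemical labels (Drug, Toxin, Chemical
Compounds) onto **Chemicals and Drugs [D]**; Disease onto **Diseases
[C]**; every other label maps to itself, and untyped tokens are
**Unknown**. Only the first two merges are forced by the sources the
labels come from; the disease merge is the one exactly parallel case, and
we deliberately stop there rather than invent further semantics. When the
two inventories disagree on one entity, the curated label wins because it
is the more specific source.

Mentions are anonymized: every mention collapses to a single `@entityN`
token. In **global** mode the map is corpus-wide and numbered by first
appearance, so an entity keeps one identity across all documents — the
setting that lets a model accumulate background knowledge about recurring
entities; IDs are deliberately not permuted per context. In **local** mode
numbering restarts at `@entity1` in every instance with a seeded random
order, hiding entity identity. Mention position indices are 1-based
throughout, following R convention.

## The reader

The reader is the attention-sum architecture. Tokens are embedded by a
lookup matrix (optionally concatenated with a 20-dimensional learned type
vector per merged type label); a bidirectional GRU encodes the document
into per-position vectors `f_i(d)` (forward and backward states
concatenated) and a second bidirectional GRU encodes the question into a
single vector `g(q)` (final forward state concatenated with final backward
state). Attention is the softmax of dot products,

$$ s_i = \frac{\exp\langle f_i(d),\, g(q)\rangle}{\sum_j \exp\langle
f_j(d),\, g(q)\rangle}, $$

computed with max-subtraction for overflow safety and taken over **all**
document positions, exactly as the displayed equations of the architecture
prescribe; candidates are then scored only through their own positions by
pointer-sum aggregation,

$$ P(a \mid d, q) = \sum_{i \in I(a,d)} s_i, $$

where `I(a,d)` is the set of positions of candidate `a`. The predicted
answer is the argmax, ties broken towards the candidate occurring earliest
in the document so that rankings (and top-N accuracy) are deterministic.

The architecture never states a training loss explicitly; we use the
canonical objective for this model family, the negative log of the
aggregated probability of the correct candidate, `-log P(a|d,q)`, averaged
per minibatch. The forward and backward passes are implemented exactly (no
autodiff framework); a finite-difference check against the analytic
gradient is part of the test suite and must agree within `1e-4` relative
error.

### Training choices

* **Optimizer**: Adam, learning rate 0.001 by default (0.0005 is the other
  standard choice and is exposed in `readerConfig()`), batch size 32.
* **Initialization**: embedding rows uniform on the open interval
  (-0.25, 0.25); rows found (case-insensitively) in a pretrained word2vec
  table are copied instead and remain trainable. GRU weights use
  Glorot-uniform limits, biases zero. The embedding interval is a property
  of the model family; the GRU limits are our choice, since the sources
  are silent on recurrent initialization.
* **Early stopping**: up to 20 epochs, stop after 3 epochs without
  validation improvement, return the snapshot with the best validation
  accuracy. The sources imply validation-based selection without giving a
  schedule; 20/3 is our choice.
* **Gradient clipping** at global norm 10 stabilizes recurrent training
  (our choice; the sources are silent).
* **Out-of-vocabulary** tokens at prediction time use a dedicated `<unk>`
  row; non-entity tokens use the `Unknown` type row.
* **Hidden size** defaults to 128 per direction and is configurable; the
  desk-scale experiments below use 32.

Ensembles (`selectMembers()`, `ensemblePredict()`) average the members'
candidate distributions with equal weights — averaging happens after
pointer-sum, on model outputs, not on position attentions. Members are
admitted when their recorded validation accuracy reaches 0.70, sorted
descending and truncated to eight, the conventional member count for this
model family.

## The synthetic generator

Real corpus construction needs millions of article records; the package
instead ships a generator (`synthConfig()`, `generateClozeCorpus()`) whose
defaults reproduce the *shape* of the real datasets: a mean of about 25.6
distinct candidate entities per document (minimum 21, so the candidate
filter passes by construction), and a mean abstract length of about 291
raw tokens. Filler tokens are Zipf-distributed to mimic natural frequency
skew; sentence periods fall every 8–15 tokens so sentence splitting is
exercised; each entity receives 1–3 surface forms so entity resolution is
exercised; occurrence counts per entity are drawn independently of answer
status so that token frequency alone carries no signal.

The planted **cue** makes the task learnable by construction: with
`cueStrength = 1` every occurrence of the answer entity in the abstract is
immediately preceded by a fixed cue token, so the rule "the entity after
the cue" scores 100% — an oracle ceiling that a working reader should
approach. With `cueStrength = 0` no document feature identifies the
answer (it is drawn uniformly among the document's entities), so held-out
accuracy of any model must stay at chance, about `1/|A|`. The paired
positive/negative conditions are what the acceptance checks train on.

Note what the generator does **not** emulate: real biomedical language
(syntax, discourse, entity co-occurrence statistics), ambiguous or nested
mentions, abbreviation-driven synonymy, or any semantic relation between
question and document beyond the planted cue. Passing tests on synthetic
corpora therefore demonstrate that the pipeline and the learner are
correct and trainable, not that any particular accuracy transfers to real
literature.

### Problem sizes used in the checks

The shipped checks run at desk scale, chosen so the whole suite completes
comfortably on one CPU: the pipeline validator uses 500 articles at the
full corpus shape (~291 tokens per abstract, both variants); reader
learnability uses the `cue-train` preset — 2,000 articles at ~80 tokens
per abstract, split 80/10/10, hidden size 32, word dimension 32, type
dimension 8 — which a correct implementation solves to near-perfect
held-out accuracy within a handful of epochs; the chance-level control
uses 500 uninformative articles. The last-sentence variant is used for
both learnability arms because the generator plants an extra answer
occurrence in the final sentence (needed so both variants share an
answer); under the title variant that occurrence would make the answer
the most frequent entity and give a frequency shortcut, whereas removing
the question sentence from the context leaves occurrence counts unbiased.

## Numerical and degenerate-input conventions

* Softmax uses max-subtraction; aggregated probabilities are clamped away
  from zero (`1e-300`) inside the log only.
* A one-position document yields `s = [1]`; empty documents or questions
  are errors.
* Sentence splitting never splits after a period that follows a closed
  abbreviation list (`al`, `Fig`, `i.e`, `e.g`, single capitals, ...); a
  boundary-free abstract is one sentence, which the last-sentence variant
  rejects as "empty context".
* The tokenizer detaches brackets/punctuation, splits slash-joined terms,
  keeps hyphenated terms and internal periods (decimals, `i.e`), and is
  idempotent on its own output — the property that makes serialized
  datasets re-tokenizable.
* When several entities occur in both document and question, the blank is
  the one occurring earliest in the question (deterministic); a seeded
  random rule is available (`answerRule = "random"`). The sources do not
  fix this choice.
* Candidate counts are counted as unique entity identifiers in the
  document; question-only entities are not added to the candidate set,
  since pointer-sum can only score tokens present in the document.
* If the answer occurs several times in the question, every occurrence is
  masked, preventing answer leakage.

## Known limitations

* The dictionary tagger has no notion of context-dependent entity senses.
* Training is single-threaded CPU; the implementation is sized for
  method-validation corpora, not for millions of articles.
* Only the text dialect of the word2vec format is read.
* The MEDLINE XML reader covers the PubmedArticle subset needed here
  (PMID, title, abstract sections, year), not the full DTD. Structured
  abstracts are concatenated in document order; records are not filtered
  by language, and year extraction (DateCompleted, then PubDate) is
  descriptive only — the pipeline never branches on it.
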