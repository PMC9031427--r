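---
title: "Metabolite NER: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolite NER: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboText)
```

metaboText finds metabolite names as exact character spans in
full-text metabolomics articles. This vignette is the package's own
account of the two annotation approaches it implements, the evaluation
measures, the synthetic data the tests run on, and the design choices
made where more than one reasonable option existed.

## The corpus model

Articles arrive as Auto-CORPus-style BioC JSON: a maintext file of
paragraph records carrying IAO section labels, plus optional table and
abbreviation files. Only the textual abstract (A), methods (M),
results (R) and discussion (D) sections are used; introductions are
dropped because they describe background rather than the study's own
measurements. A combined results-and-discussion section is coded `R`
for sentence identifiers (the identifier alphabet has only four
letters) but keeps the group `RD` for per-section evaluation.

Each sentence gets an identifier of one letter and five digits. The
five digits split as **2 digits of 0-based subsection index + 3 digits
of 0-based sentence index**: `M01001` is the second sentence of the
second methods subsection. The split is a package decision — the
identifier format fixes only "a letter and five digits" and 0-based
indexing — and is configurable in the sense that the generator and
reader agree through `articleSentences()`; more than 100 subsections
or 1000 sentences per subsection is a capacity error rather than a
silent wrap-around.

**Offsets.** All spans are 0-based, end-exclusive character offsets,
and every annotation record's `entity` field must equal the sentence
substring at its offsets (this is enforced at construction). The
annotation TSV documents the convention in a `#` header.

**Sentence splitting** is a pluggable contract (text in, start/end
span matrix out). The default is rule-based: boundaries at `.?!` runs
followed by whitespace, suppressed after common Latin abbreviations
(e.g., i.e., et al., Fig.) and single letters, so decimal numbers and
initialled names do not split. Any splitter satisfying the contract
can replace it; the fixture corpus defines gold boundaries, so tests
are splitter-honest.

## The rule-based annotation pipeline

1. **Dictionary matching.** The dictionary holds metabolite names and
   synonyms with HMDB-style statuses; by default only `quantified` and
   `detected` entries are loaded, because `expected`/`predicted`
   entries multiply the dictionary several-fold while mostly naming
   lipids that the regular expressions already capture. Cleaning
   removes entries of at most 5 characters (ambiguous abbreviations
   such as `PC`) unless whitelisted, plus a user-replaceable blocklist
   of common-word synonyms (`result`, `retinal`, ...). Matching is
   case-insensitive at word boundaries; letters, digits and hyphens
   count as word characters, so `glucose` is not found inside
   `glucoses` or `d-glucose` but is found before a comma or inside
   brackets. Nested candidates resolve longest-match-first.
2. **Regex partial matching.** A pattern set (plain-text file, one
   PCRE per line) provides partial matches that are expanded to the
   whole whitespace-delimited word(s) they touch, then stripped of
   trailing sentence punctuation. The shipped default set targets
   metabolite morphology — suffixes `-ate/-ose/-ine/-ol/-itol`,
   `-ic acid` forms, substituent prefixes (`hydroxy-`, `methyl-`,
   `acetyl-`, `phospho-`, ...), acyl linkages, and lipid shorthand
   like `PC(16:0/18:1)`. It is intentionally user-replaceable:
   `patternCoverage()` measures which dictionary "reference set"
   entries (those containing spaces, hyphens or colons — the
   less-trivial names) are matched, and lists the uncovered terms so
   a user can craft expressions recursively until coverage stops
   improving. Every pattern runs under a time budget and under PCRE's
   own match limit; a runaway pattern is skipped with a warning.
3. **Post-processing fix-ups**, applied recursively until the span
   set stops changing (with a hard iteration cap of 20 as a
   non-termination guard):
   * *Adjacent words*: the preceding word is prepended when it ends
     with a hyphen or a digit, when the entity starts with a comma
     followed by a digit, or when the entity's first word starts with
     a hyphen — never when the neighbour is a stopword. The following
     word is appended under the mirrored rules plus one extra: it is
     one of `acid`, `isomer`, `ester`, `ether`. The mirrored reading
     ("the entity becomes the preceding word") is an interpretation
     the package fixes explicitly, since the append case is otherwise
     ambiguous about which side the "ends with a number" test applies
     to.
   * *Bracket balancing*: for `()`, `[]`, `{}`, a missing closing
     bracket is appended and a missing opening bracket prepended. The
     span is extended **only** when the added bracket is the adjacent
     character in the sentence; otherwise the fix would make the
     entity differ from its substring, so the span is left unchanged
     (the standalone `balanceBrackets()` still returns the repaired
     text for callers that want it).
   * *Merging*: entities that overlap, touch, or are separated only
     by whitespace merge transitively; the output never contains two
     spans with a whitespace-only gap.

   The order within one iteration is extend → balance → merge; the
   fixpoint requirement makes most orderings equivalent, and this one
   is the documented default.

One consequence the package inherits deliberately: coordinated
mentions such as `1- and 3-methylhistidine` yield only the complete
surface form `3-methylhistidine`. Recovering the elided
`1-methylhistidine` needs semantic analysis, which is out of scope;
the behaviour is pinned by a test.

## The sequence labellers

Tokens are labelled with the BIOES scheme. Two tokenizer backends are
registered: `chem_word` (whitespace split, then punctuation peeled off
token edges while hyphens, digits, colons and balanced brackets stay
inside chemistry-like tokens) and `subword` (a synthetic stand-in that
further splits at hyphen/digit/bracket boundaries, approximating the
smaller-than-word sequences of a transformer tokenizer; a real subword
backend can be registered in its place). Labels are assigned directly
on whatever tokens the backend produces; spans are recovered in
character space by the decoder, so no label pooling is needed.

**Name-internal features.** A pre-classifier is trained from the
dictionary alone: every entry is tokenised and its tokens labelled by
position (S for singletons, otherwise B/I/E), and a negative lexicon
of common words supplies O examples. The classifier sees hashed
character n-grams (orders 1–3 with boundary markers, 128 hash
buckets) plus shape features (length, digit/hyphen/bracket/colon
presence, case pattern) — featurisation the package chose, since only
the classifier's role (per-token B/I/E/S probabilities from token
strings) is fixed. The default learner is a probability random forest
(`ranger`), fitted single-threaded under a seed for determinism. The
O class is included so the probability rows can contrast name-like
against ordinary tokens; rows always sum to 1.

**Architecture.** Per token, the 5-dimensional name-internal rows
pass through a width-3 convolution with 256 ReLU filters; the output
is concatenated with the token embedding — 300-d context-free vectors
from a plain-text vector file (556 total), or a 768-d contextual
embedder behind the embedder contract (1024 total; the concatenation
arithmetic is 256 + 768, and the package uses exactly that). A
`SpatialDropout`-style channel dropout of 0.25 is applied to
contextual embeddings during training. The concatenation feeds a
bidirectional LSTM and a per-token dense softmax over the five BIOES
classes. Embedders are frozen: fine-tuning a contextual backend is a
possible extension, not something the training loop attempts.

**Training.** Cross-entropy with Adam (learning rate 1e-3), gradients
accumulated over `batch_size` sentences (default 32) and applied in
one step — sentences keep their natural lengths, so there is no
padding or bucketing. No class weighting is applied to the dominant O
class. Per epoch (default 50), span-level F1 on the validation corpus
is computed through the same metrics module used for evaluation, and
the weights of the best-validation-F1 epoch are returned along with
the full training log. All stochastic steps (weight init, shuffling,
dropout masks) draw from seeds derived from `config$seed`, and the
C++ backend is single-threaded, so identical runs produce identical
logs. Non-finite loss aborts with the epoch in the message.

**Decoding.** Argmax over the per-token rows, then repair of illegal
label sequences. The conservative default drops orphan I/E labels and
unclosed B blocks (an independent regular-expression oracle over the
label string pins this behaviour in tests); a `promote` policy is
available that upgrades orphans instead. An optional
validation-tuned probability threshold was considered and rejected:
argmax plus repair is deterministic and the validation corpus is
already used for epoch selection. Sentences longer than the backend
limit (default 512 tokens) are processed in overlapping windows with
averaged probabilities.

**Post-processing.** Model spans pass through the same fix-up
machinery as the rule pipeline (extension, bracket balancing,
merging), so both annotators emit records with identical invariants.

## Document-level application

Table cells are annotated as standalone sentences under synthetic
identifiers `T<table><row><col>` — outside the letter+5-digit space,
never written to the corpus sentence file, and carried with source
`table` so they are evaluated separately. Abbreviation linking checks
whether an annotator recognises the ENTIRE definition as one entity
with the fix-up rules disabled (a partial hit must not be "repaired"
into a full one); if so, every case-sensitive whole-word occurrence of
the short form across A/M/R/D sentences becomes a record with source
`abbreviation`. Sources partition the record set, which the
evaluation's source filter relies on.

## Evaluation

Matching is exact on (article, sentence, start, end) keys; an overlap
mode exists but is never used for headline scores because partial
credit is undefined for exact-span corpora. From TP/FP/FN counts:
precision p = TP/(TP+FP), recall r = TP/(TP+FN), F1 = 2pr/(p+r) and
F\* = pr/(p+r−pr). F\* ≤ F1 always, with equality only at p = r = 1;
a property test sweeps random rates. Zero denominators set the
affected measures to 0 and flag the result degenerate rather than
producing NaN. Reports round to 4 decimal places. Per-section
evaluation partitions records by the A/M/R/RD/D group of their
sentence; the per-group TP/FP/FN always sum to the global counts
(tested). Corpus statistics count each metabolite once per article
(case-folded surface identity — no synonym resolution, deliberately:
surface names are what co-occurrence and frequency tables report) and
give means to one decimal.

## Co-occurrence networks

Node weight = number of articles mentioning the metabolite; edge
weight = number of articles mentioning both endpoints — each article
contributes at most once per node and per pair, a reading the package
fixes explicitly (the alternative, counting within-article co-mention
multiplicities, would conflate article frequency with verbosity).
Each node also records the PMCID of the article mentioning it most
(ties to the lexicographically lower PMCID), intended as a colour
attribute. By default only abstract, results (including tables) and
discussion sections feed the graph. Layout is out of scope; the
adjacency-list TSV and GEXF exports carry all weights so any graph
tool can render them.

## Synthetic fixtures: what they emulate, what they do not

The generator composes metabolite-like names from stems and chemistry
suffixes, multiword acid forms, numbered/prefixed forms and lipid
shorthand; plants them into a fixed set of sentence templates inside
A/M/R/D article skeletons; and records gold spans at plant time.
Typos are single-character deletions or substitutions (never the
first character, never colliding with a dictionary name), flagged so
tests can separate exact-match recall from generalisation. Everything
is a pure function of the seed.

The templates are chosen so that no fix-up rule fires on a planted
mention and no template word matches the default pattern set. That
makes the planted-recall property (recall 1.0 at typo rate 0) a test
of the matching and fix-up machinery, not of lexical luck. The
corollary is worth stating: passing on fixtures shows the algorithms
implement their specifications; it does not show real-corpus
performance, where sentence structure, nested chemistry tokens,
encoding artefacts and dictionary noise are all harder. The word
vectors are random Gaussian (they identify tokens without encoding
distributional similarity), and the synthetic contextual embedder is
a hashed projection mixed with neighbour means — it exercises the
768-d code path and its dropout, not transformer semantics.

## Problem sizes and numerical choices

The scaled-down learning check trains the context-free model on 200
fixture sentences from a 30-name dictionary for the full 50 epochs at
seed 7, with 32 LSTM units per direction (the full-scale default is
300) and batch size 8 — sizes the package chose so that the whole
suite, including this run, completes in a few minutes on one core
while the training curve still saturates. Under those conditions the
best validation F1 must reach at least 0.80 (it reaches 1.0 well
before epoch 50 in practice), and on 100 single-character corruptions
of dictionary names the model must recover at least half at exact
span — against a dictionary-only baseline that recovers none, since
exact matching cannot survive a typo. The thresholds are the
package's own, chosen to demonstrate the qualitative claim that the
learner generalises to unseen, misspelled names through token
structure and context.

Other numerical choices: Glorot-uniform weight init with forget-gate
bias 1; Adam β₁ = 0.9, β₂ = 0.999, ε = 1e-8; probabilities clamped at
1e-12 inside the loss; softmax computed with per-column max
subtraction; the fix-up recursion cap at 20 iterations (reached only
by adversarial inputs — every natural sentence converges in a
handful); regex guard timeout 1 s per pattern.

## Known limitations

* Coordination (`1- and 3-methylhistidine`) yields one entity, by
  design; elided forms need semantic parsing.
* Dictionary cleaning is list-based; genuinely ambiguous synonyms not
  on the blocklist will still match (precision cost on real corpora).
* The default pattern set is a starter, not a tuned artefact; real
  deployments should re-derive it against their dictionary's
  reference set via `patternCoverage()`.
* The contextual embedder shipped is synthetic; results with it say
  nothing about transformer-quality embeddings beyond interface
  correctness.
* Abbreviation linking depends entirely on the upstream abbreviation
  file; undetected or Greek-letter abbreviations are not recovered.
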