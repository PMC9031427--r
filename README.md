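# metaboText

Metabolite named-entity recognition (NER) and literature mining for
full-text metabolomics articles.

Metabolomics publications report which small molecules change in which
conditions, but reviewing them at scale means finding every metabolite
mention — `glucose`, `3-methylhistidine`, `PC(16:0/18:1)`, misspelled
`slanine`-style variants — as exact character spans in thousands of
full texts. metaboText implements both families of approaches used for
this task and the evaluation and summarisation machinery around them:

* **Rule-based annotation pipeline** — case-insensitive dictionary
  search over a cleaned metabolite name/synonym dictionary (HMDB-shaped
  input, any source), regular-expression partial matching expanded to
  whole words, and recursive post-processing fix-ups (adjacent-word
  extension, bracket balancing, merging of overlapping or
  whitespace-separated entities) run to a fixpoint.
* **BiLSTM sequence labellers** — tokens are tagged with the BIOES
  scheme (Begin/Inside/Outside/End/Singleton). Each token is
  represented by *name-internal features* (per-token B/I/E/S/O
  probabilities from a dictionary-trained random-forest pre-classifier)
  passed through a width-3 convolution with 256 filters, concatenated
  with a token embedding — 300-d context-free word vectors
  (556 total per token) or a 768-d contextual embedder behind a
  pluggable contract (1024 total) with channel dropout 0.25 — then a
  bidirectional LSTM and a per-token 5-class softmax. Training runs 50
  epochs and keeps the weights of the epoch with the best span-level
  validation F1. The network, backpropagation-through-time and Adam
  are implemented in the package's C++ (RcppArmadillo) backend.
* **Evaluation** — exact-span matching with precision, recall,
  F1 = 2pr/(p+r) and F\* = pr/(p+r−pr), per-section (abstract /
  methods / results / results-and-discussion / discussion) breakdowns,
  and corpus summary statistics.
* **Document-level application** — Auto-CORPus-style BioC JSON input
  (maintext + tables + abbreviations), IAO-term section filtering
  (introductions are excluded), structured sentence identifiers
  (letter + 5 digits), table cells annotated as standalone sentences,
  and abbreviation linking (a short form is linked only when its whole
  definition is recognised as one entity).
* **Co-occurrence networks** — article-weighted metabolite nodes and
  co-mention edges, minimum-article filtering, adjacency-list and GEXF
  export.
* **Synthetic fixtures** — a deterministic generator of toy
  dictionaries, articles with planted gold spans, typos, abbreviations
  and tables, and word-vector files, so the entire stack runs and is
  tested without any external download.

## Worked example

```r
library(metaboText)

fx     <- makeDictionary(30, seed = 7)              # toy dictionary
dict   <- cleanDictionary(newDictionary(fx$names))
corpus <- makeCorpus(12, dictEntries(dict), typo_rate = 0,
                     abbrev_rate = 0.4, seed = 7)

art  <- corpus$articles[[1]]
art
#> Article PMC700001 with sections: A, M, R, D
#>   tables: 1  abbreviations: 0

recs <- annotateDocument(art, ruleAnnotator(dict))
head(recs[, c("sentence_id", "start", "end", "entity", "source")], 4)
#>   sentence_id start end       entity source
#> 1      A00002    18  28   succinitol   text
#> 2      A01000     5  12      glucine   text
#> 3      A01000    17  24      stearol   text
#> 4      A01001    19  31 pyruvic acid   text

gold <- corpus$gold[corpus$gold$source == "text", ]
pred <- annotateCorpus(corpus$sentences, dict)
m    <- nerScore(matchAnnotations(pred, gold)$tp,
                 matchAnnotations(pred, gold)$fp,
                 matchAnnotations(pred, gold)$fn)
sprintf("P=%.4f R=%.4f F1=%.4f F*=%.4f",
        m$precision, m$recall, m$f1, m$fstar)
#> [1] "P=1.0000 R=1.0000 F1=1.0000 F*=1.0000"

g <- buildCooccurrenceGraph(entitiesByArticle(pred, corpus$sentences))
g
#> CooccurrenceGraph: 30 node(s), 350 edge(s), from 12 article(s)
topMetabolites(entitiesByArticle(pred, corpus$sentences), n = 3)
#>             name n_articles percent
#> 1      histidate          7      58
#> 2       oleandol          7      58
#> 3 putrescic acid          6      50
```

The offsets are 0-based and end-exclusive; every record's `entity`
equals the corresponding sentence substring. With `typo_rate = 0` the
rule pipeline recovers every planted mention exactly, which is the
baseline the trained sequence labeller is compared against on
corrupted names (see the methods vignette,
`vignettes/metabolite-ner.Rmd`).

A command-line front-end with `annotate`, `evaluate`, `network`,
`stats`, `fixtures` and `train` subcommands is installed at
`inst/cli/metabotext` (a thin wrapper over `metaboTextCli()`).

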