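# Shared fixtures, generated once per test run. Everything derives from
# fixed seeds so the suite is reproducible.

fixtureBundle <- local({
  fx <- makeDictionary(30, seed = 7)
  dict <- cleanDictionary(newDictionary(fx$names))
  corpus <- makeCorpus(12, dictEntries(dict), typo_rate = 0,
                       abbrev_rate = 0.4, table_rate = 0.5, seed = 7)
  list(fx = fx, dict = dict, corpus = corpus)
})

goldOf <- function(corpus, sources = "text") {
  corpus$gold[corpus$gold$source %in% sources, , drop = FALSE]
}

sentenceTextOf <- function(corpus, pmcid, sid) {
  s <- corpus$sentences
  s$text[s$pmcid == pmcid & s$sentence_id == sid][1]
}
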