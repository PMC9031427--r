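test_that("dictionary matching is longest-match, word-bounded, case-insensitive", {
  d <- newDictionary(c("acetate", "ammonium acetate"))
  sp <- dictionaryMatch("ammonium acetate buffer", d)
  expect_equal(nrow(sp), 1)
  expect_equal(c(sp$start, sp$end), c(0L, 16L))
  d2 <- newDictionary("glucose")
  expect_equal(dictionaryMatch("glucose", d2)[, c("start", "end")],
               data.frame(start = 0L, end = 7L))
  # substring exists but the word boundary fails
  expect_equal(nrow(dictionaryMatch("glucoses", d2)), 0)
  expect_equal(nrow(dictionaryMatch("d-glucose", d2)), 0)
  # punctuation and brackets are boundaries; case is folded
  expect_equal(nrow(dictionaryMatch("(Glucose),", d2)), 1)
})

test_that("dictionary matching equals the all-substring scan oracle", {
  dict <- fixtureBundle$dict
  corpus <- fixtureBundle$corpus
  texts <- corpus$sentences$text[1:60]
  for (tx in texts) {
    got <- dictionaryMatch(tx, dict)
    want <- oracleDictScan(tx, dictEntries(dict))
    expect_equal(nrow(got), nrow(want))
    if (nrow(want))
      expect_equal(cbind(got$start, got$end), unname(want),
                   ignore_attr = TRUE)
  }
})

test_that("regex partial matches expand to whole words", {
  ps <- newPatternSet("4-hydroxy-")
  tx <- "Here 4-hydroxy-N-desmethyltamoxifen was found."
  sp <- regexMatchExpand(tx, ps)
  expect_equal(nrow(sp), 1)
  expect_equal(substr(tx, sp$start + 1, sp$end),
               "4-hydroxy-N-desmethyltamoxifen")
  expect_equal(nrow(regexMatchExpand(tx, newPatternSet("zzz"))), 0)
  # trailing punctuation is never absorbed
  sp2 <- regexMatchExpand("We saw methylmalonate.", newPatternSet("ate\\b"))
  expect_equal(substr("We saw methylmalonate.", sp2$start + 1, sp2$end),
               "methylmalonate")
})

test_that("catastrophic patterns are skipped with a warning", {
  tx <- paste0(strrep("a", 60), "b")
  expect_warning(
    sp <- regexMatchExpand(tx, newPatternSet("(a|a?)+$"), timeout = 0.5),
    "skipped")
  expect_equal(nrow(sp), 0)
})

test_that("adjacent-word extension follows the documented rules", {
  sw <- defaultStopwords()
  tx1 <- "We saw citric acid here."
  # span over "citric" only
  expect_equal(extendAdjacent(7L, 13L, tx1, sw), c(7L, 18L))
  # preceding stopword blocks extension
  tx2 <- "values of the malate rose."
  s <- regexpr("malate", tx2) - 1L
  expect_equal(extendAdjacent(s, s + 6L, tx2, sw), c(s, s + 6L))
  # hyphen-final preceding word is absorbed
  tx3 <- "found gamma- aminobutyrate today."
  s3 <- regexpr("aminobutyrate", tx3) - 1L
  expect_equal(extendAdjacent(s3, s3 + 13L, tx3, sw),
               c(6L, s3 + 13L))
  # never crosses the sentence bounds, never ends in whitespace
  tx4 <- "citric"
  expect_equal(extendAdjacent(0L, 6L, tx4, sw), c(0L, 6L))
})

test_that("extension equals an independent word-level rule simulator", {
  sw <- defaultStopwords()
  vocab <- c("alpha-", "beta", "12", "the", "and", "acid", "ester",
             "level", "x9", "-keto", ",3-form", "sample")
  set.seed(41)
  for (rep in 1:300) {
    words <- sample(vocab, sample(3:7, 1), replace = TRUE)
    tx <- paste(words, collapse = " ")
    m <- gregexpr("\\S+", tx)[[1]]
    k <- sample(seq_along(m), 1)
    start <- m[k] - 1L
    end <- start + attr(m, "match.length")[k]
    expect_equal(extendAdjacent(start, end, tx, sw),
                 oracleExtend(tx, start, end, sw))
  }
})

test_that("bracket balancing adds exactly the missing side", {
  expect_equal(balanceBrackets("S)-malate"), "(S)-malate")
  expect_equal(balanceBrackets("(R)-lactate"), "(R)-lactate")
  expect_equal(balanceBrackets("PC(16:0"), "PC(16:0)")
  expect_equal(balanceBrackets("[2H]citrate"), "[2H]citrate")
  # bracket-count oracle on random strings
  set.seed(5)
  alphabet <- c(letters[1:4], "(", ")", "[", "]", "{", "}")
  for (rep in 1:200) {
    s <- paste(sample(alphabet, sample(2:9, 1), replace = TRUE),
               collapse = "")
    out <- balanceBrackets(s)
    for (p in list(c("\\(", "\\)"), c("\\[", "\\]"), c("\\{", "\\}"))) {
      no <- lengths(gregexpr(p[1], out))
      nc <- lengths(gregexpr(p[2], out))
      if (gregexpr(p[1], out)[[1]][1] == -1) no <- 0
      if (gregexpr(p[2], out)[[1]][1] == -1) nc <- 0
      expect_equal(no, nc)
    }
    expect_true(grepl(s, out, fixed = TRUE))
  }
})

test_that("merging matches the pairwise union-find closure oracle", {
  tx <- paste(rep("word", 30), collapse = " ")
  # spans separated by exactly one space character merge
  tx1 <- paste0(strrep("a", 10), "bcdefgh ijkl", strrep(" z", 9))
  expect_equal(
    mergeSpans(data.frame(start = c(10L, 18L), end = c(17L, 22L),
                          source = "dictionary"), tx1)[, c("start", "end")],
    data.frame(start = 10L, end = 22L))
  expect_equal(
    mergeSpans(data.frame(start = c(0L, 4L), end = c(7L, 12L),
                          source = "dictionary"), tx)[, c("start", "end")],
    data.frame(start = 0L, end = 12L))
  set.seed(17)
  n <- nchar(tx)
  for (rep in 1:300) {
    k <- sample(1:6, 1)
    starts <- sort(sample(0:(n - 3), k))
    ends <- pmin(starts + sample(1:6, k, replace = TRUE), n)
    spans <- data.frame(start = starts, end = ends, source = "x")
    got <- mergeSpans(spans, tx)[, c("start", "end")]
    want <- oracleMerge(spans, tx)
    expect_equal(unname(as.matrix(got)), unname(as.matrix(want)),
                 ignore_attr = TRUE)
    # no two output spans overlap or are whitespace-separated
    if (nrow(got) > 1) {
      for (i in 2:nrow(got)) {
        gap <- substr(tx, got$end[i - 1] + 1, got$start[i])
        expect_true(nzchar(gap) && !grepl("^\\s+$", gap))
      }
    }
  }
})

test_that("sentence annotation recovers planted mentions and is a fixpoint", {
  dict <- fixtureBundle$dict
  corpus <- fixtureBundle$corpus
  sent <- corpus$sentences[1:40, ]
  for (i in seq_len(nrow(sent))) {
    r1 <- annotateSentence(sent[i, ], dict)
    r2 <- annotateSentence(sent[i, ], dict)
    expect_identical(r1, r2)
    if (nrow(r1)) {
      spans <- data.frame(start = r1$start, end = r1$end, source = "x")
      again <- postProcessSpans(spans, sent$text[i])
      expect_equal(again[, c("start", "end")],
                   spans[, c("start", "end")], ignore_attr = TRUE)
      expect_equal(substr(rep(sent$text[i], nrow(r1)),
                          r1$start + 1, r1$end), r1$entity)
    }
  }
  expect_equal(nrow(annotateSentence("Nothing to see here.", dict)), 0)
})

test_that("coordinated mentions annotate only the complete surface form", {
  d <- newDictionary("3-methylhistidine")
  r <- annotateSentence("We measured 1- and 3-methylhistidine in urine.",
                        d, pattern_set = NULL)
  expect_equal(nrow(r), 1)
  expect_equal(r$entity, "3-methylhistidine")
})

test_that("the fix-up recursion guard triggers on pathological budgets", {
  d <- newDictionary("citric")
  expect_error(
    annotateSentence("x- citric acid", d, pattern_set = NULL,
                     max_iter = 0L),
    "converge")
})
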