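test_that("table cells are annotated as standalone sentences with table IDs", {
  dict <- newDictionary(c("glucose", "citric acid"))
  art <- newArticle("PMC000010",
    sections = list(list(code = "R", group = "R",
                         iao_term = "results section",
                         subsections = "No mentions here.")),
    tables = list(list(identifier = "Table 1",
                       rows = list(c("glucose", "1.23"),
                                   c("noise", "4.56")))))
  recs <- annotateDocument(art, ruleAnnotator(dict, pattern_set = NULL))
  tab <- recs[recs$source == "table", ]
  expect_equal(nrow(tab), 1)
  expect_equal(tab$entity, "glucose")
  expect_match(tab$sentence_id, "^T00R000C000$")
  # empty tables -> text records only
  art2 <- newArticle("PMC000011",
    sections = list(list(code = "A", group = "A",
                         iao_term = "textual abstract section",
                         subsections = "Serum glucose was measured.")))
  recs2 <- annotateDocument(art2, ruleAnnotator(dict, pattern_set = NULL))
  expect_true(all(recs2$source == "text"))
  expect_equal(recs2$entity, "glucose")
})

test_that("only A/M/R/D sentences produce text records", {
  dict <- newDictionary("glucose")
  dir <- withr::local_tempdir()
  art <- newArticle("PMC000012",
    sections = list(list(code = "M", group = "M",
                         iao_term = "methods section",
                         subsections = "We spiked glucose in.")))
  paths <- writeArticleJSON(art, dir)
  doc <- jsonlite::fromJSON(paths["maintext"], simplifyVector = FALSE)
  doc$paragraphs <- c(doc$paragraphs, list(list(
    section_heading = "Introduction", subsection_heading = "",
    body = "Background glucose prose.",
    IAO_term = "introduction section", IAO_ID = "IAO:x")))
  jsonlite::write_json(doc, paths["maintext"], auto_unbox = TRUE)
  got <- readArticle(paths["maintext"])
  recs <- annotateDocument(got, ruleAnnotator(dict, pattern_set = NULL))
  expect_equal(nrow(recs), 1)
  expect_equal(substr(recs$sentence_id, 1, 1), "M")
})

test_that("abbreviations link only when the whole definition is recognised", {
  dict <- newDictionary("trimethylamine N-oxide")
  sentences <- data.frame(
    pmcid = "PMC000013",
    sentence_id = c("A00000", "R00000"),
    section = c("A", "R"), group = c("A", "R"),
    text = c("Plasma TMAO rose sharply.",
             "No TMAO change was seen in controls (TMAO)."),
    stringsAsFactors = FALSE)
  ann <- ruleAnnotator(dict, pattern_set = NULL)
  recs <- linkAbbreviations(c(TMAO = "trimethylamine N-oxide"),
                            ann, sentences)
  expect_equal(nrow(recs), 3)
  expect_true(all(recs$source == "abbreviation"))
  expect_true(all(recs$entity == "TMAO"))
  # offsets point at real occurrences
  expect_equal(substr(sentences$text[1], recs$start[1] + 1, recs$end[1]),
               "TMAO")
  # partially recognised definition -> no links
  dict2 <- newDictionary("trimethylamine")
  recs2 <- linkAbbreviations(c(TMAO = "trimethylamine N-oxide"),
                             ruleAnnotator(dict2, pattern_set = NULL),
                             sentences)
  expect_equal(nrow(recs2), 0)
  # empty map -> no records
  expect_equal(nrow(linkAbbreviations(character(0), ann, sentences)), 0)
  # short-form matching is case-sensitive whole-word: neither "tmao"
  # nor "TMAOx" links, only the two occurrences in the second sentence
  sentences$text[1] <- "The tmao and TMAOx forms differ."
  left <- linkAbbreviations(c(TMAO = "trimethylamine N-oxide"),
                            ann, sentences)
  expect_equal(nrow(left), 2)
  expect_true(all(left$sentence_id == "R00000"))
})

test_that("source labels partition document records", {
  corpus <- fixtureBundle$corpus
  dict <- fixtureBundle$dict
  withAbbrev <- which(vapply(corpus$articles,
                             function(a) length(abbreviations(a)) > 0,
                             logical(1)))[1]
  art <- corpus$articles[[withAbbrev]]
  recs <- annotateDocument(art, ruleAnnotator(dict))
  expect_true(all(recs$source %in% c("text", "table", "abbreviation")))
  expect_gt(sum(recs$source == "abbreviation"), 0)
})

test_that("per-article entity collection honours section groups and tables", {
  recs <- annotationRecords(
    pmcid = c("P1", "P1", "P1"),
    sentence_id = c("A00000", "M00000", "T00R000C000"),
    start = c(0, 0, 0), end = c(3, 3, 3),
    entity = c("foo", "bar", "baz"),
    source = c("text", "text", "table"))
  sentences <- data.frame(pmcid = "P1",
                          sentence_id = c("A00000", "M00000"),
                          group = c("A", "M"),
                          text = c("foo x", "bar y"),
                          stringsAsFactors = FALSE)
  ents <- entitiesByArticle(recs, sentences)
  # methods-section record excluded, table record kept
  expect_setequal(ents$P1, c("foo", "baz"))
  ents2 <- entitiesByArticle(recs, sentences, include_tables = FALSE)
  expect_setequal(ents2$P1, "foo")
})
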