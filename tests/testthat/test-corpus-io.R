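test_that("IAO-based section filtering keeps A/M/R/D and drops introductions", {
  dir <- withr::local_tempdir()
  art <- newArticle("PMC000001",
    sections = list(
      list(code = "M", group = "M", iao_term = "methods section",
           subsections = c("We did things. We did more things.")),
      list(code = "R", group = "R", iao_term = "results section",
           subsections = c("Things happened."))))
  paths <- writeArticleJSON(art, dir)
  # hand-inject an introduction paragraph to confirm it is filtered
  doc <- jsonlite::fromJSON(paths["maintext"], simplifyVector = FALSE)
  intro <- list(section_heading = "Introduction", subsection_heading = "",
                body = "Background prose.",
                IAO_term = "introduction section", IAO_ID = "IAO:x")
  doc$paragraphs <- c(list(intro), doc$paragraphs)
  jsonlite::write_json(doc, paths["maintext"], auto_unbox = TRUE)
  got <- readArticle(paths["maintext"])
  expect_equal(vapply(sections(got), `[[`, "", "code"), c("M", "R"))
  # an article with no A/M/R/D sections warns and yields no sections
  doc$paragraphs <- list(intro)
  jsonlite::write_json(doc, paths["maintext"], auto_unbox = TRUE)
  expect_warning(empty <- readArticle(paths["maintext"]),
                 "no A/M/R/D")
  expect_length(sections(empty), 0)
})

test_that("malformed and incomplete JSON raise informative errors", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(readArticle(bad), "malformed JSON")
  writeLines('{"paragraphs": [{"body": "text only"}]}', bad)
  expect_error(readArticle(bad), "IAO_term")
})

test_that("sentence identifiers encode section letter + subsection + index", {
  art <- newArticle("PMC000002",
    sections = list(
      list(code = "A", group = "A", iao_term = "textual abstract section",
           subsections = "One sentence only."),
      list(code = "M", group = "M", iao_term = "methods section",
           subsections = c("First methods sentence. Second one here.",
                           "Second subsection opens. Second sentence of it."))))
  s <- articleSentences(art)
  expect_equal(s$sentence_id[1], "A00000")
  # second sentence of the second methods subsection
  expect_equal(s$sentence_id[s$text == "Second sentence of it."], "M01001")
  expect_false(any(duplicated(paste(s$pmcid, s$sentence_id))))
  # lexicographic order within a subsection follows sentence order
  m1 <- s$sentence_id[s$section == "M"]
  expect_identical(m1, sort(m1))
})

test_that("combined results-and-discussion sections use ID code R, group RD", {
  art <- newArticle("PMC000003", sections = list(
    list(code = "R", group = "RD",
         iao_term = "results and discussion section",
         subsections = "Mixed prose here.")))
  s <- articleSentences(art)
  expect_equal(substr(s$sentence_id, 1, 1), "R")
  expect_equal(s$group, "RD")
})

test_that("sentence splitter ignores decimals and latin abbreviations", {
  txt <- "Values rose by 2.5 fold, e.g. in serum. A second sentence follows."
  sp <- defaultSentenceSplitter(txt)
  expect_equal(nrow(sp), 2)
  first <- substr(txt, sp[1, 1] + 1, sp[1, 2])
  expect_match(first, "serum\\.$")
})

test_that("fixture articles reproduce their generated sentences and IDs", {
  corpus <- fixtureBundle$corpus
  art <- corpus$articles[[1]]
  got <- articleSentences(art)
  want <- corpus$sentences[corpus$sentences$pmcid == pmcid(art), ]
  rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("corpus files round-trip byte-identically and enforce integrity", {
  corpus <- fixtureBundle$corpus
  gold <- goldOf(corpus)
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "c.txt"); f2 <- file.path(dir, "c.tsv")
  writeCorpusFiles(corpus$sentences, gold, f1, f2)
  back <- readCorpusFiles(f1, f2)
  # only annotated sentences are written
  akey <- unique(paste(gold$pmcid, gold$sentence_id))
  expect_setequal(paste(back$sentences$pmcid, back$sentences$sentence_id),
                  akey)
  expect_equal(back$annotations[, 1:5],
               gold[, c("pmcid", "sentence_id", "start", "end", "entity")],
               ignore_attr = TRUE)
  # byte-identical second write
  g1 <- file.path(dir, "d.txt"); g2 <- file.path(dir, "d.tsv")
  writeCorpusFiles(back$sentences, back$annotations, g1, g2)
  expect_identical(readLines(f1), readLines(g1))
  expect_identical(readLines(f2), readLines(g2))
  # empty annotation set -> header-only files
  writeCorpusFiles(corpus$sentences, gold[0, ], g1, g2)
  expect_length(readLines(g1), 0)
  expect_true(all(startsWith(readLines(g2), "#")))
  # referential integrity
  broken <- gold[1, ]; broken$sentence_id <- "Z99999"
  expect_error(writeCorpusFiles(corpus$sentences, broken, g1, g2),
               "unknown sentence")
})

test_that("every gold record's entity equals its sentence substring", {
  corpus <- fixtureBundle$corpus
  gold <- goldOf(corpus, c("text", "abbreviation"))
  idx <- match(paste(gold$pmcid, gold$sentence_id),
               paste(corpus$sentences$pmcid, corpus$sentences$sentence_id))
  expect_false(anyNA(idx))
  expect_equal(substr(corpus$sentences$text[idx], gold$start + 1, gold$end),
               gold$entity)
})

test_that("sentence-ID capacity overflow is detected", {
  art <- newArticle("PMC000004", sections = list(
    list(code = "A", group = "A", iao_term = "textual abstract section",
         subsections = rep("A sentence.", 101))))
  expect_error(articleSentences(art), "capacity")
})
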