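makeDictFile <- function(df) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  f
}

test_that("status filtering keeps quantified/detected by default", {
  f <- makeDictFile(data.frame(
    name = c("glucose", "endoxifen"), synonyms = c("", ""),
    status = c("detected", "expected")))
  d <- loadDictionary(f)
  expect_identical(dictEntries(d), "glucose")
  dAll <- loadDictionary(f, statuses = c("quantified", "detected",
                                         "expected", "predicted"))
  expect_setequal(dictEntries(dAll), c("glucose", "endoxifen"))
})

test_that("synonyms expand into entries carrying the parent status", {
  f <- makeDictFile(data.frame(
    name = "citric acid", synonyms = "citrate|2-hydroxypropane-123",
    status = "quantified"))
  d <- loadDictionary(f)
  expect_setequal(dictEntries(d),
                  c("citric acid", "citrate", "2-hydroxypropane-123"))
  expect_true(all(dictStatus(d) == "quantified"))
})

test_that("schema errors and empty results behave as documented", {
  f <- makeDictFile(data.frame(name = "glucose", synonyms = ""))
  expect_error(loadDictionary(f), "status")
  f2 <- makeDictFile(data.frame(name = "endoxifen", synonyms = "",
                                status = "expected"))
  expect_warning(d <- loadDictionary(f2), "empty")
  expect_length(dictEntries(d), 0)
})

test_that("counting oracle: status subsetting matches brute force", {
  fx <- makeDictionary(50, seed = 3)
  f <- makeDictFile(fx$table)
  d <- loadDictionary(f, statuses = c("quantified", "detected"))
  # brute-force count from the raw table (names only; synonyms add more)
  rawKeep <- fx$table$status %in% c("quantified", "detected")
  expectMin <- sum(rawKeep)
  baseNames <- intersect(tolower(dictEntries(d)),
                         tolower(fx$table$name))
  expect_length(baseNames, expectMin)
})

test_that("cleaning removes short ambiguous and blocklisted entries, idempotently", {
  d <- newDictionary(c("PC", "phosphatidylcholine", "result",
                       "omeprazole", "ATP"),
                     whitelist = "atp")
  c1 <- cleanDictionary(d, blocklist = c("result"))
  expect_setequal(dictEntries(c1),
                  c("phosphatidylcholine", "omeprazole", "ATP"))
  expect_setequal(c1@removed, c("PC", "result"))
  c2 <- cleanDictionary(c1, blocklist = c("result"))
  expect_identical(dictEntries(c2), dictEntries(c1))
  # cleaning never adds entries
  expect_true(all(dictEntries(c1) %in% dictEntries(d)))
})

test_that("reference set is exactly the space/hyphen/colon entries", {
  d <- newDictionary(c("glucose", "citric acid", "PC(16:0/18:1)",
                       "3-methylhistidine"))
  rs <- buildReferenceSet(d)
  expect_setequal(rs, c("citric acid", "PC(16:0/18:1)",
                        "3-methylhistidine"))
  expect_length(buildReferenceSet(newDictionary(c("glucose", "alanine"))), 0)
  # brute-force substring scan oracle on a generated dictionary
  fx <- makeDictionary(40, seed = 5)
  d2 <- newDictionary(fx$names)
  want <- fx$names[vapply(fx$names, function(s) {
    any(strsplit(s, "")[[1]] %in% c(" ", "-", ":"))
  }, logical(1))]
  expect_setequal(buildReferenceSet(d2), want)
})

test_that("pattern coverage counts partially matched terms and is monotone", {
  terms <- c("lactate-2", "citric acid", "PC(16:0)")
  cov0 <- patternCoverage(character(0), terms)
  expect_equal(cov0$coverage, 0)
  expect_setequal(cov0$uncovered, terms)
  expect_equal(patternCoverage(".", terms)$coverage, 1)
  cov1 <- patternCoverage("ate", terms)
  # brute-force per-term match oracle
  want <- vapply(terms, function(tm) grepl("ate", tm), logical(1))
  expect_equal(cov1$coverage, mean(want))
  expect_setequal(cov1$covered, terms[want])
  cov2 <- patternCoverage(c("ate", "acid"), terms)
  expect_gte(cov2$coverage, cov1$coverage)
  expect_error(patternCoverage("(unclosed", terms), "compile")
})
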