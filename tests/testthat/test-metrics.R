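randRecords <- function(n, pmcids = c("P1", "P2"), seed) {
  set.seed(seed)
  annotationRecords(
    pmcid = sample(pmcids, n, replace = TRUE),
    sentence_id = sprintf("A%05d", sample(0:5, n, replace = TRUE)),
    start = s <- sample(0:30, n, replace = TRUE),
    end = s + sample(1:8, n, replace = TRUE),
    entity = strrep("x", sample(1:8, n, replace = TRUE)))
}

test_that("exact matching equals the set-algebra oracle", {
  g <- randRecords(8, seed = 1)
  expect_equal(matchAnnotations(g, g), list(tp = nrow(unique(g[1:4])),
                                            fp = 0L, fn = 0L))
  for (seed in 1:20) {
    p <- randRecords(10, seed = seed)
    g <- randRecords(10, seed = seed + 100)
    p <- p[!duplicated(p[1:4]), ]; g <- g[!duplicated(g[1:4]), ]
    key <- function(x) paste(x$pmcid, x$sentence_id, x$start, x$end)
    m <- matchAnnotations(p, g)
    expect_equal(m$tp, length(intersect(key(p), key(g))))
    expect_equal(m$fp, length(setdiff(key(p), key(g))))
    expect_equal(m$fn, length(setdiff(key(g), key(p))))
  }
})

test_that("a shifted span costs one fp and one fn", {
  g <- randRecords(8, seed = 2)
  g <- g[!duplicated(g[1:4]), ]
  p <- g
  p$start[1] <- p$start[1] + 1L
  m <- matchAnnotations(p, g)
  expect_equal(m, list(tp = nrow(g) - 1L, fp = 1L, fn = 1L))
  # duplicates are deduplicated with a warning
  expect_warning(matchAnnotations(rbind(g, g[1, ]), g), "duplicate")
})

test_that("source filters apply to both sides", {
  g <- randRecords(6, seed = 3)
  g$source <- c(rep("text", 4), rep("table", 2))
  p <- g
  m <- matchAnnotations(p, g, include_sources = "text")
  expect_equal(m$tp + m$fp, 4L)
  m2 <- matchAnnotations(p, g, include_sources = c("text", "table"))
  expect_equal(m2$tp, nrow(unique(g[1:4])))
})

test_that("score arithmetic matches its definitions and degenerate flags", {
  s <- nerScore(8, 2, 4)
  expect_equal(s$precision, 0.8)
  expect_equal(s$recall, 8 / 12)
  expect_equal(s$f1, 2 * 0.8 * (8 / 12) / (0.8 + 8 / 12))
  expect_equal(s$fstar, 0.8 * (8 / 12) / (0.8 + 8 / 12 - 0.8 * 8 / 12))
  expect_false(s$degenerate)
  z <- nerScore(0, 0, 3)
  expect_true(z$degenerate)
  expect_equal(z$precision, 0)
  perfect <- nerScore(5, 0, 0)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$fstar, 1)
})

test_that("F* never exceeds F1, which never exceeds max(p, r)", {
  set.seed(7)
  for (rep in 1:200) {
    p <- runif(1, 0.01, 1); r <- runif(1, 0.01, 1)
    fm <- fMeasures(p, r)
    expect_lte(fm$fstar, fm$f1 + 1e-12)
    expect_lte(fm$f1, max(p, r) + 1e-12)
  }
  eq <- fMeasures(1, 1)
  expect_equal(eq$f1, eq$fstar)
})

test_that("per-section metrics partition and conserve global counts", {
  corpus <- fixtureBundle$corpus
  gold <- goldOf(corpus)
  pred <- gold
  set.seed(9)                       # corrupt a few predictions
  flip <- sample(nrow(pred), 5)
  pred$start[flip] <- pred$start[flip] + 1L
  per <- perSectionMetrics(pred, gold, corpus$sentences)
  gl <- matchAnnotations(pred, gold)
  expect_equal(sum(vapply(per, `[[`, 0, "tp")), gl$tp)
  expect_equal(sum(vapply(per, `[[`, 0, "fp")), gl$fp)
  expect_equal(sum(vapply(per, `[[`, 0, "fn")), gl$fn)
  # per-group scores equal a partition-then-score oracle
  skey <- paste(corpus$sentences$pmcid, corpus$sentences$sentence_id)
  for (grp in names(per)) {
    sel <- corpus$sentences$group[match(paste(gold$pmcid,
                                              gold$sentence_id),
                                        skey)] == grp
    selP <- corpus$sentences$group[match(paste(pred$pmcid,
                                               pred$sentence_id),
                                         skey)] == grp
    mo <- matchAnnotations(pred[selP, ], gold[sel, ])
    expect_equal(per[[grp]]$tp, mo$tp)
  }
  # unknown sentence is an integrity error
  bad <- pred; bad$sentence_id[1] <- "Z00000"
  expect_error(perSectionMetrics(bad, gold, corpus$sentences), "absent")
  # all records in one group -> only that key present
  aOnly <- gold[substr(gold$sentence_id, 1, 1) == "A", ]
  expect_named(perSectionMetrics(aOnly, aOnly, corpus$sentences), "A")
})

test_that("corpus statistics count each metabolite once per article", {
  one <- corpusStats(list(P1 = c("Glucose", "glucose", "GLUCOSE")))
  expect_equal(one$n_unique_metabolites, 1L)
  expect_equal(one$n_articles, 1L)
  expect_equal(one$mean_per_article, 1.0)
  # brute-force per-article set-size oracle on fixture annotations
  corpus <- fixtureBundle$corpus
  gold <- goldOf(corpus)
  ents <- split(gold$entity, gold$pmcid)
  st <- corpusStats(ents)
  want <- sum(vapply(ents, function(e) length(unique(tolower(e))),
                     integer(1)))
  expect_equal(st$n_unique_metabolites, want)
  expect_equal(st$n_articles, length(ents))
  expect_equal(st$mean_per_article, round(want / length(ents), 1))
  # grouping splits articles
  grp <- stats::setNames(rep(c("g1", "g2"), length.out = length(ents)),
                         names(ents))
  st2 <- corpusStats(ents, grp)
  expect_setequal(st2$group, c("g1", "g2"))
  expect_equal(sum(st2$n_articles), length(ents))
})

test_that("evaluation reports serialise scores at 4 decimal places", {
  sc <- list(overall = nerScore(100, 13, 12))
  f <- withr::local_tempfile(fileext = ".tsv")
  j <- withr::local_tempfile(fileext = ".json")
  df <- writeEvalReport(sc, f, j)
  expect_equal(df$precision, round(100 / 113, 4))
  expect_true(file.exists(f))
  parsed <- jsonlite::fromJSON(j)
  expect_equal(parsed$overall$tp, 100)
})
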