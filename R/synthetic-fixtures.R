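# Deterministic synthetic fixtures: toy metabolite dictionaries,
# articles in the Auto-CORPus-style JSON dialects with planted gold
# annotations (optionally typo-corrupted), abbreviations and tables,
# and word-vector files. Everything is fully determined by the seed, so
# the whole pipeline can be exercised without downloads.

withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

fixtureStems <- c("gluc", "lact", "citr", "pyruv", "succin", "fumar",
                  "malon", "palmit", "stear", "oleand", "cholester",
                  "creatin", "tyros", "leucin", "valer", "adenos",
                  "guanid", "histid", "threon", "sarcos", "taurin",
                  "carnit", "betain", "xanth", "hippur", "indox",
                  "kynuren", "spermid", "putresc", "cadaver")

fixturePrefixes <- c("hydroxy", "methyl", "acetyl", "phospho", "amino")

#' Generate a toy metabolite dictionary
#'
#' Composes metabolite-like names from stems and chemistry suffixes
#' (-ate, -ose, -ine, -ol, -itol), multiword acid forms ("citrulic
#' acid" style), prefixed and numbered forms ("3-hydroxypalmitate") and
#' lipid shorthand with brackets and colons ("PC(16:0/18:1)"). Statuses
#' cycle through quantified/detected/expected/predicted with the given
#' weights; some entries receive a synonym. All generated names are
#' longer than 5 characters and off the default blocklist, so a default
#' clean pass keeps them.
#'
#' @param n_names number of names.
#' @param seed integer seed (all output is a pure function of it).
#' @param status_weights sampling weights for quantified, detected,
#'   expected, predicted.
#' @return list(table = data.frame(name, synonyms, status),
#'   names = character vector).
#' @export
makeDictionary <- function(n_names, seed = 1L,
                           status_weights = c(0.4, 0.4, 0.15, 0.05)) {
  stopifnot(n_names >= 1L)
  withSeed(deriveSeed(seed, 11L), {
    suffixes <- c("ate", "ose", "ine", "ol", "itol")
    lipidClasses <- c("PC", "PE", "SM", "TG", "LPC")
    names <- character(0)
    k <- 0L
    while (length(names) < n_names && k < n_names * 20L) {
      k <- k + 1L
      kind <- sample(c("suffix", "acid", "prefixed", "numbered",
                       "lipid"), 1,
                     prob = c(0.45, 0.2, 0.15, 0.1, 0.1))
      nm <- switch(kind,
        suffix = paste0(sample(fixtureStems, 1),
                        sample(suffixes, 1)),
        acid = paste0(sample(fixtureStems, 1), "ic acid"),
        prefixed = paste0(sample(fixturePrefixes, 1),
                          sample(fixtureStems, 1),
                          sample(suffixes, 1)),
        numbered = paste0(sample(2:9, 1), "-",
                          sample(fixturePrefixes, 1),
                          sample(fixtureStems, 1),
                          sample(suffixes, 1)),
        lipid = sprintf("%s(%d:%d/%d:%d)",
                        sample(lipidClasses, 1),
                        sample(c(14, 16, 18, 20), 1), sample(0:2, 1),
                        sample(c(14, 16, 18, 20), 1), sample(0:2, 1)))
      if (nchar(nm) <= 5L || foldCase(nm) %in% foldCase(names)) next
      names <- c(names, nm)
    }
    if (length(names) < n_names)
      stop("could not compose ", n_names, " distinct names")
    status <- sample(c("quantified", "detected", "expected",
                       "predicted"), length(names), replace = TRUE,
                     prob = status_weights)
    synonyms <- character(length(names))
    synIdx <- which(grepl("ic acid$", names))
    for (i in synIdx)   # acid <-> -ate synonym pairs, as databases list
      synonyms[i] <- sub("ic acid$", "ate-form", names[i])
    list(table = data.frame(name = names, synonyms = synonyms,
                            status = status, stringsAsFactors = FALSE),
         names = names)
  })
}

#' Write a dictionary fixture to a TSV file
#'
#' @param dict_fixture from \code{\link{makeDictionary}}.
#' @param path output TSV.
#' @export
writeDictionaryFile <- function(dict_fixture, path) {
  utils::write.table(dict_fixture$table, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

# sentence templates as (prefix, separator..., suffix) pieces between
# planted mentions; chosen so no adjacent-word fix-up rule fires on the
# planted names and no template word matches the default pattern set
sentenceTemplates <- list(
  list(n = 0L, parts = c("The cohort was profiled with untargeted assays.")),
  list(n = 0L, parts = c("Spectral data were processed with standard software.")),
  list(n = 1L, parts = c("Levels of ", " were higher in cases.")),
  list(n = 1L, parts = c("Concentrations of ", " correlated with the outcome.")),
  list(n = 1L, parts = c("In serum, ", " was reduced after treatment.")),
  list(n = 1L, parts = c("The assay detected ", " in plasma samples.")),
  list(n = 2L, parts = c("We observed that ", " and ",
                         " differed between groups.")),
  list(n = 2L, parts = c("Both ", " and ", " were measured by NMR.")))

#' Corrupt a metabolite name by one character
#'
#' Single-character deletion or substitution (never the first
#' character), avoiding every name in \code{forbidden} — the typo model
#' used by the corpus generator and by generalisation tests. Uses the
#' current RNG state; wrap in \code{set.seed} for determinism.
#'
#' @param name name to corrupt.
#' @param forbidden case-folded names the corruption must not equal.
#' @return the corrupted string (the input if no corruption was found).
#' @export
corruptName <- function(name, forbidden) {
  letters26 <- letters
  for (try in 1:20) {
    pos <- sample(2:nchar(name), 1)
    if (sample(c(TRUE, FALSE), 1) && nchar(name) > 6L) {
      cand <- paste0(substr(name, 1, pos - 1L),
                     substr(name, pos + 1L, nchar(name)))
    } else {
      ch <- sample(letters26, 1)
      cand <- paste0(substr(name, 1, pos - 1L), ch,
                     substr(name, pos + 1L, nchar(name)))
    }
    if (!foldCase(cand) %in% forbidden && cand != name) return(cand)
  }
  name
}

buildSentence <- function(template, mentions, corruptedFlags) {
  parts <- template$parts
  text <- parts[1]
  gold <- list()
  if (template$n > 0L) {
    for (k in seq_len(template$n)) {
      start <- nchar(text)
      text <- paste0(text, mentions[k])
      gold[[k]] <- data.frame(start = start,
                              end = nchar(text),
                              entity = mentions[k],
                              corrupted = corruptedFlags[k],
                              stringsAsFactors = FALSE)
      text <- paste0(text, parts[k + 1L])
    }
  }
  list(text = text, gold = do.call(rbind, gold))
}

#' Generate a synthetic annotated corpus
#'
#' Builds \code{n_articles} articles with abstract/methods/results/
#' discussion sections (1-2 subsections of 2-3 sentences each),
#' planting dictionary names into sentence templates and recording the
#' gold character spans at plant time. With probability
#' \code{typo_rate} a planted mention is corrupted by one character
#' (deletion or substitution away from every dictionary name) and
#' flagged, emulating the spelling errors deep models can recover but
#' exact matching cannot. With probability \code{abbrev_rate} an
#' article defines an abbreviation for a multiword name, mentions the
#' short form in the discussion and records the gold abbreviation
#' occurrences. With probability \code{table_rate} an article carries a
#' table whose metabolite cells are gold table records.
#'
#' @param n_articles number of articles.
#' @param dict_names character vector of plantable names (e.g. the
#'   cleaned dictionary entries).
#' @param typo_rate,abbrev_rate,table_rate rates in [0,1].
#' @param seed integer seed.
#' @return list(articles, sentences, gold) where gold carries columns
#'   pmcid, sentence_id, start, end, entity, source, corrupted.
#' @export
makeCorpus <- function(n_articles, dict_names, typo_rate = 0,
                       abbrev_rate = 0, table_rate = 0.3, seed = 1L) {
  stopifnot(n_articles >= 1L, length(dict_names) >= 2L,
            typo_rate >= 0, typo_rate <= 1,
            abbrev_rate >= 0, abbrev_rate <= 1)
  folded <- foldCase(dict_names)
  withSeed(deriveSeed(seed, 23L), {
    articles <- list()
    goldAll <- list()
    sentAll <- list()
    secPlan <- list(c(code = "A", group = "A",
                      iao = "textual abstract section"),
                    c(code = "M", group = "M", iao = "methods section"),
                    c(code = "R", group = "R", iao = "results section"),
                    c(code = "D", group = "D", iao = "discussion section"))
    for (ai in seq_len(n_articles)) {
      pmc <- sprintf("PMC%06d", 700000L + ai)
      sections <- list()
      for (sp in secPlan) {
        nSub <- sample(1:2, 1)
        subs <- character(nSub)
        for (si in seq_len(nSub)) {
          nSent <- sample(2:3, 1)
          sentTexts <- character(nSent)
          for (li in seq_len(nSent)) {
            tmpl <- sentenceTemplates[[
              sample(seq_along(sentenceTemplates), 1)]]
            mentions <- character(0); flags <- logical(0)
            if (tmpl$n > 0L) {
              mentions <- sample(dict_names, tmpl$n)
              flags <- stats::runif(tmpl$n) < typo_rate
              for (k in which(flags))
                mentions[k] <- corruptName(mentions[k], folded)
            }
            built <- buildSentence(tmpl, mentions, flags)
            sid <- sprintf("%s%02d%03d", sp[["code"]], si - 1L, li - 1L)
            sentTexts[li] <- built$text
            sentAll[[length(sentAll) + 1L]] <- data.frame(
              pmcid = pmc, sentence_id = sid, section = sp[["code"]],
              group = sp[["group"]], text = built$text,
              stringsAsFactors = FALSE)
            if (!is.null(built$gold) && nrow(built$gold)) {
              g <- built$gold
              g$pmcid <- pmc; g$sentence_id <- sid; g$source <- "text"
              goldAll[[length(goldAll) + 1L]] <-
                g[, c("pmcid", "sentence_id", "start", "end", "entity",
                      "source", "corrupted")]
            }
          }
          subs[si] <- paste(sentTexts, collapse = " ")
        }
        sections[[length(sections) + 1L]] <-
          list(code = sp[["code"]], group = sp[["group"]],
               iao_term = sp[["iao"]], subsections = subs)
      }
      tables <- list()
      if (stats::runif(1) < table_rate) {
        nCells <- sample(2:4, 1)
        cellNames <- sample(dict_names, nCells)
        rows <- lapply(seq_len(nCells), function(ri)
          c(cellNames[ri], sprintf("%.2f", stats::runif(1, 0.1, 9.9))))
        tables <- list(list(identifier = "Table 1", rows = rows))
        for (ri in seq_len(nCells))
          goldAll[[length(goldAll) + 1L]] <- data.frame(
            pmcid = pmc,
            sentence_id = sprintf("T%02dR%03dC%03d", 0L, ri - 1L, 0L),
            start = 0L, end = nchar(cellNames[ri]),
            entity = cellNames[ri], source = "table",
            corrupted = FALSE, stringsAsFactors = FALSE)
      }
      abbrevs <- character(0)
      if (stats::runif(1) < abbrev_rate) {
        multi <- dict_names[grepl(" ", dict_names)]
        defn <- if (length(multi)) sample(multi, 1) else
          sample(dict_names, 1)
        shortForm <- toupper(paste(substr(strsplit(defn, "[ -]")[[1]],
                                          1, 1), collapse = ""))
        if (nchar(shortForm) < 2L)
          shortForm <- toupper(substr(gsub("[^A-Za-z]", "", defn), 1, 3))
        abbrevs <- stats::setNames(defn, shortForm)
        extra <- paste0("The ", shortForm, " level declined over time.")
        sid <- "D99000"
        sections[[length(sections) + 1L]] <-
          list(code = "D", group = "D",
               iao_term = "discussion section", subsections = extra)
        # the synthetic extra subsection lands at the next D index;
        # recompute its true id from the current D subsection count
        dCount <- sum(vapply(sections, function(s)
          if (s$code == "D") length(s$subsections) else 0L, integer(1)))
        sid <- sprintf("D%02d%03d", dCount - 1L, 0L)
        sentAll[[length(sentAll) + 1L]] <- data.frame(
          pmcid = pmc, sentence_id = sid, section = "D", group = "D",
          text = extra, stringsAsFactors = FALSE)
        goldAll[[length(goldAll) + 1L]] <- data.frame(
          pmcid = pmc, sentence_id = sid,
          start = 4L, end = 4L + nchar(shortForm),
          entity = shortForm, source = "abbreviation",
          corrupted = FALSE, stringsAsFactors = FALSE)
      }
      articles[[length(articles) + 1L]] <-
        newArticle(pmc, sections, tables, abbrevs)
    }
    sentences <- do.call(rbind, sentAll); rownames(sentences) <- NULL
    gold <- if (length(goldAll)) {
      g <- do.call(rbind, goldAll); rownames(g) <- NULL
      g[order(g$pmcid, g$sentence_id, g$start), ]
    } else data.frame(pmcid = character(0), sentence_id = character(0),
                      start = integer(0), end = integer(0),
                      entity = character(0), source = character(0),
                      corrupted = logical(0), stringsAsFactors = FALSE)
    rownames(gold) <- NULL
    list(articles = articles, sentences = sentences, gold = gold)
  })
}

#' Write an article fixture as Auto-CORPus-style JSON files
#'
#' Emits the maintext (paragraph records with IAO terms), table and
#' abbreviation JSON dialects that \code{\link{readArticle}} consumes.
#'
#' @param article an \linkS4class{Article}.
#' @param dir output directory.
#' @return named character vector of the three file paths.
#' @export
writeArticleJSON <- function(article, dir) {
  stopifnot(is(article, "Article"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paras <- list()
  for (sec in sections(article))
    for (sub in sec$subsections)
      paras[[length(paras) + 1L]] <- list(
        section_heading = sec$iao_term, subsection_heading = "",
        body = sub, IAO_term = sec$iao_term, IAO_ID = "IAO:0000000")
  mainPath <- file.path(dir, paste0(pmcid(article), "_maintext.json"))
  jsonlite::write_json(list(pmcid = pmcid(article), paragraphs = paras),
                       mainPath, auto_unbox = TRUE)
  tabPath <- file.path(dir, paste0(pmcid(article), "_tables.json"))
  jsonlite::write_json(list(tables = lapply(articleTables(article),
    function(tb) list(identifier = tb$identifier,
                      rows = lapply(tb$rows, as.list)))),
    tabPath, auto_unbox = TRUE)
  abbPath <- file.path(dir, paste0(pmcid(article), "_abbreviations.json"))
  jsonlite::write_json(list(abbreviations = as.list(
    abbreviations(article))), abbPath, auto_unbox = TRUE)
  c(maintext = mainPath, tables = tabPath, abbreviations = abbPath)
}

#' Generate a word-vector fixture file
#'
#' One line per token: token followed by \code{dim} floats, drawn
#' deterministically from the seed.
#'
#' @param vocab character vector of tokens.
#' @param dim vector width.
#' @param seed integer seed.
#' @param path output file.
#' @return the path, invisibly.
#' @export
makeWordVecFile <- function(vocab, dim = 300L, seed = 1L,
                            path = tempfile(fileext = ".vec")) {
  stopifnot(dim >= 1L)
  withSeed(deriveSeed(seed, 31L), {
    lines <- vapply(vocab, function(tok) {
      v <- stats::rnorm(dim) / sqrt(dim)
      paste(tok, paste(sprintf("%.6f", v), collapse = " "))
    }, character(1))
    writeLines(lines, path)
  })
  invisible(path)
}

#' Article-based train/validation/test split
#'
#' Random partition of article identifiers at the given ratios
#' (75:10:15 by default), deterministic per seed; counts are taken from
#' the data.
#'
#' @param article_ids character vector of ids.
#' @param ratios length-3 numeric summing to 1.
#' @param seed integer seed.
#' @return list(train, validation, test) of id vectors.
#' @export
splitArticles <- function(article_ids, ratios = c(0.75, 0.10, 0.15),
                          seed = 1L) {
  stopifnot(abs(sum(ratios) - 1) < 1e-9, length(ratios) == 3L)
  withSeed(deriveSeed(seed, 41L), {
    ids <- sample(article_ids)
    n <- length(ids)
    nTrain <- round(n * ratios[1])
    nVal <- round(n * ratios[2])
    list(train = ids[seq_len(nTrain)],
         validation = ids[nTrain + seq_len(min(nVal, n - nTrain))],
         test = ids[setdiff(seq_len(n), seq_len(nTrain + nVal))])
  })
}
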