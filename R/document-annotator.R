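# Apply an annotator (rule-based or model) to whole articles: A/M/R/D
# sentences, table cells treated as standalone sentences, and
# abbreviation linking.

#' Annotator closures
#'
#' Wrap the rule-based pipeline or a trained model as a uniform
#' annotator: a function \code{(sentence, fixups = TRUE) -> annotation
#' records} usable by \code{\link{annotateDocument}}.
#'
#' @param dict a \linkS4class{MetaboliteDictionary}.
#' @param pattern_set a \linkS4class{PatternSet} or NULL.
#' @param stopwords stopword list.
#' @return an annotator function.
#' @export
ruleAnnotator <- function(dict, pattern_set = defaultPatternSet(),
                          stopwords = defaultStopwords()) {
  function(sentence, fixups = TRUE)
    annotateSentence(sentence, dict, pattern_set = pattern_set,
                     stopwords = stopwords, fixups = fixups)
}

#' @rdname ruleAnnotator
#' @param model a trained \linkS4class{NERModel}.
#' @param embedder,preclassifier the model's backends.
#' @export
modelAnnotator <- function(model, embedder, preclassifier,
                           stopwords = defaultStopwords()) {
  function(sentence, fixups = TRUE)
    predictNer(model, sentence, embedder, preclassifier,
               stopwords = stopwords, fixups = fixups)
}

tableCellSentences <- function(article) {
  rows <- list()
  tabs <- articleTables(article)
  for (ti in seq_along(tabs)) {
    trows <- tabs[[ti]]$rows
    for (ri in seq_along(trows)) {
      cells <- trows[[ri]]
      for (ci in seq_along(cells)) {
        if (!nzchar(trimws(cells[ci]))) next
        rows[[length(rows) + 1L]] <- data.frame(
          pmcid = pmcid(article),
          sentence_id = sprintf("T%02dR%03dC%03d", ti - 1L, ri - 1L,
                                ci - 1L),
          section = "T", group = "T", text = cells[ci],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(pmcid = character(0), sentence_id = character(0),
                      section = character(0), group = character(0),
                      text = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

#' Annotate a whole article
#'
#' Runs the annotator over every A/M/R/D sentence and (optionally) over
#' every table cell as a standalone sentence. Table records carry
#' synthetic identifiers ("T" + table/row/column indices, 0-based) that
#' live outside the letter+5-digit sentence-ID space and are never
#' written to the corpus sentence file. Sources partition the records:
#' "text", "table" and (via \code{\link{linkAbbreviations}})
#' "abbreviation".
#'
#' @param article an \linkS4class{Article}.
#' @param annotator from \code{\link{ruleAnnotator}} or
#'   \code{\link{modelAnnotator}}.
#' @param include_tables annotate table cells.
#' @param include_abbreviations run abbreviation linking.
#' @param splitter sentence splitter.
#' @return annotation record data.frame with a source column.
#' @export
annotateDocument <- function(article, annotator, include_tables = TRUE,
                             include_abbreviations = TRUE,
                             splitter = defaultSentenceSplitter) {
  stopifnot(is(article, "Article"), is.function(annotator))
  sentences <- articleSentences(article, splitter)
  recs <- list(emptyAnnotations(character(0)))
  for (i in seq_len(nrow(sentences)))
    recs[[length(recs) + 1L]] <- annotator(sentences[i, , drop = FALSE])
  if (include_tables) {
    cells <- tableCellSentences(article)
    for (i in seq_len(nrow(cells))) {
      r <- annotator(cells[i, , drop = FALSE])
      if (nrow(r)) r$source <- "table"
      recs[[length(recs) + 1L]] <- r
    }
  }
  if (include_abbreviations && length(abbreviations(article)))
    recs[[length(recs) + 1L]] <-
      linkAbbreviations(abbreviations(article), annotator, sentences)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Link recognised abbreviation definitions to their short forms
#'
#' A short form is linked if and only if the annotator recognises the
#' ENTIRE definition as a single entity; the incomplete-entity fix-up
#' rules are not applied to definitions. Every case-sensitive
#' whole-word occurrence of a linked short form across the article's
#' A/M/R/D sentences becomes a record with source "abbreviation".
#'
#' @param abbrev_map named character vector short form -> definition.
#' @param annotator annotator closure (called with fixups disabled).
#' @param sentences sentence table of the article.
#' @return annotation record data.frame (source "abbreviation").
#' @export
linkAbbreviations <- function(abbrev_map, annotator, sentences) {
  out <- list(emptyAnnotations(character(0)))
  for (shortForm in names(abbrev_map)) {
    definition <- trimws(abbrev_map[[shortForm]])
    if (!nzchar(definition)) next
    recs <- annotator(definition, fixups = FALSE)
    whole <- nrow(recs) > 0 && any(recs$start == 0L &
                                   recs$end == nchar(definition))
    if (!whole) next
    pat <- paste0("(?<![A-Za-z0-9])", escapeRegex(shortForm),
                  "(?![A-Za-z0-9])")
    for (i in seq_len(nrow(sentences))) {
      m <- gregexpr(pat, sentences$text[i], perl = TRUE)[[1]]
      if (m[1] == -1L) next
      for (k in seq_along(m)) {
        out[[length(out) + 1L]] <- annotationRecords(
          pmcid = sentences$pmcid[i],
          sentence_id = sentences$sentence_id[i],
          start = m[k] - 1L,
          end = m[k] - 1L + attr(m, "match.length")[k],
          entity = shortForm, source = "abbreviation",
          sentence_text = sentences$text[i])
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collect per-article entity lists for network construction
#'
#' Filters records to the sections that feed the co-occurrence graph
#' (by default abstract, results — including tables — and discussion)
#' and returns the per-article entity vectors expected by
#' \code{\link{buildCooccurrenceGraph}}.
#'
#' @param records annotation records with source column.
#' @param sentences sentence table (pmcid, sentence_id, group) covering
#'   the text records.
#' @param groups section groups to keep.
#' @param include_tables keep table-sourced records.
#' @return named list pmcid -> character vector of entities.
#' @export
entitiesByArticle <- function(records, sentences,
                              groups = c("A", "R", "RD", "D"),
                              include_tables = TRUE) {
  src <- if ("source" %in% names(records)) records$source else
    rep("text", nrow(records))
  keep <- rep(FALSE, nrow(records))
  textRec <- src == "text"
  if (any(textRec)) {
    skey <- paste(sentences$pmcid, sentences$sentence_id, sep = "\r")
    idx <- match(paste(records$pmcid, records$sentence_id, sep = "\r"),
                 skey)
    keep[textRec] <- !is.na(idx[textRec]) &
      sentences$group[idx[textRec]] %in% groups
  }
  if (include_tables) keep <- keep | src == "table"
  sel <- records[keep, , drop = FALSE]
  split(sel$entity, sel$pmcid)
}
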