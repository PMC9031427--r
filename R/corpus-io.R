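# Reading Auto-CORPus-style article JSON, sentence splitting and
# identification, and the two corpus files (sentence text + annotation TSV).

# IAO term -> (sentence-ID code, evaluation group). Combined
# results-and-discussion sections carry code R (the ID alphabet has only
# A/M/R/D) but keep group RD for per-section evaluation.
iaoSectionCode <- function(iao_term) {
  t <- foldCase(trimws(iao_term))
  if (grepl("introduction", t)) return(NULL)
  if (grepl("abstract", t)) return(list(code = "A", group = "A"))
  if (grepl("method", t)) return(list(code = "M", group = "M"))
  if (grepl("results and discussion", t)) return(list(code = "R", group = "RD"))
  if (grepl("result", t)) return(list(code = "R", group = "R"))
  if (grepl("discussion", t)) return(list(code = "D", group = "D"))
  NULL
}

#' Construct an Article object
#'
#' Used by the fixture generator and by code assembling articles in
#' memory; \code{\link{readArticle}} is the file-based entry point.
#'
#' @param pmcid article identifier.
#' @param sections list of section records (code, group, iao_term,
#'   subsections).
#' @param tables list of table records (each with a \code{rows} list of
#'   character vectors).
#' @param abbreviations named character vector short form -> definition.
#' @return an \linkS4class{Article}.
#' @export
newArticle <- function(pmcid, sections = list(), tables = list(),
                       abbreviations = character()) {
  new("Article", pmcid = pmcid, sections = sections, tables = tables,
      abbreviations = abbreviations)
}

#' Read an Auto-CORPus-style article
#'
#' Parses the maintext JSON (paragraph records with
#' \code{section_heading}, \code{subsection_heading}, \code{body},
#' \code{IAO_term}, \code{IAO_ID}) plus optional table and abbreviation
#' JSON files. Sections are filtered by IAO term to abstract, methods,
#' results, discussion (and combined results-and-discussion);
#' introduction and any other section types are dropped. Consecutive
#' paragraphs with the same section code form one section whose ordered
#' subsections are the paragraph bodies.
#'
#' @param maintext_path path to the maintext JSON file.
#' @param table_path optional path to the table JSON file.
#' @param abbrev_path optional path to the abbreviation JSON file.
#' @return an \linkS4class{Article}.
#' @export
readArticle <- function(maintext_path, table_path = NULL,
                        abbrev_path = NULL) {
  if (!file.exists(maintext_path))
    stop("maintext file not found: ", maintext_path)
  doc <- tryCatch(jsonlite::fromJSON(maintext_path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed JSON in ", maintext_path, ": ",
                         conditionMessage(e)))
  paras <- if (!is.null(doc$paragraphs)) doc$paragraphs else doc
  pmcid <- if (!is.null(doc$pmcid)) as.character(doc$pmcid) else
    sub("_maintext.*$", "", basename(maintext_path))
  if (!length(paras)) stop("schema error in ", maintext_path,
                           ": no paragraphs found")
  sections <- list()
  cur <- NULL
  for (p in paras) {
    missing <- setdiff(c("body", "IAO_term"), names(p))
    if (length(missing))
      stop("schema error in ", maintext_path, ": missing key(s) ",
           paste(missing, collapse = ", "))
    sc <- iaoSectionCode(p$IAO_term)
    if (is.null(sc)) { cur <- NULL; next }
    if (!is.null(cur) && cur$code == sc$code && cur$group == sc$group) {
      cur$subsections <- c(cur$subsections, as.character(p$body))
      sections[[length(sections)]] <- cur
    } else {
      cur <- list(code = sc$code, group = sc$group,
                  iao_term = as.character(p$IAO_term),
                  subsections = as.character(p$body))
      sections[[length(sections) + 1L]] <- cur
    }
  }
  if (!length(sections))
    warning("no A/M/R/D sections found in ", maintext_path)

  tables <- list()
  if (!is.null(table_path) && file.exists(table_path)) {
    tdoc <- tryCatch(jsonlite::fromJSON(table_path, simplifyVector = FALSE),
                     error = function(e)
                       stop("malformed JSON in ", table_path, ": ",
                            conditionMessage(e)))
    tl <- if (!is.null(tdoc$tables)) tdoc$tables else tdoc
    tables <- lapply(tl, function(tb) {
      rows <- lapply(tb$rows, function(r)
        vapply(r, as.character, character(1)))
      list(identifier = if (!is.null(tb$identifier))
             as.character(tb$identifier) else NA_character_,
           rows = rows)
    })
  }

  abbrev <- character()
  if (!is.null(abbrev_path) && file.exists(abbrev_path)) {
    adoc <- tryCatch(jsonlite::fromJSON(abbrev_path, simplifyVector = FALSE),
                     error = function(e)
                       stop("malformed JSON in ", abbrev_path, ": ",
                            conditionMessage(e)))
    al <- if (!is.null(adoc$abbreviations)) adoc$abbreviations else adoc
    if (length(al)) {
      if (!is.null(names(al)) && all(nzchar(names(al)))) {
        abbrev <- vapply(al, as.character, character(1))
      } else {
        sf <- vapply(al, function(a)
          as.character(a$short_form %||% a$abbreviation), character(1))
        lf <- vapply(al, function(a)
          as.character(a$long_form %||% a$definition), character(1))
        abbrev <- stats::setNames(lf, sf)
      }
    }
  }
  newArticle(pmcid, sections, tables, abbrev)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default rule-based sentence splitter
#'
#' Splits a text block into sentence spans (0-based, end-exclusive).
#' Boundaries are runs of \code{.?!} followed by whitespace; a boundary
#' is suppressed when the preceding token is a common abbreviation
#' (e.g., i.e., vs., et al., Fig.) or a single letter/digit (initials,
#' decimal-adjacent). Any function with this signature (text ->
#' two-column matrix of start/end offsets) can replace it.
#'
#' @param text a character scalar.
#' @return integer matrix with columns start, end (0-based,
#'   end-exclusive), one row per sentence.
#' @export
defaultSentenceSplitter <- function(text) {
  n <- nchar(text)
  out <- NULL
  if (n == 0L || !nzchar(trimws(text)))
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  noSplit <- c("e.g", "i.e", "etc", "vs", "al", "fig", "figs", "ca",
               "approx", "no", "cf")
  m <- gregexpr("[.?!]+\\s+", text, perl = TRUE)[[1]]
  bounds <- integer(0)
  if (m[1] != -1L) {
    for (k in seq_along(m)) {
      pos <- m[k]                      # 1-based index of first punct char
      len <- attr(m, "match.length")[k]
      before <- substr(text, 1L, pos - 1L)
      lastTok <- sub("^.*\\s", "", before)
      lastTok <- sub("[.?!]+$", "", lastTok)
      if (foldCase(lastTok) %in% noSplit) next
      if (nchar(lastTok) == 1L && grepl("^[A-Za-z]$", lastTok)) next
      # end of sentence = end of the punctuation run (before whitespace)
      punctEnd <- pos
      while (punctEnd < n &&
             grepl("[.?!]", substr(text, punctEnd + 1L, punctEnd + 1L)))
        punctEnd <- punctEnd + 1L
      bounds <- c(bounds, punctEnd)
    }
  }
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  rows <- list()
  for (k in seq_along(starts)) {
    s <- starts[k]; e <- ends[k]
    while (s <= e && grepl("\\s", substr(text, s, s))) s <- s + 1L
    while (e >= s && grepl("\\s", substr(text, e, e))) e <- e - 1L
    if (s <= e) rows[[length(rows) + 1L]] <- c(s - 1L, e)
  }
  if (!length(rows))
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  mat <- do.call(rbind, rows)
  dimnames(mat) <- list(NULL, c("start", "end"))
  mat
}

#' Split an article into identified sentences
#'
#' Applies the sentence splitter to every subsection of every retained
#' section and assigns each sentence its structured identifier: the
#' section code letter followed by a 2-digit 0-based subsection index
#' and a 3-digit 0-based sentence index ("M01001" is the second sentence
#' of the second methods subsection).
#'
#' @param article an \linkS4class{Article}.
#' @param splitter a sentence splitter (see
#'   \code{\link{defaultSentenceSplitter}}).
#' @return data.frame with columns pmcid, sentence_id, section (ID code
#'   letter), group (evaluation group A/M/R/RD/D), text.
#' @export
articleSentences <- function(article, splitter = defaultSentenceSplitter) {
  stopifnot(is(article, "Article"))
  rows <- list()
  # subsection indices run per section code so IDs stay unique when a
  # code spans several section records (e.g. two R-coded sections)
  subIdx <- c(A = 0L, M = 0L, R = 0L, D = 0L)
  for (sec in sections(article)) {
    for (block in sec$subsections) {
      si <- subIdx[[sec$code]]
      if (si > 99L)
        stop("sentence-ID capacity exceeded: >100 subsections for code ",
             sec$code, " in ", pmcid(article))
      spans <- splitter(block)
      if (nrow(spans) > 1000L)
        stop("sentence-ID capacity exceeded: >1000 sentences in one ",
             "subsection of ", pmcid(article))
      if (nrow(spans)) {
        for (k in seq_len(nrow(spans))) {
          txt <- substr(block, spans[k, 1] + 1L, spans[k, 2])
          rows[[length(rows) + 1L]] <- data.frame(
            pmcid = pmcid(article),
            sentence_id = sprintf("%s%02d%03d", sec$code, si, k - 1L),
            section = sec$code, group = sec$group, text = txt,
            stringsAsFactors = FALSE)
        }
      }
      subIdx[[sec$code]] <- si + 1L
    }
  }
  if (!length(rows))
    return(data.frame(pmcid = character(0), sentence_id = character(0),
                      section = character(0), group = character(0),
                      text = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

annotTsvHeader <- c(
  "# metaboText annotation records",
  "# fields: PMCID<TAB>sentence_id<TAB>start<TAB>end<TAB>entity",
  "# offsets are 0-based character positions, end-exclusive")

#' Write the corpus sentence file and annotation TSV
#'
#' The sentence file holds one row per sentence that carries at least
#' one annotation (PMCID, sentence identifier, text; tab-separated).
#' The annotation TSV holds the 5 fields PMCID, sentence identifier,
#' start, end, entity with a comment header documenting the offset
#' convention (0-based, end-exclusive).
#'
#' @param sentences data.frame with pmcid, sentence_id, text.
#' @param annotations 5-field annotation data.frame.
#' @param out_text,out_tsv output paths.
#' @return invisibly, the number of sentences written.
#' @export
writeCorpusFiles <- function(sentences, annotations, out_text, out_tsv) {
  skey <- paste(sentences$pmcid, sentences$sentence_id)
  akey <- paste(annotations$pmcid, annotations$sentence_id)
  unknown <- setdiff(akey, skey)
  if (length(unknown))
    stop("annotation(s) reference unknown sentence(s): ",
         paste(utils::head(unknown, 3), collapse = "; "))
  keep <- skey %in% akey
  sel <- sentences[keep, , drop = FALSE]
  txtLines <- if (nrow(sel))
    paste(sel$pmcid, sel$sentence_id, sel$text, sep = "\t") else character(0)
  writeLines(txtLines, out_text)
  tsvLines <- annotTsvHeader
  if (nrow(annotations))
    tsvLines <- c(tsvLines,
                  paste(annotations$pmcid, annotations$sentence_id,
                        annotations$start, annotations$end,
                        annotations$entity, sep = "\t"))
  writeLines(tsvLines, out_tsv)
  invisible(nrow(sel))
}

#' Read the corpus sentence file and annotation TSV
#'
#' Inverse of \code{\link{writeCorpusFiles}}; tolerates comment lines
#' (\code{#}) in either file.
#'
#' @param text_path,tsv_path input paths.
#' @return list with elements \code{sentences} (pmcid, sentence_id,
#'   text) and \code{annotations} (5-field data.frame, source "text").
#' @export
readCorpusFiles <- function(text_path, tsv_path) {
  tl <- readLines(text_path, warn = FALSE)
  tl <- tl[!startsWith(tl, "#") & nzchar(tl)]
  sentences <- if (length(tl)) {
    parts <- strsplit(tl, "\t", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) < 3L
    if (any(bad)) stop("sentence file row(s) with <3 fields")
    data.frame(pmcid = vapply(parts, `[[`, "", 1),
               sentence_id = vapply(parts, `[[`, "", 2),
               text = vapply(parts, function(p)
                 paste(p[-(1:2)], collapse = "\t"), ""),
               stringsAsFactors = FALSE)
  } else data.frame(pmcid = character(0), sentence_id = character(0),
                    text = character(0), stringsAsFactors = FALSE)
  al <- readLines(tsv_path, warn = FALSE)
  al <- al[!startsWith(al, "#") & nzchar(al)]
  annotations <- if (length(al)) {
    parts <- strsplit(al, "\t", fixed = TRUE)
    if (any(vapply(parts, length, integer(1)) != 5L))
      stop("annotation TSV row(s) without exactly 5 fields")
    annotationRecords(
      pmcid = vapply(parts, `[[`, "", 1),
      sentence_id = vapply(parts, `[[`, "", 2),
      start = as.integer(vapply(parts, `[[`, "", 3)),
      end = as.integer(vapply(parts, `[[`, "", 4)),
      entity = vapply(parts, `[[`, "", 5))
  } else emptyAnnotations()
  skey <- paste(sentences$pmcid, sentences$sentence_id)
  akey <- paste(annotations$pmcid, annotations$sentence_id)
  if (length(setdiff(akey, skey)))
    stop("annotation(s) reference sentence(s) absent from the text file")
  list(sentences = sentences, annotations = annotations)
}
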