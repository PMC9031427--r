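# Rule-based annotation: dictionary matching, regex partial matching
# with word expansion, and the recursive post-processing fix-ups
# (adjacent-word extension, bracket balancing, overlap merging) run to a
# fixpoint.

#' Construct, read and write pattern sets
#'
#' A pattern set is an ordered list of PCRE expressions stored one per
#' line in a plain-text file (\code{#} comments and blank lines
#' ignored).
#'
#' @param patterns character vector of regular expressions.
#' @param name,version identifiers carried on the object.
#' @return a \linkS4class{PatternSet}.
#' @export
newPatternSet <- function(patterns, name = "custom", version = "0") {
  new("PatternSet", patterns = as.character(patterns), name = name,
      version = version)
}

#' @rdname newPatternSet
#' @param path file to read from / write to.
#' @export
readPatternSet <- function(path, name = basename(path), version = "0") {
  newPatternSet(readTermFile(path), name = name, version = version)
}

#' @rdname newPatternSet
#' @param ps a PatternSet to serialise.
#' @export
writePatternSet <- function(ps, path) {
  stopifnot(is(ps, "PatternSet"))
  writeLines(c(sprintf("# PatternSet %s (version %s)", ps@name, ps@version),
               patterns(ps)), path)
  invisible(path)
}

#' Default metabolite pattern set
#'
#' Regular expressions crafted against common metabolite morphology:
#' anion/sugar/amine/alcohol suffixes (-ate, -ose, -ine, -ol, -itol),
#' "-ic acid" forms, substituent prefixes (hydroxy-, methyl-, acetyl-,
#' phospho-, ...), acyl linkages and lipid shorthand such as
#' \code{PC(16:0/18:1)}. Partial matches are expanded to whole words by
#' \code{\link{regexMatchExpand}}. Fully user-replaceable; coverage of a
#' dictionary-derived reference set can be measured with
#' \code{\link{patternCoverage}} to craft new expressions recursively.
#'
#' @return a \linkS4class{PatternSet}.
#' @export
defaultPatternSet <- function() {
  newPatternSet(c(
    "[A-Za-z]{3,}(ate|ates)\\b",
    "[A-Za-z]{3,}(ose|uloses?|itol)\\b",
    "[A-Za-z]{4,}ines?\\b",
    "[A-Za-z]{4,}(ol|ols)\\b",
    "[A-Za-z]{3,}(ic|oic)\\s+acids?\\b",
    "(hydroxy|methyl|acetyl|phospho|amino|glycero|sphingo|desmethyl|dehydro|deoxy|keto)-",
    "[A-Za-z]{3,}yl-[A-Za-z]",
    "\\b[A-Z]{2,4}\\(\\d+:\\d+(/\\d+:\\d+)*\\)?",
    "\\d+-(hydroxy|methyl|amino|oxo|keto)"
  ), name = "metabolite-morphology", version = "1")
}

#' Default English stopword list
#'
#' Small fixed list used by the adjacent-word extension rules: a
#' neighbouring word that is a stopword is never absorbed into an
#' entity. Versioned with the package; user-replaceable.
#'
#' @return character vector (case-folded).
#' @export
defaultStopwords <- function() {
  c("a", "an", "the", "and", "or", "but", "of", "in", "on", "at", "to",
    "from", "by", "with", "for", "as", "is", "are", "was", "were", "be",
    "been", "that", "this", "these", "those", "we", "our", "their",
    "its", "it", "than", "then", "when", "while", "between", "during",
    "after", "before", "both", "all", "each", "per", "not", "no",
    "into", "within", "using", "about", "also", "such", "other",
    "which", "where", "has", "have", "had", "can", "may", "more",
    "most", "less", "least", "very", "only", "there", "here")
}

escapeRegex <- function(x)
  gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", x)

# gregexpr with a guard against runaway patterns: a per-pattern time
# limit plus the PCRE match-limit diagnostics (catastrophic
# backtracking). Returns NULL with a warning when the pattern is
# skipped.
guardedMatch <- function(pattern, text, timeout = 1) {
  on.exit(setTimeLimit(cpu = Inf, elapsed = Inf, transient = FALSE),
          add = TRUE)
  setTimeLimit(cpu = timeout, elapsed = timeout, transient = TRUE)
  skip <- function(cond) {
    warning("pattern skipped (", trimws(conditionMessage(cond)), "): ",
            pattern, call. = FALSE)
    NULL
  }
  tryCatch(gregexpr(pattern, text, perl = TRUE, ignore.case = TRUE)[[1]],
           error = skip, warning = skip)
}

emptySpans <- function()
  data.frame(start = integer(0), end = integer(0),
             source = character(0), stringsAsFactors = FALSE)

# Drop spans strictly contained in another span (longest-match-first
# resolution of nested dictionary candidates).
dropContained <- function(spans) {
  if (nrow(spans) < 2L) return(spans)
  keep <- rep(TRUE, nrow(spans))
  for (i in seq_len(nrow(spans))) {
    for (j in seq_len(nrow(spans))) {
      if (i == j || !keep[i]) next
      if (spans$start[j] <= spans$start[i] && spans$end[i] <= spans$end[j] &&
          (spans$end[j] - spans$start[j]) > (spans$end[i] - spans$start[i]))
        keep[i] <- FALSE
    }
  }
  spans[keep, , drop = FALSE]
}

#' Dictionary matching within one sentence
#'
#' Finds all case-insensitive occurrences of dictionary entries at word
#' boundaries (letters, digits and hyphens count as word characters, so
#' "glucose" is not found inside "glucoses" or "d-glucose", but is found
#' before a comma or inside brackets). Candidates nested inside a longer
#' candidate are resolved longest-match-first.
#'
#' @param sentence_text character scalar.
#' @param dict a \linkS4class{MetaboliteDictionary}.
#' @return data.frame of spans (start, end 0-based end-exclusive,
#'   source = "dictionary").
#' @export
dictionaryMatch <- function(sentence_text, dict) {
  stopifnot(is(dict, "MetaboliteDictionary"))
  out <- emptySpans()
  for (entry in dictEntries(dict)) {
    pat <- paste0("(?<![A-Za-z0-9-])", escapeRegex(entry),
                  "(?![A-Za-z0-9-])")
    m <- gregexpr(pat, sentence_text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    for (k in seq_along(m)) {
      out <- rbind(out, data.frame(
        start = m[k] - 1L,
        end = m[k] - 1L + attr(m, "match.length")[k],
        source = "dictionary", stringsAsFactors = FALSE))
    }
  }
  out <- unique(out)
  out <- dropContained(out)
  out[order(out$start, out$end), , drop = FALSE]
}

# trim leading/trailing sentence punctuation (never brackets, hyphens
# or colons, which are part of chemical names)
trimSpanPunct <- function(text, start, end) {
  punct <- c(".", ",", ";", "!", "?", "\"", "'")
  while (end - start > 1L &&
         substr(text, end, end) %in% punct) end <- end - 1L
  while (end - start > 1L &&
         substr(text, start + 1L, start + 1L) %in% punct)
    start <- start + 1L
  c(start, end)
}

#' Regular-expression matching with word expansion
#'
#' Applies each pattern to the sentence; every (partial) match is
#' expanded to the full whitespace-delimited word(s) it touches, then
#' stripped of trailing sentence punctuation. Spans are deduplicated.
#' Each pattern runs under a time budget; a pattern that exceeds it
#' (catastrophic backtracking) is skipped with a warning.
#'
#' @param sentence_text character scalar.
#' @param patterns a \linkS4class{PatternSet} or character vector.
#' @param timeout per-pattern time budget in seconds.
#' @return data.frame of spans (source = "regex").
#' @export
regexMatchExpand <- function(sentence_text, patterns, timeout = 1) {
  pats <- if (is(patterns, "PatternSet")) patterns(patterns) else
    as.character(patterns)
  out <- emptySpans()
  n <- nchar(sentence_text)
  for (p in pats) {
    m <- guardedMatch(p, sentence_text, timeout)
    if (is.null(m) || m[1] == -1L) next
    for (k in seq_along(m)) {
      s1 <- m[k]                                  # 1-based match start
      e1 <- m[k] + attr(m, "match.length")[k] - 1L
      if (e1 < s1) next                           # zero-length match
      ws <- wordExtent(sentence_text, s1)
      we <- wordExtent(sentence_text, min(e1, n))
      if (is.null(ws) || is.null(we)) next
      sp <- trimSpanPunct(sentence_text, ws[1] - 1L, we[2])
      out <- rbind(out, data.frame(start = sp[1], end = sp[2],
                                   source = "regex",
                                   stringsAsFactors = FALSE))
    }
  }
  out <- unique(out)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Adjacent-word extension of an entity span
#'
#' The word before the entity is prepended when it is not a stopword and
#' one of the rules holds: the preceding word ends with a hyphen, the
#' preceding word ends with a digit, the entity starts with a comma
#' followed by a digit, or the entity's first word starts with a hyphen.
#' The word after the entity is appended under the mirrored rules (the
#' entity now plays the "preceding word" role) plus one extra rule: the
#' next word is one of "acid", "isomer", "ester", "ether". Applied
#' recursively until no rule fires.
#'
#' @param start,end 0-based end-exclusive span offsets.
#' @param sentence_text character scalar.
#' @param stopwords case-folded stopword list.
#' @return integer vector c(start, end) of the extended span.
#' @export
extendAdjacent <- function(start, end, sentence_text,
                           stopwords = defaultStopwords()) {
  followers <- c("acid", "isomer", "ester", "ether")
  repeat {
    changed <- FALSE
    entity <- substr(sentence_text, start + 1L, end)
    firstWord <- sub("\\s.*$", "", entity)
    prev <- adjacentWord(sentence_text, start, end, "before")
    if (!is.null(prev) && !foldCase(prev$text) %in% stopwords) {
      if (grepl("-$", prev$text) || grepl("[0-9]$", prev$text) ||
          grepl("^,[0-9]", entity) || grepl("^-", firstWord)) {
        start <- prev$start
        changed <- TRUE
      }
    }
    entity <- substr(sentence_text, start + 1L, end)
    lastWord <- sub("^.*\\s", "", entity)
    nxt <- adjacentWord(sentence_text, start, end, "after")
    if (!is.null(nxt) && !foldCase(nxt$text) %in% stopwords) {
      nxtClean <- foldCase(sub("[.,;!?]+$", "", nxt$text))
      if (grepl("-$", lastWord) || grepl("[0-9]$", lastWord) ||
          grepl("^,[0-9]", nxt$text) || grepl("^-", nxt$text) ||
          nxtClean %in% followers) {
        # never absorb trailing sentence punctuation of the next word
        newEnd <- nxt$end
        sp <- trimSpanPunct(sentence_text, start, newEnd)
        if (sp[2] > end) { end <- sp[2]; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  c(start, end)
}

#' Balance brackets in an entity string
#'
#' For each bracket type (round, square, curly): when one side is
#' missing, the entity is enclosed by the corresponding missing
#' bracket(s) — unmatched opening brackets get closers appended,
#' unmatched closing brackets get openers prepended. Balanced input is
#' returned unchanged.
#'
#' @param entity_text character scalar, non-empty.
#' @return the balanced entity string.
#' @export
balanceBrackets <- function(entity_text) {
  stopifnot(nzchar(entity_text))
  pairs <- list(c("(", ")"), c("[", "]"), c("{", "}"))
  out <- entity_text
  for (p in pairs) {
    no <- lengths(regmatches(out, gregexpr(p[1], out, fixed = TRUE)))
    nc <- lengths(regmatches(out, gregexpr(p[2], out, fixed = TRUE)))
    if (no > nc) out <- paste0(out, strrep(p[2], no - nc))
    if (nc > no) out <- paste0(strrep(p[1], nc - no), out)
  }
  out
}

#' Merge overlapping or whitespace-separated spans
#'
#' Computes the transitive closure of the merge relation: two spans are
#' merged when they overlap, touch, or are separated only by whitespace.
#' The result is sorted by start and contains no two spans that overlap
#' or have a whitespace-only gap.
#'
#' @param spans data.frame with start, end (0-based end-exclusive).
#' @param sentence_text the sentence the spans index into.
#' @return merged span data.frame (source = "merged" where spans were
#'   combined, original source otherwise).
#' @export
mergeSpans <- function(spans, sentence_text) {
  if (!nrow(spans)) return(emptySpans())
  if (!"source" %in% names(spans)) spans$source <- "unknown"
  spans <- spans[order(spans$start, spans$end), , drop = FALSE]
  res <- spans[1, , drop = FALSE]
  for (i in seq_len(nrow(spans))[-1]) {
    last <- nrow(res)
    gapStart <- res$end[last]          # 0-based exclusive end
    gapEnd <- spans$start[i]
    mergeable <- if (gapEnd <= gapStart) TRUE else
      grepl("^\\s+$", substr(sentence_text, gapStart + 1L, gapEnd))
    if (mergeable) {
      if (spans$end[i] > res$end[last]) {
        if (spans$start[i] > res$start[last] ||
            spans$end[i] > res$end[last])
          res$source[last] <- if (identical(res$source[last],
                                            spans$source[i]))
            res$source[last] else "merged"
        res$end[last] <- spans$end[i]
      }
    } else {
      res <- rbind(res, spans[i, , drop = FALSE])
    }
  }
  rownames(res) <- NULL
  res
}

#' Recursive post-processing fix-ups on a span set
#'
#' Applies adjacent-word extension, bracket balancing (extending the
#' span only when the missing bracket is the adjacent sentence
#' character; otherwise the fix would be virtual and the span is left
#' unchanged so entities remain substrings) and merging of
#' overlapping/whitespace-separated spans, repeating the sequence until
#' the span set reaches a fixpoint. Shared by the rule-based annotator
#' and the sequence-labeller post-processing.
#'
#' @param spans span data.frame (start, end, source).
#' @param sentence_text the sentence.
#' @param stopwords case-folded stopword list.
#' @param max_iter recursion guard.
#' @return the post-processed span data.frame.
#' @export
postProcessSpans <- function(spans, sentence_text,
                             stopwords = defaultStopwords(),
                             max_iter = 20L) {
  text <- sentence_text
  if (!nrow(spans)) return(spans)
  it <- 0L
  repeat {
    before <- spans[, c("start", "end")]
    # adjacent-word extension
    for (i in seq_len(nrow(spans))) {
      sp <- extendAdjacent(spans$start[i], spans$end[i], text, stopwords)
      if (sp[1] != spans$start[i] || sp[2] != spans$end[i]) {
        spans$start[i] <- sp[1]; spans$end[i] <- sp[2]
        spans$source[i] <- "extended"
      }
    }
    # bracket balancing with span extension where the sentence allows
    for (i in seq_len(nrow(spans))) {
      ent <- substr(text, spans$start[i] + 1L, spans$end[i])
      fixed <- balanceBrackets(ent)
      if (nchar(fixed) > nchar(ent)) {
        nPre <- regexpr(ent, fixed, fixed = TRUE) - 1L
        nApp <- nchar(fixed) - nchar(ent) - nPre
        if (nPre > 0L && spans$start[i] - nPre >= 0L &&
            substr(text, spans$start[i] - nPre + 1L, spans$start[i]) ==
              substr(fixed, 1L, nPre))
          spans$start[i] <- spans$start[i] - nPre
        if (nApp > 0L && spans$end[i] + nApp <= nchar(text) &&
            substr(text, spans$end[i] + 1L, spans$end[i] + nApp) ==
              substr(fixed, nchar(fixed) - nApp + 1L, nchar(fixed)))
          spans$end[i] <- spans$end[i] + nApp
        # otherwise: virtual fix; span (and entity) left unchanged
      }
    }
    spans <- mergeSpans(spans, text)
    spans <- dropContained(unique(spans))
    if (identical(before, spans[, c("start", "end")])) break
    it <- it + 1L
    if (it >= max_iter)
      stop("fix-up recursion did not converge for sentence: ",
           substr(text, 1, 60))
  }
  spans
}

#' Annotate one sentence with the rule-based pipeline
#'
#' Runs dictionary matching and regex matching with word expansion, then
#' the post-processing fix-ups — adjacent-word extension, bracket
#' balancing (the span is extended only when the missing bracket is the
#' adjacent sentence character, so entities always remain substrings),
#' and merging of overlapping or whitespace-separated entities —
#' recursively until the span set no longer changes.
#'
#' @param sentence a character scalar, or a 1-row sentence data.frame
#'   with pmcid, sentence_id, text.
#' @param dict a \linkS4class{MetaboliteDictionary}.
#' @param pattern_set a \linkS4class{PatternSet}
#'   (\code{\link{defaultPatternSet}} by default); \code{NULL} disables
#'   regex matching.
#' @param stopwords case-folded stopword list.
#' @param fixups apply the post-processing fix-ups (disable for raw
#'   matching, e.g. abbreviation-definition checks).
#' @param max_iter recursion guard on the fixpoint loop.
#' @return annotation record data.frame (pmcid, sentence_id, start, end,
#'   entity, source).
#' @export
annotateSentence <- function(sentence, dict,
                             pattern_set = defaultPatternSet(),
                             stopwords = defaultStopwords(),
                             fixups = TRUE, max_iter = 20L) {
  if (is.character(sentence)) {
    text <- sentence
    pmcid <- NA_character_; sid <- NA_character_
  } else {
    text <- sentence$text[1]
    pmcid <- sentence$pmcid[1]; sid <- sentence$sentence_id[1]
  }
  spans <- rbind(dictionaryMatch(text, dict),
                 if (!is.null(pattern_set))
                   regexMatchExpand(text, pattern_set) else emptySpans())
  spans <- dropContained(unique(spans))
  if (fixups && nrow(spans))
    spans <- postProcessSpans(spans, text, stopwords, max_iter)
  if (!nrow(spans)) return(emptyAnnotations(character(0)))
  annotationRecords(pmcid = pmcid, sentence_id = sid,
                    start = spans$start, end = spans$end,
                    entity = substr(rep(text, nrow(spans)),
                                    spans$start + 1L, spans$end),
                    source = "text")
}

#' Annotate a sentence table with the rule-based pipeline
#'
#' @param sentences sentence data.frame (pmcid, sentence_id, text).
#' @param ... passed to \code{\link{annotateSentence}}.
#' @inheritParams annotateSentence
#' @return combined annotation record data.frame.
#' @export
annotateCorpus <- function(sentences, dict, ...) {
  out <- lapply(seq_len(nrow(sentences)), function(i)
    annotateSentence(sentences[i, , drop = FALSE], dict, ...))
  res <- do.call(rbind, c(list(emptyAnnotations(character(0))), out))
  rownames(res) <- NULL
  res
}
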