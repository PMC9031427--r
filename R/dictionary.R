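# Metabolite dictionary loading, cleaning, the regex reference set and
# pattern-coverage measurement.

#' Load a metabolite dictionary
#'
#' Reads a CSV/TSV file with columns \code{name}, \code{synonyms} (a
#' \code{|}- or \code{;}-separated list, possibly empty) and
#' \code{status}, keeps only entries whose status is allowed (HMDB-style
#' classes; by default the experimentally supported "quantified" and
#' "detected"), and expands synonyms into entries of their own carrying
#' the parent's status. The delimiter is autodetected from the header
#' line.
#'
#' @param path dictionary file.
#' @param statuses statuses to retain.
#' @param whitelist case-folded short entries exempt from cleaning.
#' @return a \linkS4class{MetaboliteDictionary}.
#' @export
loadDictionary <- function(path,
                           statuses = c("quantified", "detected"),
                           whitelist = character()) {
  header <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", fill = TRUE)
  names(tab) <- foldCase(names(tab))
  if (!"status" %in% names(tab))
    stop("schema error: dictionary file has no 'status' column")
  if (!"name" %in% names(tab))
    stop("schema error: dictionary file has no 'name' column")
  synCol <- intersect(c("synonyms", "synonym"), names(tab))[1]
  entries <- character(); status <- character()
  for (i in seq_len(nrow(tab))) {
    st <- foldCase(trimws(tab$status[i]))
    if (!st %in% statuses) next
    forms <- trimws(tab$name[i])
    if (!is.na(synCol) && !is.na(tab[[synCol]][i])) {
      syns <- trimws(strsplit(as.character(tab[[synCol]][i]),
                              "[|;]")[[1]])
      syns <- syns[!is.na(syns) & nzchar(syns)]
      forms <- c(forms, syns)
    }
    forms <- forms[!is.na(forms) & nzchar(forms)]
    keep <- !foldCase(forms) %in% foldCase(entries)
    entries <- c(entries, forms[keep])
    status <- c(status, rep(st, sum(keep)))
  }
  if (!length(entries))
    warning("dictionary is empty after status filtering")
  newDictionary(entries, status, whitelist = foldCase(whitelist))
}

#' Construct a MetaboliteDictionary from vectors
#'
#' @param entries surface strings (case preserved, case-folded-unique).
#' @param status one status per entry (recycled if scalar).
#' @param whitelist case-folded short entries exempt from cleaning.
#' @param removed optional log of removed entries.
#' @return a \linkS4class{MetaboliteDictionary}.
#' @export
newDictionary <- function(entries, status = "detected",
                          whitelist = character(), removed = character()) {
  entries <- as.character(entries)
  dup <- duplicated(foldCase(entries))
  entries <- entries[!dup]
  status <- rep_len(as.character(status), length(entries) + sum(dup))[!dup]
  new("MetaboliteDictionary", entries = entries,
      status = stats::setNames(status, entries),
      whitelist = foldCase(whitelist), removed = removed)
}

#' Default blocklist of non-specific dictionary synonyms
#'
#' Common English words that appear in metabolite databases as synonyms
#' (e.g. "result" is a synonym of omeprazole) and would flood any corpus
#' with false positives. A starter list; fully user-replaceable.
#'
#' @return character vector (case-folded).
#' @export
defaultBlocklist <- function() {
  c("result", "results", "retinal", "silica", "water", "lead", "iron",
    "gold", "media", "medium", "target", "product", "factor", "base")
}

#' Clean a dictionary
#'
#' Removes short ambiguous entries (length at most \code{max_ambig_len}
#' characters, unless whitelisted) and entries on the blocklist.
#' Idempotent; removed entries are logged on the returned object.
#'
#' @param dict a \linkS4class{MetaboliteDictionary}.
#' @param blocklist case-folded terms to drop
#'   (\code{\link{defaultBlocklist}} by default).
#' @param max_ambig_len maximum length of an entry treated as an
#'   ambiguous abbreviation (default 5).
#' @return the cleaned \linkS4class{MetaboliteDictionary}.
#' @export
cleanDictionary <- function(dict, blocklist = defaultBlocklist(),
                            max_ambig_len = 5L) {
  stopifnot(is(dict, "MetaboliteDictionary"))
  e <- dictEntries(dict)
  fold <- foldCase(e)
  drop <- (nchar(e) <= max_ambig_len & !fold %in% dict@whitelist) |
    fold %in% foldCase(blocklist)
  new("MetaboliteDictionary",
      entries = e[!drop],
      status = dict@status[e[!drop]],
      whitelist = dict@whitelist,
      removed = unique(c(dict@removed, e[drop])))
}

#' Build the regex reference set
#'
#' Selects the dictionary entries containing at least one space, hyphen
#' or colon — the less trivial names that regular expressions are
#' crafted against (singletons are assumed to be covered by the
#' dictionary itself).
#'
#' @param dict a \linkS4class{MetaboliteDictionary}.
#' @return character vector of reference terms.
#' @export
buildReferenceSet <- function(dict) {
  stopifnot(is(dict, "MetaboliteDictionary"))
  e <- dictEntries(dict)
  e[grepl("[ :-]", e)]
}

#' Measure pattern coverage of a reference set
#'
#' Fraction of reference terms with at least one partial match from the
#' pattern set, plus the uncovered terms — the working quantity of the
#' recursive pattern-crafting workflow (add or augment expressions while
#' uncovered terms still show an observable pattern).
#'
#' @param patterns a \linkS4class{PatternSet}, or character vector of
#'   regular expressions.
#' @param reference_set character vector of reference terms.
#' @return list with \code{coverage} (fraction in [0,1]),
#'   \code{covered}, \code{uncovered}.
#' @export
patternCoverage <- function(patterns, reference_set) {
  pats <- if (is(patterns, "PatternSet")) patterns(patterns) else
    as.character(patterns)
  for (p in pats) {
    ok <- tryCatch({ suppressWarnings(grepl(p, "", perl = TRUE)); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("pattern does not compile: ", p)
  }
  if (!length(reference_set))
    return(list(coverage = NA_real_, covered = character(0),
                uncovered = character(0)))
  hit <- rep(FALSE, length(reference_set))
  for (p in pats)
    hit <- hit | grepl(p, reference_set, perl = TRUE, ignore.case = TRUE)
  list(coverage = mean(hit),
       covered = reference_set[hit],
       uncovered = reference_set[!hit])
}
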