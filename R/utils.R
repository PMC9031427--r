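# Internal helpers shared across modules.

# Empty annotation-record data.frame with the canonical 5 fields (+source).
emptyAnnotations <- function(source = character(0)) {
  data.frame(pmcid = character(0), sentence_id = character(0),
             start = integer(0), end = integer(0),
             entity = character(0), source = source,
             stringsAsFactors = FALSE)
}

#' Assemble annotation records
#'
#' Builds the canonical 5-field annotation record table (PMCID, sentence
#' identifier, 0-based start offset, end-exclusive offset, entity text)
#' from parallel vectors, checking the span invariants against the
#' sentence text when supplied.
#'
#' @param pmcid,sentence_id,start,end,entity parallel vectors.
#' @param source record provenance: "text", "table" or "abbreviation".
#' @param sentence_text optional sentence string(s) to validate the
#'   entity/substring invariant against.
#' @return data.frame with columns pmcid, sentence_id, start, end,
#'   entity, source.
#' @export
annotationRecords <- function(pmcid, sentence_id, start, end, entity,
                              source = "text", sentence_text = NULL) {
  df <- data.frame(pmcid = as.character(pmcid),
                   sentence_id = as.character(sentence_id),
                   start = as.integer(start), end = as.integer(end),
                   entity = as.character(entity),
                   source = source, stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start < 0L) || any(df$start >= df$end))
      stop("annotation offsets must satisfy 0 <= start < end")
    if (!is.null(sentence_text)) {
      got <- substr(rep_len(sentence_text, nrow(df)),
                    df$start + 1L, df$end)
      if (!all(got == df$entity))
        stop("entity text does not equal its sentence substring")
    }
  }
  df
}

# Case folding used for every dictionary/entity identity decision.
foldCase <- function(x) tolower(x)

# Stable short hash of a character vector (content fingerprint for
# model metadata); polynomial hash over the concatenated strings.
contentHash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = ""))
  h <- 21661
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Derive a stream-specific 31-bit seed from a base seed.
deriveSeed <- function(seed, stream) {
  (as.integer(seed) * 2654435761 + stream * 97) %% .Machine$integer.max
}

# Word-extent helpers: a "word" is a maximal run of non-whitespace.
wordExtent <- function(text, pos) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (pos < 1L || pos > n || grepl("\\s", chars[pos])) return(NULL)
  s <- pos
  while (s > 1L && !grepl("\\s", chars[s - 1L])) s <- s - 1L
  e <- pos
  while (e < n && !grepl("\\s", chars[e + 1L])) e <- e + 1L
  c(s, e)  # 1-based inclusive
}

# Preceding / following whitespace-delimited word relative to a 0-based,
# end-exclusive span; returns list(start, end, text) in 0-based
# end-exclusive coordinates, or NULL.
adjacentWord <- function(text, start, end, side = c("before", "after")) {
  side <- match.arg(side)
  n <- nchar(text)
  if (side == "before") {
    i <- start               # 1-based index of char just before span is `start`
    while (i >= 1L && grepl("\\s", substr(text, i, i))) i <- i - 1L
    if (i < 1L) return(NULL)
    ext <- wordExtent(text, i)
    if (is.null(ext)) return(NULL)
    list(start = ext[1] - 1L, end = ext[2], text = substr(text, ext[1], ext[2]))
  } else {
    i <- end + 1L            # 1-based index of char just after span
    while (i <= n && grepl("\\s", substr(text, i, i))) i <- i + 1L
    if (i > n) return(NULL)
    ext <- wordExtent(text, i)
    if (is.null(ext)) return(NULL)
    list(start = ext[1] - 1L, end = ext[2], text = substr(text, ext[1], ext[2]))
  }
}

# read a one-term-per-line text file, '#' comments allowed
readTermFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
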