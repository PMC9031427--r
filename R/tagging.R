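# Tokenisation contracts and BIOES encoding/decoding between character
# spans and token sequences.

tokenizerEnv <- new.env(parent = emptyenv())

#' Register a tokenizer backend
#'
#' Tokenizers are looked up by id. A backend is a function
#' \code{text -> data.frame(text, start, end)} with 0-based,
#' end-exclusive character offsets; every token's text must equal its
#' offset substring.
#'
#' @param id tokenizer identifier.
#' @param fun backend function.
#' @export
registerTokenizer <- function(id, fun) {
  stopifnot(is.character(id), is.function(fun))
  assign(id, fun, envir = tokenizerEnv)
  invisible(id)
}

emptyTokens <- function()
  data.frame(text = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)

# chemistry-aware word tokenizer: whitespace split, then peel sentence
# punctuation off token edges while keeping hyphens, digits, colons and
# balanced brackets inside chemistry-like tokens ("PC(16:0/18:1)",
# "4-hydroxy-N-desmethyltamoxifen", "2.5" stay whole).
chemWordTokenize <- function(text) {
  out <- emptyTokens()
  if (!nzchar(text)) return(out)
  m <- gregexpr("\\S+", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(out)
  punct <- c(".", ",", ";", ":", "!", "?", "\"", "'")
  openB <- c("(", "[", "{"); closeB <- c(")", "]", "}")
  bracketBalance <- function(s, type) {
    o <- lengths(regmatches(s, gregexpr(openB[type], s, fixed = TRUE)))
    c <- lengths(regmatches(s, gregexpr(closeB[type], s, fixed = TRUE)))
    o - c
  }
  rows <- list()
  emit <- function(s, e) {             # 1-based inclusive char range
    rows[[length(rows) + 1L]] <<- data.frame(
      text = substr(text, s, e), start = s - 1L, end = e,
      stringsAsFactors = FALSE)
  }
  for (k in seq_along(m)) {
    s <- m[k]; e <- m[k] + attr(m, "match.length")[k] - 1L
    repeat {
      if (s > e) break
      chunk <- substr(text, s, e)
      first <- substr(chunk, 1, 1); last <- substr(chunk, nchar(chunk),
                                                   nchar(chunk))
      if (first %in% punct && !(first == "." && grepl("^\\.[0-9]", chunk))) {
        emit(s, s); s <- s + 1L; next
      }
      ti <- match(first, openB)
      if (!is.na(ti) && bracketBalance(chunk, ti) > 0L) {
        emit(s, s); s <- s + 1L; next
      }
      if (last %in% punct) {
        emit(e, e); e <- e - 1L; next
      }
      ti <- match(last, closeB)
      if (!is.na(ti) && bracketBalance(chunk, ti) < 0L) {
        emit(e, e); e <- e - 1L; next
      }
      break
    }
    if (s <= e) emit(s, e)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# synthetic subword backend: splits each chemistry token further at
# hyphens, digit runs and brackets, approximating the smaller-than-word
# token sequences a transformer tokenizer produces. A real subword
# backend can replace it via registerTokenizer("subword", ...).
syntheticSubwordTokenize <- function(text) {
  words <- chemWordTokenize(text)
  if (!nrow(words)) return(emptyTokens())
  rows <- list()
  for (i in seq_len(nrow(words))) {
    w <- words$text[i]
    m <- gregexpr("[0-9]+|[A-Za-z]+|[^A-Za-z0-9]", w, perl = TRUE)[[1]]
    for (k in seq_along(m)) {
      s <- m[k]; len <- attr(m, "match.length")[k]
      rows[[length(rows) + 1L]] <- data.frame(
        text = substr(w, s, s + len - 1L),
        start = words$start[i] + s - 1L,
        end = words$start[i] + s + len - 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tokenize a sentence
#'
#' Dispatches to a registered tokenizer backend. The package registers
#' \code{chem_word} (whitespace split followed by punctuation peeling
#' that keeps hyphens, digits, colons and balanced brackets inside
#' chemistry-like tokens) and \code{subword} (a synthetic stand-in
#' splitting further at hyphen/digit/bracket boundaries; replace it with
#' a real transformer tokenizer via \code{\link{registerTokenizer}}).
#'
#' @param text character scalar.
#' @param tokenizer_id backend id.
#' @return data.frame(text, start, end); offsets 0-based end-exclusive.
#' @export
tokenize <- function(text, tokenizer_id = "chem_word") {
  if (!exists(tokenizer_id, envir = tokenizerEnv))
    stop("unknown tokenizer: ", tokenizer_id)
  get(tokenizer_id, envir = tokenizerEnv)(text)
}

#' Encode character spans as BIOES labels
#'
#' Single-token entities become S; multi-token entities B (I ...) E; all
#' other tokens O. Spans must be disjoint and aligned to token
#' boundaries; misalignment raises an error by default or snaps the
#' span to the covering tokens with a warning.
#'
#' @param tokens token data.frame from \code{\link{tokenize}}.
#' @param spans data.frame with start, end (0-based end-exclusive).
#' @param on_misaligned "error" or "snap".
#' @return character vector of labels over \code{\link{BIOES_LABELS}}.
#' @export
spansToBioes <- function(tokens, spans, on_misaligned = c("error", "snap")) {
  on_misaligned <- match.arg(on_misaligned)
  labels <- rep("O", nrow(tokens))
  if (is.null(spans) || !nrow(spans)) return(labels)
  spans <- spans[order(spans$start), , drop = FALSE]
  if (any(spans$start[-1] < spans$end[-nrow(spans)]))
    stop("spans must be disjoint")
  for (i in seq_len(nrow(spans))) {
    covered <- which(tokens$start < spans$end[i] &
                     tokens$end > spans$start[i])
    if (!length(covered))
      stop("span [", spans$start[i], ",", spans$end[i],
           ") covers no token")
    aligned <- tokens$start[covered[1]] == spans$start[i] &&
      tokens$end[covered[length(covered)]] == spans$end[i]
    if (!aligned) {
      if (on_misaligned == "error")
        stop("span [", spans$start[i], ",", spans$end[i],
             ") is not aligned to token boundaries")
      warning("span snapped to token boundaries: [", spans$start[i],
              ",", spans$end[i], ")")
    }
    if (length(covered) == 1L) {
      labels[covered] <- "S"
    } else {
      labels[covered[1]] <- "B"
      labels[covered[length(covered)]] <- "E"
      mid <- covered[-c(1, length(covered))]
      labels[mid] <- "I"
    }
  }
  labels
}

#' Decode BIOES labels (or probability rows) to character spans
#'
#' Takes hard labels or a per-token probability matrix (columns in
#' \code{\link{BIOES_LABELS}} order; argmax is applied), repairs illegal
#' transitions, and emits one span per S token or B..E block. Repair
#' policies: \code{conservative} drops orphan I/E labels and unclosed B
#' blocks; \code{promote} upgrades an orphan I to a block start and an
#' orphan E to a singleton, and closes an unclosed block at its last
#' in-entity token.
#'
#' @param tokens token data.frame.
#' @param labels_or_probs character vector of labels, or numeric matrix
#'   (tokens x 5).
#' @param policy repair policy.
#' @return data.frame of spans (start, end, source = "model").
#' @export
bioesToSpans <- function(tokens, labels_or_probs,
                         policy = c("conservative", "promote")) {
  policy <- match.arg(policy)
  if (is.matrix(labels_or_probs)) {
    if (nrow(labels_or_probs) != nrow(tokens))
      stop("probability rows do not match token count")
    labels <- BIOES_LABELS[max.col(labels_or_probs, ties.method = "first")]
  } else {
    labels <- as.character(labels_or_probs)
    if (length(labels) != nrow(tokens))
      stop("label count does not match token count")
  }
  spans <- list()
  addSpan <- function(i, j) spans[[length(spans) + 1L]] <<- data.frame(
    start = tokens$start[i], end = tokens$end[j], source = "model",
    stringsAsFactors = FALSE)
  openAt <- NA_integer_
  lastIn <- NA_integer_
  for (t in seq_along(labels)) {
    lb <- labels[t]
    if (lb == "S") {
      if (!is.na(openAt) && policy == "promote") addSpan(openAt, lastIn)
      openAt <- NA_integer_
      addSpan(t, t)
    } else if (lb == "B") {
      if (!is.na(openAt) && policy == "promote") addSpan(openAt, lastIn)
      openAt <- t; lastIn <- t
    } else if (lb == "I") {
      if (!is.na(openAt)) lastIn <- t
      else if (policy == "promote") { openAt <- t; lastIn <- t }
      # conservative: orphan I dropped
    } else if (lb == "E") {
      if (!is.na(openAt)) { addSpan(openAt, t); openAt <- NA_integer_ }
      else if (policy == "promote") addSpan(t, t)
      # conservative: orphan E dropped
    } else {                                  # O
      if (!is.na(openAt) && policy == "promote") addSpan(openAt, lastIn)
      openAt <- NA_integer_
    }
  }
  if (!is.na(openAt) && policy == "promote") addSpan(openAt, lastIn)
  if (!length(spans)) return(emptySpans())
  out <- do.call(rbind, spans)
  out[order(out$start), , drop = FALSE]
}
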