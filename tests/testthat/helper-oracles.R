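# Independent brute-force oracles used to cross-check the
# implementation. These deliberately use different algorithms from the
# package code paths they verify.

# all-substring dictionary scan with boundary check + maximal filter
oracleDictScan <- function(text, entries) {
  hits <- list()
  lowText <- tolower(text)
  n <- nchar(text)
  for (e in entries) {
    le <- tolower(e); L <- nchar(e)
    if (L > n) next
    for (s in seq_len(n - L + 1L)) {
      if (substr(lowText, s, s + L - 1L) != le) next
      before <- if (s > 1L) substr(text, s - 1L, s - 1L) else ""
      after <- if (s + L <= n) substr(text, s + L, s + L) else ""
      if (grepl("[A-Za-z0-9-]", before) || grepl("[A-Za-z0-9-]", after))
        next
      hits[[length(hits) + 1L]] <- c(s - 1L, s - 1L + L)
    }
  }
  if (!length(hits)) return(matrix(integer(0), ncol = 2))
  m <- unique(do.call(rbind, hits))
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(nrow(m)))
    if (i != j && m[j, 1] <= m[i, 1] && m[i, 2] <= m[j, 2] &&
        (m[j, 2] - m[j, 1]) > (m[i, 2] - m[i, 1])) keep[i] <- FALSE
  m <- m[keep, , drop = FALSE]
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# pairwise union-find closure of the merge relation
oracleMerge <- function(spans, text) {
  n <- nrow(spans)
  if (n == 0L) return(spans[, c("start", "end")])
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  related <- function(i, j) {
    a <- spans[i, ]; b <- spans[j, ]
    if (a$start > b$start) { t <- a; a <- b; b <- t }
    if (b$start <= a$end) return(TRUE)               # overlap or touch
    gap <- substr(text, a$end + 1L, b$start)
    nzchar(gap) && grepl("^\\s+$", gap)
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j) next
      ri <- find(i); rj <- find(j)
      if (ri != rj && related(i, j)) {
        # merged blocks are intervals: refresh both to the hull so the
        # relation composes transitively
        parent[rj] <- ri
        hullS <- min(spans$start[c(i, j)]); hullE <- max(spans$end[c(i, j)])
        for (k in seq_len(n)) if (find(k) == ri) {
          spans$start[k] <- min(spans$start[k], hullS)
          spans$end[k] <- max(spans$end[k], hullE)
        }
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- do.call(rbind, lapply(unique(comp), function(cmp) {
    sel <- comp == cmp
    data.frame(start = min(spans$start[sel]), end = max(spans$end[sel]))
  }))
  out[order(out$start), , drop = FALSE]
}

# independent conservative BIOES repair: a regular expression over the
# collapsed label string finds exactly the legal S and B..E blocks
oracleDecodeConservative <- function(labels) {
  s <- paste(labels, collapse = "")
  m <- gregexpr("BI*E|S", s)[[1]]
  if (m[1] == -1L) return(matrix(integer(0), ncol = 2))
  cbind(as.integer(m), as.integer(m) + attr(m, "match.length") - 1L)
}

# word-level simulator of the adjacent-word extension rules
oracleExtend <- function(text, start, end, stopwords) {
  m <- gregexpr("\\S+", text)[[1]]
  ws <- as.integer(m); we <- ws + attr(m, "match.length") - 1L  # 1-based
  words <- substring(text, ws, we)
  followers <- c("acid", "isomer", "ester", "ether")
  stripTrail <- function(e) {
    while (e > 0 && substr(text, e, e) %in%
           c(".", ",", ";", "!", "?", "\"", "'")) e <- e - 1L
    e
  }
  repeat {
    changed <- FALSE
    entity <- substr(text, start + 1L, end)
    firstWord <- sub("\\s.*$", "", entity)
    pi <- which(we < start + 1L)
    if (length(pi)) {
      p <- max(pi)
      pw <- words[p]
      if (!(tolower(pw) %in% stopwords) &&
          (grepl("-$", pw) || grepl("[0-9]$", pw) ||
           grepl("^,[0-9]", entity) || grepl("^-", firstWord))) {
        start <- ws[p] - 1L; changed <- TRUE
      }
    }
    entity <- substr(text, start + 1L, end)
    lastWord <- sub("^.*\\s", "", entity)
    ni <- which(ws > end)
    if (length(ni)) {
      q <- min(ni)
      nw <- words[q]
      nwClean <- tolower(sub("[.,;!?]+$", "", nw))
      if (!(tolower(nw) %in% stopwords) &&
          (grepl("-$", lastWord) || grepl("[0-9]$", lastWord) ||
           grepl("^,[0-9]", nw) || grepl("^-", nw) ||
           nwClean %in% followers)) {
        newEnd <- stripTrail(we[q])
        if (newEnd > end) { end <- newEnd; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  c(start, end)
}
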