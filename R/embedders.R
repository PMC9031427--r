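# Token-embedding backends behind a single contract: an embedder is a
# list with elements `dim` (integer) and `embed` (function taking the
# character vector of a sentence's tokens and returning a tokens x dim
# numeric matrix), plus a `kind` label. Context-free backends look each
# token up independently; contextual backends may use the whole token
# sequence.

#' Check the embedder contract
#'
#' @param x candidate object.
#' @return TRUE if \code{x} is a valid embedder.
#' @export
isEmbedder <- function(x) {
  is.list(x) && is.numeric(x$dim) && length(x$dim) == 1L &&
    is.function(x$embed)
}

#' Load a word-vector text file
#'
#' One line per token: the token followed by \code{dim} whitespace-
#' separated floats (the common plain-text distribution format of
#' pretrained context-free vectors).
#'
#' @param path vector file.
#' @return numeric matrix with one named row per token.
#' @export
loadWordVectors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  dims <- unique(vapply(parts, length, integer(1)))
  if (length(dims) != 1L)
    stop("inconsistent field counts in word-vector file")
  toks <- vapply(parts, `[[`, "", 1)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]),
                  numeric(dims - 1L)))
  rownames(mat) <- toks
  mat
}

#' Context-free word-vector embedder
#'
#' Case-folded lookup into a fixed vector table; out-of-vocabulary
#' tokens embed as the zero vector.
#'
#' @param vectors matrix from \code{\link{loadWordVectors}}, or a path
#'   to a vector file.
#' @return an embedder (see \code{\link{isEmbedder}}).
#' @export
wordVectorEmbedder <- function(vectors) {
  if (is.character(vectors)) vectors <- loadWordVectors(vectors)
  rownames(vectors) <- foldCase(rownames(vectors))
  d <- ncol(vectors)
  list(
    kind = "context_free",
    dim = d,
    embed = function(tokens) {
      out <- matrix(0, nrow = length(tokens), ncol = d)
      idx <- match(foldCase(tokens), rownames(vectors))
      hit <- !is.na(idx)
      if (any(hit)) out[hit, ] <- vectors[idx[hit], , drop = FALSE]
      out
    })
}

# deterministic pseudo-random unit-ish vector for a token (hashed
# random projection; no RNG state touched)
hashProjection <- function(token, dim, streams = 4L) {
  v <- numeric(dim)
  bytes <- utf8ToInt(foldCase(token))
  for (s in seq_len(streams)) {
    h <- (21661 + s * 7919) %% 2147483647
    for (b in bytes) h <- (h * 31 + b) %% 2147483647
    # spread the hash state into dim pseudo-uniform values
    idx <- (h + (seq_len(dim) - 1) * 2654435) %% 2147483647
    v <- v + cos(2 * pi * idx / 2147483647)
  }
  v / sqrt(streams * dim / 2)
}

#' Synthetic contextual embedder
#'
#' A deterministic stand-in for a transformer's last hidden layer, used
#' to exercise the contextual (768-d) code path without pretrained
#' weights: each token's vector is a hashed random projection of its
#' string, mixed with the mean projection of its neighbouring tokens so
#' that the representation depends on context. Any real contextual
#' backend satisfying the embedder contract can replace it.
#'
#' @param dim embedding width (default 768).
#' @param context_weight fraction of the vector contributed by the
#'   neighbour mean.
#' @param window neighbourhood half-width.
#' @return an embedder (see \code{\link{isEmbedder}}).
#' @export
syntheticContextualEmbedder <- function(dim = 768L, context_weight = 0.3,
                                        window = 2L) {
  dim <- as.integer(dim)
  cache <- new.env(parent = emptyenv())
  proj <- function(tok) {
    key <- foldCase(tok)
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- hashProjection(tok, dim)
    cache[[key]] <- v
    v
  }
  list(
    kind = "contextual",
    dim = dim,
    embed = function(tokens) {
      n <- length(tokens)
      base <- matrix(0, n, dim)
      for (i in seq_len(n)) base[i, ] <- proj(tokens[i])
      if (n == 1L || context_weight == 0) return(base)
      out <- base
      for (i in seq_len(n)) {
        lo <- max(1L, i - window); hi <- min(n, i + window)
        nb <- setdiff(lo:hi, i)
        ctx <- colMeans(base[nb, , drop = FALSE])
        out[i, ] <- (1 - context_weight) * base[i, ] +
          context_weight * ctx
      }
      out
    })
}
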