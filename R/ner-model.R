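# The BiLSTM sequence labeller: width-3 convolution over name-internal
# features, concatenation with token embeddings (channel dropout for
# contextual embeddings), bidirectional LSTM, per-token 5-class softmax.
# Trained with Adam and best-validation-F1 epoch selection.

#' Sequence-labeller configuration
#'
#' Defaults mirror the published architecture: width-3 convolution with
#' 256 filters over the 5-dimensional name-internal features, giving a
#' concatenated per-token width of \code{conv_filters + embedding_dim}
#' (556 for 300-d context-free embeddings, 1024 for 768-d contextual
#' ones), channel dropout 0.25 on contextual embeddings, 50 training
#' epochs with the best-validation-F1 epoch retained.
#'
#' @param embedding "context_free" or "contextual".
#' @param embedding_dim embedding width (300 context-free, 768
#'   contextual by default).
#' @param conv_width convolution window (odd).
#' @param conv_filters number of convolution filters.
#' @param embed_dropout channel dropout rate on the embedding (applied
#'   for contextual embeddings; 0 disables).
#' @param hidden LSTM units per direction.
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size sentences per gradient step (accumulated).
#' @param seed integer seed for weight init, shuffling and dropout.
#' @param decode_policy BIOES repair policy for decoding.
#' @param tokenizer tokenizer backend id.
#' @param max_tokens backend sequence limit; longer sentences are
#'   processed in overlapping windows.
#' @return a validated config list.
#' @export
nerModelConfig <- function(embedding = c("context_free", "contextual"),
                           embedding_dim = NULL, conv_width = 3L,
                           conv_filters = 256L,
                           embed_dropout = NULL, hidden = 300L,
                           epochs = 50L, lr = 1e-3, batch_size = 32L,
                           seed = 1L,
                           decode_policy = "conservative",
                           tokenizer = NULL, max_tokens = 512L) {
  embedding <- match.arg(embedding)
  if (is.null(embedding_dim))
    embedding_dim <- if (embedding == "context_free") 300L else 768L
  if (is.null(embed_dropout))
    embed_dropout <- if (embedding == "contextual") 0.25 else 0
  if (is.null(tokenizer))
    tokenizer <- if (embedding == "context_free") "chem_word" else "subword"
  if (conv_width %% 2L != 1L) stop("conv_width must be odd")
  list(embedding = embedding,
       embedding_dim = as.integer(embedding_dim),
       conv_width = as.integer(conv_width),
       conv_filters = as.integer(conv_filters),
       concat_dim = as.integer(conv_filters + embedding_dim),
       embed_dropout = embed_dropout, hidden = as.integer(hidden),
       epochs = as.integer(epochs), lr = lr,
       batch_size = as.integer(batch_size), seed = as.integer(seed),
       decode_policy = decode_policy, tokenizer = tokenizer,
       max_tokens = as.integer(max_tokens))
}

#' Initialise an untrained sequence labeller
#'
#' @param config from \code{\link{nerModelConfig}}.
#' @return an \linkS4class{NERModel} with freshly initialised weights.
#' @export
buildNerModel <- function(config) {
  w <- .nn_init(5L, config$conv_width, config$conv_filters,
                config$embedding_dim, config$hidden, 5L, config$seed)
  new("NERModel", weights = w, config = config,
      trainingLog = data.frame(), bestEpoch = NA_integer_)
}

# tokenize + featurize + embed + label one corpus; annotations may be
# NULL (prediction time)
encodeNerCorpus <- function(sentences, annotations, embedder,
                            preclassifier, config) {
  stopifnot(isEmbedder(embedder))
  if (embedder$dim != config$embedding_dim)
    stop("embedder width ", embedder$dim,
         " does not match config embedding_dim ", config$embedding_dim)
  n <- nrow(sentences)
  enc <- list(tokens = vector("list", n), feats = vector("list", n),
              embs = vector("list", n), labels = vector("list", n),
              gold = vector("list", n))
  akey <- if (!is.null(annotations))
    paste(annotations$pmcid, annotations$sentence_id) else character(0)
  for (i in seq_len(n)) {
    toks <- tokenize(sentences$text[i], config$tokenizer)
    enc$tokens[[i]] <- toks
    enc$feats[[i]] <- scoreTokens(preclassifier, toks$text)
    enc$embs[[i]] <- embedder$embed(toks$text)
    if (!is.null(annotations)) {
      sel <- annotations[akey == paste(sentences$pmcid[i],
                                       sentences$sentence_id[i]), ,
                         drop = FALSE]
      enc$gold[[i]] <- sel
      labs <- spansToBioes(toks, sel, on_misaligned = "snap")
      enc$labels[[i]] <- match(labs, BIOES_LABELS) - 1L
    }
  }
  enc
}

spanF1 <- function(pred_list, gold_list) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(pred_list)) {
    p <- pred_list[[i]]; g <- gold_list[[i]]
    pk <- if (nrow(p)) paste(p$start, p$end) else character(0)
    gk <- if (nrow(g)) paste(g$start, g$end) else character(0)
    tp <- tp + length(intersect(pk, gk))
    fp <- fp + length(setdiff(pk, gk))
    fn <- fn + length(setdiff(gk, pk))
  }
  nerScore(tp, fp, fn)
}

#' Train the sequence labeller
#'
#' Runs \code{config$epochs} passes over the training sentences
#' (shuffled deterministically per epoch from the seed), computing the
#' span-level F1 on the validation corpus after every epoch; the
#' weights of the epoch with the highest validation F1 are retained.
#' Sentences are tokenised, scored by the pre-classifier and embedded
#' once before training. Aborts on non-finite loss.
#'
#' @param train_sentences,train_annotations training corpus (sentence
#'   table and gold records).
#' @param val_sentences,val_annotations validation corpus (non-empty).
#' @param embedder an embedder (\code{\link{wordVectorEmbedder}} or
#'   \code{\link{syntheticContextualEmbedder}}).
#' @param preclassifier a trained \linkS4class{PreClassifier}.
#' @param config from \code{\link{nerModelConfig}}.
#' @param verbose print per-epoch progress.
#' @return a trained \linkS4class{NERModel} (training log attached).
#' @export
trainNerModel <- function(train_sentences, train_annotations,
                          val_sentences, val_annotations,
                          embedder, preclassifier, config = nerModelConfig(),
                          verbose = FALSE) {
  if (!nrow(train_sentences)) stop("empty training corpus")
  if (!nrow(val_sentences)) stop("empty validation corpus")
  trainEnc <- encodeNerCorpus(train_sentences, train_annotations,
                              embedder, preclassifier, config)
  valEnc <- encodeNerCorpus(val_sentences, val_annotations,
                            embedder, preclassifier, config)
  valGold <- lapply(valEnc$gold, function(g)
    if (nrow(g)) g[, c("start", "end")] else
      data.frame(start = integer(0), end = integer(0)))

  params <- .nn_init(5L, config$conv_width, config$conv_filters,
                     config$embedding_dim, config$hidden, 5L,
                     config$seed)
  adam <- .nn_adam_init(params)
  n <- nrow(train_sentences)
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    val_precision = numeric(0), val_recall = numeric(0),
                    val_f1 = numeric(0))
  best <- list(f1 = -Inf, params = params, epoch = NA_integer_)
  oldSeed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, globalenv()), add = TRUE)
  for (epoch in seq_len(config$epochs)) {
    set.seed(deriveSeed(config$seed, epoch))
    ord <- sample.int(n)
    res <- .nn_train_epoch(params, adam, trainEnc$feats, trainEnc$embs,
                           trainEnc$labels, ord, config$lr,
                           config$batch_size, config$embed_dropout,
                           config$conv_width,
                           deriveSeed(config$seed, 1000L + epoch))
    params <- res$params; adam <- res$adam
    if (!is.finite(res$loss))
      stop("non-finite training loss at epoch ", epoch)
    predSpans <- lapply(seq_along(valEnc$tokens), function(i) {
      toks <- valEnc$tokens[[i]]
      if (!nrow(toks))
        return(data.frame(start = integer(0), end = integer(0)))
      probs <- modelProbs(params, config, valEnc$feats[[i]],
                          valEnc$embs[[i]])
      bioesToSpans(toks, probs, policy = config$decode_policy)
    })
    sc <- spanF1(predSpans, valGold)
    log <- rbind(log, data.frame(epoch = epoch, loss = res$loss,
                                 val_precision = sc$precision,
                                 val_recall = sc$recall,
                                 val_f1 = sc$f1))
    if (verbose)
      message(sprintf("epoch %02d  loss %.4f  val F1 %.4f", epoch,
                      res$loss, sc$f1))
    if (sc$f1 > best$f1) best <- list(f1 = sc$f1, params = params,
                                      epoch = epoch)
  }
  new("NERModel", weights = best$params, config = config,
      trainingLog = log, bestEpoch = best$epoch)
}

# forward pass with windowing for sentences past the backend limit;
# overlapping halves are averaged
modelProbs <- function(params, config, feats, embs) {
  T <- nrow(feats)
  limit <- config$max_tokens
  if (T <= limit)
    return(.nn_forward(params, feats, embs, config$conv_width))
  overlap <- 16L
  probs <- matrix(0, T, 5L); wt <- numeric(T)
  s <- 1L
  while (s <= T) {
    e <- min(T, s + limit - 1L)
    p <- .nn_forward(params, feats[s:e, , drop = FALSE],
                     embs[s:e, , drop = FALSE], config$conv_width)
    probs[s:e, ] <- probs[s:e, ] + p
    wt[s:e] <- wt[s:e] + 1
    if (e == T) break
    s <- e - overlap + 1L
  }
  probs / wt
}

#' Predict metabolite mentions in a sentence
#'
#' Tokenises, scores name-internal features, embeds, runs the network,
#' decodes the BIOES output and applies the same post-processing
#' fix-ups as the rule-based pipeline (adjacent-word extension, bracket
#' balancing, merging).
#'
#' @param model a trained \linkS4class{NERModel}.
#' @param sentence character scalar or 1-row sentence data.frame.
#' @param embedder,preclassifier the backends used at training time.
#' @param stopwords stopword list for the fix-ups.
#' @param fixups apply the rule-based post-processing.
#' @return annotation record data.frame.
#' @export
predictNer <- function(model, sentence, embedder, preclassifier,
                       stopwords = defaultStopwords(), fixups = TRUE) {
  stopifnot(is(model, "NERModel"))
  cfg <- model@config
  if (is.character(sentence)) {
    text <- sentence; pmcid <- NA_character_; sid <- NA_character_
  } else {
    text <- sentence$text[1]
    pmcid <- sentence$pmcid[1]; sid <- sentence$sentence_id[1]
  }
  if (!nzchar(text)) return(emptyAnnotations(character(0)))
  toks <- tokenize(text, cfg$tokenizer)
  if (!nrow(toks)) return(emptyAnnotations(character(0)))
  feats <- scoreTokens(preclassifier, toks$text)
  embs <- embedder$embed(toks$text)
  probs <- modelProbs(model@weights, cfg, feats, embs)
  spans <- bioesToSpans(toks, probs, policy = cfg$decode_policy)
  if (fixups && nrow(spans))
    spans <- postProcessSpans(spans, text, stopwords)
  if (!nrow(spans)) return(emptyAnnotations(character(0)))
  annotationRecords(pmcid = pmcid, sentence_id = sid,
                    start = spans$start, end = spans$end,
                    entity = substr(rep(text, nrow(spans)),
                                    spans$start + 1L, spans$end),
                    source = "text")
}

#' Forward pass on one sentence (probability rows)
#'
#' Low-level access to the network output: per-token probability rows
#' over the five BIOES classes (each row sums to 1).
#'
#' @param model a trained \linkS4class{NERModel}.
#' @param feats tokens x 5 name-internal feature matrix.
#' @param embs tokens x embedding_dim matrix.
#' @return tokens x 5 probability matrix.
#' @export
modelForward <- function(model, feats, embs) {
  stopifnot(is(model, "NERModel"))
  out <- modelProbs(model@weights, model@config, feats, embs)
  colnames(out) <- BIOES_LABELS
  out
}
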