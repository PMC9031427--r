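# Small-scale mechanics of the sequence labeller; the scaled-down
# learning run lives in the acceptance suite.

tinySetup <- local({
  done <- NULL
  function() {
    if (!is.null(done)) return(done)
    dict <- fixtureBundle$dict
    corpus <- makeCorpus(4, dictEntries(dict), typo_rate = 0, seed = 21)
    sent <- corpus$sentences
    gold <- corpus$gold[corpus$gold$source == "text", ]
    vocab <- unique(unlist(lapply(sent$text,
                                  function(t) tokenize(t)$text)))
    emb <- wordVectorEmbedder(makeWordVecFile(vocab, 50, seed = 21))
    pc <- trainPreclassifier(buildPreclassifierData(dict), seed = 21)
    done <<- list(sent = sent, gold = gold, emb = emb, pc = pc)
    done
  }
})

tinyConfig <- function(...) {
  nerModelConfig(embedding = "context_free", embedding_dim = 50L,
                 conv_filters = 16L, hidden = 8L, batch_size = 4L,
                 seed = 5L, ...)
}

test_that("configuration arithmetic and validation", {
  cfg <- nerModelConfig("context_free")
  expect_equal(cfg$concat_dim, 556L)          # 256 conv + 300 embedding
  cfg2 <- nerModelConfig("contextual")
  expect_equal(cfg2$concat_dim, 1024L)        # 256 conv + 768 embedding
  expect_equal(cfg2$embed_dropout, 0.25)
  expect_equal(cfg$embed_dropout, 0)
  expect_error(nerModelConfig(conv_width = 4L), "odd")
})

test_that("forward pass yields one softmax row per token", {
  setup <- tinySetup()
  cfg <- tinyConfig(epochs = 1L)
  model <- buildNerModel(cfg)
  toks <- tokenize("Levels of glucitol were higher in cases.")
  feats <- scoreTokens(setup$pc, toks$text)
  embs <- setup$emb$embed(toks$text)
  pr <- modelForward(model, feats, embs)
  expect_equal(dim(pr), c(nrow(toks), 5L))
  expect_equal(rowSums(pr), rep(1, nrow(toks)), tolerance = 1e-9)
  expect_true(all(pr >= 0))
  # embedder/config width mismatch is caught
  bad <- syntheticContextualEmbedder(dim = 12)
  expect_error(
    trainNerModel(setup$sent, setup$gold, setup$sent, setup$gold,
                  bad, setup$pc, cfg),
    "does not match")
})

test_that("training is deterministic and a 1-epoch run keeps epoch 1", {
  setup <- tinySetup()
  ids <- unique(setup$sent$pmcid)
  isVal <- setup$sent$pmcid == ids[1]
  gVal <- setup$gold$pmcid == ids[1]
  args <- list(setup$sent[!isVal, ], setup$gold[!gVal, ],
               setup$sent[isVal, ], setup$gold[gVal, ],
               setup$emb, setup$pc)
  m1 <- do.call(trainNerModel, c(args, list(tinyConfig(epochs = 2L))))
  m2 <- do.call(trainNerModel, c(args, list(tinyConfig(epochs = 2L))))
  expect_identical(trainingLog(m1), trainingLog(m2))
  expect_identical(m1@weights, m2@weights)
  mOne <- do.call(trainNerModel, c(args, list(tinyConfig(epochs = 1L))))
  expect_equal(mOne@bestEpoch, 1L)
  expect_equal(nrow(trainingLog(mOne)), 1L)
  # best-epoch selection attains the maximum of the logged series
  expect_equal(trainingLog(m1)$val_f1[m1@bestEpoch],
               max(trainingLog(m1)$val_f1))
})

test_that("prediction is deterministic, empty on empty input", {
  setup <- tinySetup()
  ids <- unique(setup$sent$pmcid)
  isVal <- setup$sent$pmcid == ids[1]
  gVal <- setup$gold$pmcid == ids[1]
  model <- trainNerModel(setup$sent[!isVal, ], setup$gold[!gVal, ],
                         setup$sent[isVal, ], setup$gold[gVal, ],
                         setup$emb, setup$pc, tinyConfig(epochs = 2L))
  s <- setup$sent[which(isVal)[1], , drop = FALSE]
  p1 <- predictNer(model, s, setup$emb, setup$pc)
  p2 <- predictNer(model, s, setup$emb, setup$pc)
  expect_identical(p1, p2)
  expect_equal(nrow(predictNer(model, "", setup$emb, setup$pc)), 0)
  if (nrow(p1))
    expect_equal(substr(rep(s$text, nrow(p1)), p1$start + 1, p1$end),
                 p1$entity)
})

test_that("long inputs are processed in overlapping windows", {
  setup <- tinySetup()
  cfg <- tinyConfig(epochs = 1L, max_tokens = 24L)
  model <- buildNerModel(cfg)
  text <- paste(rep("Levels of glucitol were higher in cases.", 12),
                collapse = " ")
  toks <- tokenize(text, cfg$tokenizer)
  expect_gt(nrow(toks), cfg$max_tokens)
  feats <- scoreTokens(setup$pc, toks$text)
  embs <- setup$emb$embed(toks$text)
  pr <- modelForward(model, feats, embs)
  expect_equal(nrow(pr), nrow(toks))
  expect_equal(rowSums(pr), rep(1, nrow(toks)), tolerance = 1e-6)
})
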