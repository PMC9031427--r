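# Name-internal feature generator: a token-level classifier trained
# from the metabolite dictionary alone (no sentence context) that
# scores each token's probability of being the B/I/E/S of a metabolite
# name, or O. Its probability rows are the second input of the
# sequence labeller.

defaultFeatureConfig <- function(hash_dim = 128L, ngram_max = 3L)
  list(hash_dim = as.integer(hash_dim), ngram_max = as.integer(ngram_max))

# polynomial rolling hash of a string into [1, hash_dim]
hashNgram <- function(s, hash_dim) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% hash_dim
  h + 1L
}

#' Token shape and hashed n-gram features
#'
#' Character n-grams (orders 1..ngram_max, with boundary markers) hashed
#' into a fixed-width count vector, plus shape features: token length,
#' digit/hyphen/bracket/colon presence, and case pattern. This is the
#' name-internal featurisation used by the pre-classifier; it sees only
#' the token string, never its sentence context.
#'
#' @param token_texts character vector of tokens.
#' @param config from \code{defaultFeatureConfig}.
#' @return numeric matrix, one row per token.
#' @export
tokenFeatureMatrix <- function(token_texts,
                               config = defaultFeatureConfig()) {
  hd <- config$hash_dim
  nmax <- config$ngram_max
  nShape <- 8L
  out <- matrix(0, nrow = length(token_texts), ncol = hd + nShape)
  colnames(out) <- c(paste0("h", seq_len(hd)),
                     c("len", "has_digit", "has_hyphen", "has_bracket",
                       "has_colon", "all_upper", "init_upper", "has_lower"))
  for (i in seq_along(token_texts)) {
    tok <- foldCase(token_texts[i])
    padded <- paste0("^", tok, "$")
    L <- nchar(padded)
    for (n in seq_len(nmax)) {
      if (L < n) next
      for (s in seq_len(L - n + 1L)) {
        j <- hashNgram(substr(padded, s, s + n - 1L), hd)
        out[i, j] <- out[i, j] + 1
      }
    }
    raw <- token_texts[i]
    out[i, hd + 1L] <- nchar(raw)
    out[i, hd + 2L] <- grepl("[0-9]", raw)
    out[i, hd + 3L] <- grepl("-", raw, fixed = TRUE)
    out[i, hd + 4L] <- grepl("[][(){}]", raw)
    out[i, hd + 5L] <- grepl(":", raw, fixed = TRUE)
    out[i, hd + 6L] <- grepl("^[A-Z0-9]+$", raw) && grepl("[A-Z]", raw)
    out[i, hd + 7L] <- grepl("^[A-Z]", raw)
    out[i, hd + 8L] <- grepl("[a-z]", raw)
  }
  out
}

#' Build pre-classifier training data from a dictionary
#'
#' Tokenises every dictionary entry and labels its tokens by position
#' (single token: S; several: B, I..., E); tokens of the negative
#' lexicon (common non-metabolite words) are labelled O.
#'
#' @param dict a \linkS4class{MetaboliteDictionary}.
#' @param negative_lexicon character vector of common words
#'   (\code{\link{defaultNegativeLexicon}} by default).
#' @param tokenizer_id tokenizer backend id.
#' @param config featurisation config.
#' @return list(features = matrix, labels = factor over BIOES,
#'   tokens = character).
#' @export
buildPreclassifierData <- function(dict,
                                   negative_lexicon = defaultNegativeLexicon(),
                                   tokenizer_id = "chem_word",
                                   config = defaultFeatureConfig()) {
  stopifnot(is(dict, "MetaboliteDictionary"))
  entries <- dictEntries(dict)
  if (!length(entries)) stop("empty dictionary")
  toks <- character(); labs <- character()
  for (e in entries) {
    tt <- tokenize(e, tokenizer_id)$text
    if (!length(tt)) next
    ll <- if (length(tt) == 1L) "S" else
      c("B", rep("I", length(tt) - 2L), "E")
    toks <- c(toks, tt); labs <- c(labs, ll)
  }
  for (w in negative_lexicon) {
    tt <- tokenize(w, tokenizer_id)$text
    toks <- c(toks, tt); labs <- c(labs, rep("O", length(tt)))
  }
  list(features = tokenFeatureMatrix(toks, config),
       labels = factor(labs, levels = BIOES_LABELS),
       tokens = toks, tokenizer = tokenizer_id, config = config,
       dictionaryHash = contentHash(entries))
}

#' Default negative lexicon
#'
#' Common English words (function words plus frequent scientific prose
#' vocabulary) used as O-class examples when training the
#' pre-classifier. User-replaceable; a frequency list file can be read
#' with one term per line.
#'
#' @return character vector.
#' @export
defaultNegativeLexicon <- function() {
  c(defaultStopwords(),
    "study", "studies", "analysis", "analyses", "sample", "samples",
    "patient", "patients", "control", "controls", "group", "groups",
    "significant", "significantly", "increased", "decreased", "higher",
    "lower", "observed", "measured", "compared", "associated", "found",
    "show", "shown", "showed", "data", "method", "methods", "model",
    "models", "table", "figure", "serum", "plasma", "urine", "blood",
    "tissue", "cells", "disease", "cancer", "healthy", "subjects",
    "cohort", "concentration", "concentrations", "abundance", "levels",
    "level", "profile", "profiles", "metabolite", "metabolites",
    "metabolomics", "spectroscopy", "chromatography", "spectrometry",
    "mass", "assay", "cases", "changes", "effect", "effects",
    "expression", "pathway", "pathways", "response", "risk", "test",
    "tests", "time", "treatment", "used", "versus", "weight", "worse")
}

#' Train the pre-classifier
#'
#' Fits a probability random forest on the dictionary-derived token
#' data. Deterministic for a fixed seed (single-threaded).
#'
#' @param data list from \code{\link{buildPreclassifierData}}.
#' @param seed integer seed.
#' @param num_trees forest size.
#' @return a \linkS4class{PreClassifier}.
#' @export
trainPreclassifier <- function(data, seed = 1L, num_trees = 100L) {
  present <- unique(as.character(data$labels))
  if (length(present) < 2L)
    stop("pre-classifier training data has a single class")
  df <- data.frame(data$features, check.names = FALSE)
  df$.label <- droplevels(data$labels)
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    probability = TRUE, num.trees = num_trees,
    seed = as.integer(seed), num.threads = 1L,
    respect.unordered.factors = TRUE)
  new("PreClassifier", model = fit,
      featureConfig = data$config, tokenizer = data$tokenizer,
      dictionaryHash = data$dictionaryHash, seed = as.integer(seed))
}

#' Score tokens with the pre-classifier
#'
#' @param pc a \linkS4class{PreClassifier}.
#' @param token_texts character vector of tokens.
#' @return numeric matrix (tokens x 5), columns in
#'   \code{\link{BIOES_LABELS}} order; rows sum to 1.
#' @export
scoreTokens <- function(pc, token_texts) {
  stopifnot(is(pc, "PreClassifier"))
  out <- matrix(0, nrow = length(token_texts), ncol = 5L,
                dimnames = list(NULL, BIOES_LABELS))
  if (!length(token_texts)) return(out)
  feat <- tokenFeatureMatrix(token_texts, pc@featureConfig)
  pred <- stats::predict(pc@model, data.frame(feat, check.names = FALSE),
                         num.threads = 1L)$predictions
  out[, colnames(pred)] <- pred
  sums <- rowSums(out)
  sums[sums == 0] <- 1
  out / sums
}

#' Persist / restore a pre-classifier
#'
#' Saved as an RDS with the model, feature config, tokenizer id,
#' dictionary hash and seed, so a loaded model can be checked against
#' the dictionary it was trained from.
#'
#' @param pc a \linkS4class{PreClassifier}.
#' @param path file path.
#' @export
savePreclassifier <- function(pc, path) {
  saveRDS(list(model = pc@model, featureConfig = pc@featureConfig,
               tokenizer = pc@tokenizer,
               dictionaryHash = pc@dictionaryHash, seed = pc@seed,
               format = 1L), path)
  invisible(path)
}

#' @rdname savePreclassifier
#' @export
loadPreclassifier <- function(path) {
  x <- readRDS(path)
  new("PreClassifier", model = x$model, featureConfig = x$featureConfig,
      tokenizer = x$tokenizer, dictionaryHash = x$dictionaryHash,
      seed = x$seed)
}
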