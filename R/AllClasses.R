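#' @import methods
NULL

#' The five BIOES labels in canonical order
#'
#' Begin, Inside, End, Singleton, Outside. All label vectors and
#' probability matrices in the package use this column order.
#' @export
BIOES_LABELS <- c("B", "I", "E", "S", "O")

#' MetaboliteDictionary: cleaned metabolite surface forms
#'
#' Holds the set of metabolite names and synonyms retained after status
#' filtering, together with the HMDB-style status of each entry
#' (\code{quantified}, \code{detected}, \code{expected},
#' \code{predicted}) and a case-folded index used for lookups. Original
#' casing is kept; all matching is case-insensitive.
#'
#' @slot entries character vector of surface strings (original casing).
#' @slot status named character vector, one status per entry
#'   (names are the entries).
#' @slot whitelist case-folded short entries exempt from length-based
#'   cleaning (e.g. "atp").
#' @slot removed character vector logging entries dropped by
#'   \code{\link{cleanDictionary}}.
#' @export
setClass("MetaboliteDictionary",
  representation(
    entries   = "character",
    status    = "character",
    whitelist = "character",
    removed   = "character"
  ),
  prototype(entries = character(), status = character(),
            whitelist = character(), removed = character())
)

setValidity("MetaboliteDictionary", function(object) {
  msg <- character()
  if (anyDuplicated(tolower(object@entries)))
    msg <- c(msg, "case-folded entries must be unique")
  if (length(object@status) &&
      !all(names(object@status) %in% object@entries))
    msg <- c(msg, "status names must be dictionary entries")
  bad <- setdiff(unique(object@status),
                 c("quantified", "detected", "expected", "predicted"))
  if (length(bad))
    msg <- c(msg, paste0("unknown status value(s): ",
                         paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' PatternSet: an ordered set of regular expressions
#'
#' A named, versioned list of PCRE patterns used for partial matching of
#' metabolite names. Serialisable to a plain-text file (one pattern per
#' line, \code{#} comments).
#'
#' @slot patterns character vector of regular expressions (PCRE).
#' @slot name short identifier for the set.
#' @slot version free-form version string.
#' @export
setClass("PatternSet",
  representation(patterns = "character", name = "character",
                 version = "character"),
  prototype(patterns = character(), name = "patterns", version = "0")
)

setValidity("PatternSet", function(object) {
  for (p in object@patterns) {
    ok <- tryCatch({ suppressWarnings(grepl(p, "", perl = TRUE)); TRUE },
                   error = function(e) FALSE)
    if (!ok) return(paste0("pattern does not compile: ", p))
  }
  TRUE
})

#' Article: one publication in Auto-CORPus-style form
#'
#' Sections are kept as a list of lists with elements \code{code} (one
#' of A/M/R/D for sentence identifiers), \code{group} (A/M/R/RD/D, used
#' for per-section evaluation; combined results-and-discussion sections
#' carry code R but group RD), \code{iao_term} and \code{subsections}
#' (ordered character vector of text blocks). Tables are lists with a
#' \code{rows} element (list of character vectors). Abbreviations map
#' short form to definition.
#'
#' @slot pmcid article identifier, non-empty.
#' @slot sections ordered list of section records (see Details).
#' @slot tables list of table records.
#' @slot abbreviations named character vector, short form -> definition.
#' @export
setClass("Article",
  representation(pmcid = "character", sections = "list",
                 tables = "list", abbreviations = "character"),
  prototype(pmcid = NA_character_, sections = list(), tables = list(),
            abbreviations = character())
)

setValidity("Article", function(object) {
  if (length(object@pmcid) != 1L || is.na(object@pmcid) ||
      !nzchar(object@pmcid))
    return("pmcid must be a single non-empty string")
  for (s in object@sections) {
    if (!all(c("code", "group", "iao_term", "subsections") %in% names(s)))
      return("each section needs code, group, iao_term, subsections")
    if (!s$code %in% c("A", "M", "R", "D"))
      return("section code must be one of A, M, R, D")
    if (!s$group %in% c("A", "M", "R", "RD", "D"))
      return("section group must be one of A, M, R, RD, D")
  }
  TRUE
})

#' PreClassifier: dictionary-trained name-internal feature model
#'
#' A token-level probabilistic classifier over the five BIOES classes,
#' trained on dictionary entries (positions within names) and a negative
#' lexicon of common words. Its per-token probability rows are the
#' "name-internal features" consumed by the sequence labeller.
#'
#' @slot model the fitted ensemble-of-trees model.
#' @slot featureConfig list describing the featurisation (hash width,
#'   n-gram orders).
#' @slot tokenizer tokenizer id the training tokens came from.
#' @slot dictionaryHash hash of the training dictionary entries.
#' @slot seed integer seed the model was fitted under.
#' @export
setClass("PreClassifier",
  representation(model = "ANY", featureConfig = "list",
                 tokenizer = "character", dictionaryHash = "character",
                 seed = "integer")
)

#' NERModel: trained BiLSTM sequence labeller
#'
#' Weights of the convolution (width-3 filters over name-internal
#' features), bidirectional LSTM and per-token 5-class softmax output
#' layer, together with the configuration and training log.
#'
#' @slot weights named list of numeric matrices.
#' @slot config the \code{\link{nerModelConfig}} list used for training.
#' @slot trainingLog data.frame with one row per epoch (epoch, loss,
#'   val_precision, val_recall, val_f1).
#' @slot bestEpoch epoch whose weights are stored (highest validation F1).
#' @export
setClass("NERModel",
  representation(weights = "list", config = "list",
                 trainingLog = "data.frame", bestEpoch = "integer")
)

#' CooccurrenceGraph: article-weighted metabolite co-mention network
#'
#' Nodes are case-folded metabolite surface names weighted by the number
#' of articles mentioning them; edges are unordered metabolite pairs
#' weighted by the number of articles mentioning both. Each node carries
#' the PMCID of the article that reports it most (ties broken towards
#' the lexicographically lower PMCID), used downstream as a colour
#' attribute.
#'
#' @slot nodes data.frame(name, weight, top_pmcid).
#' @slot edges data.frame(from, to, weight) with from < to.
#' @slot nArticles number of articles the graph was built from.
#' @export
setClass("CooccurrenceGraph",
  representation(nodes = "data.frame", edges = "data.frame",
                 nArticles = "integer")
)

setValidity("CooccurrenceGraph", function(object) {
  nd <- object@nodes; ed <- object@edges
  if (!all(c("name", "weight", "top_pmcid") %in% names(nd)))
    return("nodes needs columns name, weight, top_pmcid")
  if (!all(c("from", "to", "weight") %in% names(ed)))
    return("edges needs columns from, to, weight")
  if (nrow(ed)) {
    if (any(ed$from == ed$to)) return("self-edges are not allowed")
    if (any(ed$from >= ed$to)) return("edges must be stored with from < to")
    w <- stats::setNames(nd$weight, nd$name)
    if (any(ed$weight > pmin(w[ed$from], w[ed$to])))
      return("edge weight exceeds an endpoint node weight")
  }
  TRUE
})

setMethod("show", "MetaboliteDictionary", function(object) {
  cat("MetaboliteDictionary with", length(object@entries), "entries\n")
  tab <- table(object@status)
  if (length(tab))
    cat("  status:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (length(object@removed))
    cat("  removed by cleaning:", length(object@removed), "\n")
})

setMethod("show", "PatternSet", function(object) {
  cat(sprintf("PatternSet '%s' (version %s): %d expression(s)\n",
              object@name, object@version, length(object@patterns)))
})

setMethod("show", "Article", function(object) {
  codes <- vapply(object@sections, function(s) s$group, character(1))
  cat("Article", object@pmcid, "with sections:",
      if (length(codes)) paste(codes, collapse = ", ") else "(none)", "\n")
  cat("  tables:", length(object@tables),
      " abbreviations:", length(object@abbreviations), "\n")
})

setMethod("show", "NERModel", function(object) {
  cfg <- object@config
  cat(sprintf("NERModel (%s embedding, %d-d): conv %dx%d, %d LSTM units/direction\n",
              cfg$embedding, cfg$embedding_dim, cfg$conv_width,
              cfg$conv_filters, cfg$hidden))
  if (nrow(object@trainingLog))
    cat(sprintf("  best epoch %d of %d (validation F1 = %.4f)\n",
                object@bestEpoch, nrow(object@trainingLog),
                object@trainingLog$val_f1[object@bestEpoch]))
})

setMethod("show", "CooccurrenceGraph", function(object) {
  cat(sprintf("CooccurrenceGraph: %d node(s), %d edge(s), from %d article(s)\n",
              nrow(object@nodes), nrow(object@edges), object@nArticles))
})

setMethod("show", "PreClassifier", function(object) {
  cat(sprintf("PreClassifier (%s tokens, %d-d hashed n-grams, seed %d)\n",
              object@tokenizer, object@featureConfig$hash_dim, object@seed))
})

#' @describeIn MetaboliteDictionary-class number of entries
#' @param x a MetaboliteDictionary
#' @export
setMethod("length", "MetaboliteDictionary",
          function(x) length(x@entries))
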