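# Span-level evaluation: exact-key TP/FP/FN matching, precision,
# recall, F1 and F*, per-section breakdown, and corpus summary
# statistics.

#' Match predicted against gold annotations
#'
#' Records are keyed by (pmcid, sentence_id, start, end) and matched
#' exactly; an overlap mode credits a prediction that overlaps a gold
#' span in the same sentence. Abbreviation- and table-sourced records
#' are evaluated separately, so the source filter is applied to both
#' sides; records without a source column count as "text". Duplicate
#' keys within one side are deduplicated with a warning.
#'
#' @param pred,gold annotation record data.frames.
#' @param mode "exact" (default) or "overlap".
#' @param include_sources sources to keep on both sides.
#' @return list(tp, fp, fn).
#' @export
matchAnnotations <- function(pred, gold, mode = c("exact", "overlap"),
                             include_sources = "text") {
  mode <- match.arg(mode)
  filt <- function(x) {
    src <- if ("source" %in% names(x)) x$source else
      rep("text", nrow(x))
    x[src %in% include_sources, , drop = FALSE]
  }
  pred <- filt(pred); gold <- filt(gold)
  key <- function(x) paste(x$pmcid, x$sentence_id, x$start, x$end,
                           sep = "\r")
  pk <- key(pred); gk <- key(gold)
  if (anyDuplicated(pk)) {
    warning("duplicate prediction keys deduplicated")
    pred <- pred[!duplicated(pk), , drop = FALSE]; pk <- key(pred)
  }
  if (anyDuplicated(gk)) {
    warning("duplicate gold keys deduplicated")
    gold <- gold[!duplicated(gk), , drop = FALSE]; gk <- key(gold)
  }
  if (mode == "exact") {
    tp <- sum(pk %in% gk)
    list(tp = tp, fp = length(pk) - tp, fn = length(gk) - tp)
  } else {
    sent <- function(x) paste(x$pmcid, x$sentence_id, sep = "\r")
    ps <- sent(pred); gs <- sent(gold)
    gMatched <- rep(FALSE, nrow(gold))
    tp <- 0L
    for (i in seq_len(nrow(pred))) {
      cand <- which(gs == ps[i] & !gMatched &
                    gold$start < pred$end[i] & gold$end > pred$start[i])
      if (length(cand)) { gMatched[cand[1]] <- TRUE; tp <- tp + 1L }
    }
    list(tp = tp, fp = nrow(pred) - tp, fn = sum(!gMatched))
  }
}

#' Precision, recall, F1 and F* from match counts
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2pr/(p+r), F* = pr/(p+r-pr). A zero denominator sets the
#' affected measures to 0 and flags the result as degenerate.
#' F* never exceeds F1.
#'
#' @param tp,fp,fn non-negative counts.
#' @return list(tp, fp, fn, precision, recall, f1, fstar, degenerate).
#' @export
nerScore <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  degenerate <- (tp + fp == 0) || (tp + fn == 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  fm <- fMeasures(p, r)
  list(tp = tp, fp = fp, fn = fn, precision = p, recall = r,
       f1 = fm$f1, fstar = fm$fstar, degenerate = degenerate)
}

#' F1 and F* from precision and recall
#'
#' Computes F1 = 2pr/(p+r) and F* = pr/(p+r-pr) directly from rates;
#' useful for reproducing reported scores from published precision and
#' recall values.
#'
#' @param precision,recall rates in [0,1].
#' @return list(f1, fstar).
#' @export
fMeasures <- function(precision, recall) {
  p <- precision; r <- recall
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  fstar <- if (p + r - p * r > 0) p * r / (p + r - p * r) else 0
  list(f1 = f1, fstar = fstar)
}

#' Per-section evaluation
#'
#' Partitions predictions and gold records by the section group
#' (A/M/R/RD/D) of the sentence they belong to and scores each group.
#' The per-group (tp, fp, fn) always sum to the global counts.
#'
#' @param pred,gold annotation record data.frames.
#' @param sentences sentence table with pmcid, sentence_id, group.
#' @param ... passed to \code{\link{matchAnnotations}}.
#' @return named list of \code{\link{nerScore}} results, one per group
#'   present.
#' @export
perSectionMetrics <- function(pred, gold, sentences, ...) {
  skey <- paste(sentences$pmcid, sentences$sentence_id, sep = "\r")
  groupOf <- function(x) {
    idx <- match(paste(x$pmcid, x$sentence_id, sep = "\r"), skey)
    if (anyNA(idx))
      stop("record references a sentence absent from the sentence table")
    sentences$group[idx]
  }
  pg <- groupOf(pred); gg <- groupOf(gold)
  out <- list()
  for (grp in intersect(c("A", "M", "R", "RD", "D"),
                        unique(c(pg, gg)))) {
    m <- matchAnnotations(pred[pg == grp, , drop = FALSE],
                          gold[gg == grp, , drop = FALSE], ...)
    out[[grp]] <- nerScore(m$tp, m$fp, m$fn)
  }
  out
}

#' Corpus summary statistics
#'
#' Counts metabolites once per article (case-folded surface identity)
#' and summarises per grouping level: the total number of
#' unique-per-article annotations, the number of articles, and the mean
#' number of unique metabolites per article (1 decimal place).
#'
#' @param per_article_entities named list: article id -> character
#'   vector of entity surface strings (duplicates allowed; case-folded
#'   and deduplicated internally).
#' @param grouping optional named character vector article id -> group
#'   (trait/journal); absent articles form group "all".
#' @return data.frame(group, n_unique_metabolites, n_articles,
#'   mean_per_article).
#' @export
corpusStats <- function(per_article_entities, grouping = NULL) {
  ids <- names(per_article_entities)
  if (is.null(ids)) stop("per_article_entities must be a named list")
  grp <- if (is.null(grouping)) rep("all", length(ids)) else
    unname(grouping[ids])
  grp[is.na(grp)] <- "all"
  counts <- vapply(per_article_entities,
                   function(e) length(unique(foldCase(e))), integer(1))
  out <- do.call(rbind, lapply(unique(grp), function(g) {
    sel <- grp == g
    data.frame(group = g,
               n_unique_metabolites = sum(counts[sel]),
               n_articles = sum(sel),
               mean_per_article = round(sum(counts[sel]) / sum(sel), 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write an evaluation report
#'
#' Serialises one or more \code{\link{nerScore}} results as TSV and, if
#' a path is given, JSON.
#'
#' @param scores named list of score lists.
#' @param tsv_path,json_path output paths (either may be NULL).
#' @return the report data.frame, invisibly.
#' @export
writeEvalReport <- function(scores, tsv_path = NULL, json_path = NULL) {
  df <- do.call(rbind, lapply(names(scores), function(nm) {
    s <- scores[[nm]]
    data.frame(set = nm, tp = s$tp, fp = s$fp, fn = s$fn,
               precision = round(s$precision, 4),
               recall = round(s$recall, 4), f1 = round(s$f1, 4),
               fstar = round(s$fstar, 4), stringsAsFactors = FALSE)
  }))
  if (!is.null(tsv_path))
    utils::write.table(df, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(scores, json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(df)
}
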