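# Article-weighted metabolite co-occurrence networks and top-metabolite
# frequency tables.

#' Build a metabolite co-occurrence graph
#'
#' Entity identity is the case-folded surface string. The node weight
#' of a metabolite is the number of articles mentioning it; the edge
#' weight of a pair is the number of articles mentioning both (each
#' article contributes at most once per node and per pair). Each node
#' records the PMCID of the article with the most mentions of it (ties
#' towards the lexicographically lower PMCID), used downstream as a
#' colour attribute.
#'
#' @param per_article_entities named list: article id -> character
#'   vector of entity strings (duplicates allowed; they only influence
#'   the top-article attribute).
#' @return a \linkS4class{CooccurrenceGraph}.
#' @export
buildCooccurrenceGraph <- function(per_article_entities) {
  ids <- names(per_article_entities)
  if (is.null(ids)) stop("per_article_entities must be a named list")
  nodeW <- new.env(parent = emptyenv())
  mentions <- list()   # name -> data.frame(pmcid, count)
  edgeW <- new.env(parent = emptyenv())
  for (a in ids) {
    raw <- foldCase(per_article_entities[[a]])
    if (!length(raw)) next
    tab <- table(raw)
    ents <- sort(names(tab))
    for (e in ents) {
      nodeW[[e]] <- (if (is.null(nodeW[[e]])) 0L else nodeW[[e]]) + 1L
      mentions[[e]] <- rbind(mentions[[e]],
                             data.frame(pmcid = a,
                                        count = as.integer(tab[[e]]),
                                        stringsAsFactors = FALSE))
    }
    if (length(ents) >= 2L) {
      for (i in seq_len(length(ents) - 1L))
        for (j in seq((i + 1L), length(ents))) {
          k <- paste(ents[i], ents[j], sep = "\r")
          edgeW[[k]] <- (if (is.null(edgeW[[k]])) 0L else edgeW[[k]]) + 1L
        }
    }
  }
  nodeNames <- sort(ls(nodeW))
  topOf <- function(e) {
    m <- mentions[[e]]
    m <- m[order(-m$count, m$pmcid), , drop = FALSE]
    m$pmcid[1]
  }
  nodes <- data.frame(
    name = nodeNames,
    weight = vapply(nodeNames, function(e) nodeW[[e]], integer(1)),
    top_pmcid = vapply(nodeNames, topOf, character(1)),
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  ek <- sort(ls(edgeW))
  edges <- if (length(ek)) {
    parts <- strsplit(ek, "\r", fixed = TRUE)
    data.frame(from = vapply(parts, `[[`, "", 1),
               to = vapply(parts, `[[`, "", 2),
               weight = vapply(ek, function(k) edgeW[[k]], integer(1)),
               stringsAsFactors = FALSE)
  } else data.frame(from = character(0), to = character(0),
                    weight = integer(0), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  new("CooccurrenceGraph", nodes = nodes, edges = edges,
      nArticles = length(ids))
}

#' Filter a graph to metabolites found in at least k articles
#'
#' Removes nodes with weight below \code{k} together with their
#' incident edges; \code{k = 1} is the identity. Idempotent and
#' monotone in \code{k}.
#'
#' @param graph a \linkS4class{CooccurrenceGraph}.
#' @param k minimum article count (>= 1).
#' @return the filtered graph.
#' @export
filterMinArticles <- function(graph, k) {
  stopifnot(is(graph, "CooccurrenceGraph"), k >= 1L)
  nodes <- graphNodes(graph)
  keep <- nodes$weight >= k
  nodes <- nodes[keep, , drop = FALSE]
  edges <- graphEdges(graph)
  edges <- edges[edges$from %in% nodes$name &
                 edges$to %in% nodes$name, , drop = FALSE]
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  new("CooccurrenceGraph", nodes = nodes, edges = edges,
      nArticles = graph@nArticles)
}

#' Top metabolites by article count
#'
#' @param per_article_entities named list article -> entities.
#' @param n number of rows to return.
#' @return data.frame(name, n_articles, percent) sorted by article
#'   count (ties alphabetical); percent is of the total article count,
#'   rounded to whole percent.
#' @export
topMetabolites <- function(per_article_entities, n = 10L) {
  ids <- names(per_article_entities)
  if (is.null(ids)) stop("per_article_entities must be a named list")
  total <- length(ids)
  perArticle <- lapply(per_article_entities,
                       function(e) unique(foldCase(e)))
  tab <- sort(table(unlist(perArticle, use.names = FALSE)),
              decreasing = TRUE)
  out <- data.frame(name = names(tab),
                    n_articles = as.integer(tab),
                    percent = round(100 * as.integer(tab) / total),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_articles, out$name), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n)
}

#' Export a co-occurrence graph
#'
#' \code{writeAdjacencyList} writes a weighted edge list TSV
#' (from, to, weight); \code{writeGEXF} writes GEXF 1.2 XML with node
#' weights as size attributes and the top-article PMCID as a node
#' attribute, ready for layout in any graph tool.
#'
#' @param graph a \linkS4class{CooccurrenceGraph}.
#' @param path output file.
#' @export
writeAdjacencyList <- function(graph, path) {
  stopifnot(is(graph, "CooccurrenceGraph"))
  utils::write.table(graphEdges(graph), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' @rdname writeAdjacencyList
#' @export
writeGEXF <- function(graph, path) {
  stopifnot(is(graph, "CooccurrenceGraph"))
  nodes <- graphNodes(graph); edges <- graphEdges(graph)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<gexf xmlns=\"http://www.gexf.net/1.2draft\" version=\"1.2\">",
    "  <graph mode=\"static\" defaultedgetype=\"undirected\">",
    "    <attributes class=\"node\">",
    "      <attribute id=\"0\" title=\"top_pmcid\" type=\"string\"/>",
    "      <attribute id=\"1\" title=\"articles\" type=\"integer\"/>",
    "    </attributes>",
    "    <nodes>")
  for (i in seq_len(nrow(nodes)))
    lines <- c(lines, sprintf(
      paste0("      <node id=\"%d\" label=\"%s\"><attvalues>",
             "<attvalue for=\"0\" value=\"%s\"/>",
             "<attvalue for=\"1\" value=\"%d\"/>",
             "</attvalues></node>"),
      i - 1L, xmlEscape(nodes$name[i]), xmlEscape(nodes$top_pmcid[i]),
      nodes$weight[i]))
  lines <- c(lines, "    </nodes>", "    <edges>")
  if (nrow(edges)) {
    fromId <- match(edges$from, nodes$name) - 1L
    toId <- match(edges$to, nodes$name) - 1L
    for (i in seq_len(nrow(edges)))
      lines <- c(lines, sprintf(
        "      <edge id=\"%d\" source=\"%d\" target=\"%d\" weight=\"%d\"/>",
        i - 1L, fromId[i], toId[i], edges$weight[i]))
  }
  lines <- c(lines, "    </edges>", "  </graph>", "</gexf>")
  writeLines(lines, path)
  invisible(path)
}
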