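#' Accessors for metaboText objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dictEntries", function(x, ...) standardGeneric("dictEntries"))

#' @rdname accessors
#' @export
setGeneric("dictStatus", function(x, ...) standardGeneric("dictStatus"))

#' @rdname accessors
#' @export
setGeneric("patterns", function(x, ...) standardGeneric("patterns"))

#' @rdname accessors
#' @export
setGeneric("pmcid", function(x, ...) standardGeneric("pmcid"))

#' @rdname accessors
#' @export
setGeneric("sections", function(x, ...) standardGeneric("sections"))

#' @rdname accessors
#' @export
setGeneric("articleTables", function(x, ...) standardGeneric("articleTables"))

#' @rdname accessors
#' @export
setGeneric("abbreviations", function(x, ...) standardGeneric("abbreviations"))

#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x, ...) standardGeneric("graphNodes"))

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x, ...) standardGeneric("graphEdges"))

#' @rdname accessors
#' @export
setGeneric("trainingLog", function(x, ...) standardGeneric("trainingLog"))

#' @rdname accessors
#' @export
setMethod("dictEntries", "MetaboliteDictionary", function(x, ...) x@entries)

#' @rdname accessors
#' @export
setMethod("dictStatus", "MetaboliteDictionary", function(x, ...) x@status)

#' @rdname accessors
#' @export
setMethod("patterns", "PatternSet", function(x, ...) x@patterns)

#' @rdname accessors
#' @export
setMethod("pmcid", "Article", function(x, ...) x@pmcid)

#' @rdname accessors
#' @export
setMethod("sections", "Article", function(x, ...) x@sections)

#' @rdname accessors
#' @export
setMethod("articleTables", "Article", function(x, ...) x@tables)

#' @rdname accessors
#' @export
setMethod("abbreviations", "Article", function(x, ...) x@abbreviations)

#' @rdname accessors
#' @export
setMethod("graphNodes", "CooccurrenceGraph", function(x, ...) x@nodes)

#' @rdname accessors
#' @export
setMethod("graphEdges", "CooccurrenceGraph", function(x, ...) x@edges)

#' @rdname accessors
#' @export
setMethod("trainingLog", "NERModel", function(x, ...) x@trainingLog)
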