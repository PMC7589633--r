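#' Accessors for RegulatoryNetwork and friends
#'
#' \code{networkEdges} and \code{networkNodes} return the edge and node tables;
#' \code{nodeIds} returns the ids of one node class; \code{edgeCounts} the
#' per-class edge tally. \code{geneSets} and \code{setUniverse} access a
#' \linkS4class{GeneSetCollection}; \code{featureClass}, \code{sampleCondition}
#' and \code{samplePair} access \linkS4class{ExpressionStudy} metadata;
#' \code{nullScores} the draws of an \linkS4class{FFLNull}.
#'
#' @param x the object.
#' @param node_class one of \code{"TF"}, \code{"miRNA"}, \code{"gene"};
#'   \code{NULL} returns all ids.
#' @return base vectors / data.frames mirroring the slots.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x, node_class = NULL) standardGeneric("nodeIds"))
#' @rdname accessors
#' @export
setGeneric("edgeCounts", function(x) standardGeneric("edgeCounts"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("setUniverse", function(x) standardGeneric("setUniverse"))
#' @rdname accessors
#' @export
setGeneric("featureClass", function(x) standardGeneric("featureClass"))
#' @rdname accessors
#' @export
setGeneric("sampleCondition", function(x) standardGeneric("sampleCondition"))
#' @rdname accessors
#' @export
setGeneric("samplePair", function(x) standardGeneric("samplePair"))
#' @rdname accessors
#' @export
setGeneric("nullScores", function(x) standardGeneric("nullScores"))

#' @rdname accessors
setMethod("networkEdges", "RegulatoryNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("networkNodes", "RegulatoryNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("nodeIds", "RegulatoryNetwork", function(x, node_class = NULL) {
  if (is.null(node_class)) return(x@nodes$id)
  node_class <- match.arg(node_class, .NODE_CLASSES)
  x@nodes$id[x@nodes$node_class == node_class]
})
#' @rdname accessors
setMethod("edgeCounts", "RegulatoryNetwork", function(x) {
  counts <- table(factor(x@edges$edge_class, levels = .EDGE_CLASSES))
  setNames(as.integer(counts), .EDGE_CLASSES)
})
#' @rdname accessors
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)
#' @rdname accessors
setMethod("setUniverse", "GeneSetCollection", function(x)
  if (length(x@universe)) x@universe else NULL)
#' @rdname accessors
setMethod("featureClass", "ExpressionStudy", function(x)
  setNames(as.character(SummarizedExperiment::rowData(x)$featureClass),
           rownames(x)))
#' @rdname accessors
setMethod("sampleCondition", "ExpressionStudy", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$condition),
           colnames(x)))
#' @rdname accessors
setMethod("samplePair", "ExpressionStudy", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$pairId),
           colnames(x)))
#' @rdname accessors
setMethod("nullScores", "FFLNull", function(x) x@scores)

setMethod("show", "RegulatoryNetwork", function(object) {
  nc <- table(factor(object@nodes$node_class, levels = .NODE_CLASSES))
  ec <- edgeCounts(object)
  cat("RegulatoryNetwork with", nrow(object@nodes), "nodes and",
      nrow(object@edges), "edges\n")
  cat("  nodes:", paste(sprintf("%d %s", as.integer(nc), names(nc)),
                        collapse = ", "), "\n")
  cat("  edges:", paste(sprintf("%d %s", ec, names(ec)), collapse = ", "),
      "\n")
  if (object@removedSelfLoops > 0L)
    cat("  self-loops removed at build:", object@removedSelfLoops, "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets")
  if (length(object@universe))
    cat(" over a universe of", length(object@universe), "identifiers")
  cat("\n")
  if (length(object@sets)) {
    sizes <- vapply(object@sets, length, integer(1))
    cat("  set sizes:", paste(range(sizes), collapse = "-"), "\n")
  }
})

setMethod("show", "ExpressionStudy", function(object) {
  fc <- table(featureClass(object))
  cond <- table(sampleCondition(object))
  cat("ExpressionStudy:", nrow(object), "features x", ncol(object),
      "samples\n")
  cat("  features:", paste(sprintf("%d %s", as.integer(fc), names(fc)),
                           collapse = ", "), "\n")
  cat("  samples :", paste(sprintf("%d %s", as.integer(cond), names(cond)),
                           collapse = ", "),
      sprintf("(%d pairs)\n", length(unique(samplePair(object)))))
})

setMethod("show", "FFLNull", function(object) {
  cat("FFLNull:", object@nDraws, "random-triple scores (seed",
      paste0(object@seed, ")\n"))
  cat("  quartiles:",
      paste(.fmtNum(quantile(object@scores, c(.25, .5, .75))),
            collapse = " / "), "\n")
})
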