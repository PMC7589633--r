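#' @import methods
#' @importFrom stats pnorm qnorm pt phyper setNames var sd cor p.adjust
#'   fisher.test wilcox.test ks.test rnorm runif quantile
#' @importFrom utils head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame
NULL

.EDGE_CLASSES <- c("tf_gene", "tf_mirna", "mirna_gene", "mirna_tf")
.NODE_CLASSES <- c("TF", "miRNA", "gene")
.FFL_TYPES <- c("TF_FFL", "MIRNA_FFL", "FB_FFL")

#' RegulatoryNetwork: a typed TF/miRNA/gene regulation graph
#'
#' Directed graph over three disjoint node classes (\code{TF}, \code{miRNA},
#' \code{gene}) with four regulation classes: \code{tf_gene}, \code{tf_mirna},
#' \code{mirna_gene} and \code{mirna_tf}. A miRNA repressing a TF's transcript
#' is encoded as edge class \code{mirna_tf} so the target keeps node class
#' \code{TF}; mutual TF/miRNA regulation is therefore two distinct edges.
#' The class enforces the motif substrate's invariants: no self-loops, no
#' duplicated (source, target, class) triple, every endpoint declared with
#' exactly one node class.
#'
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{edge_class}, \code{provenance}.
#' @slot nodes data.frame with columns \code{id}, \code{node_class}.
#' @slot removedSelfLoops integer count of self-loops dropped at build time.
#' @seealso [buildNetwork()], [enumerateFFLs()]
#' @export
setClass("RegulatoryNetwork",
  slots = c(edges = "data.frame", nodes = "data.frame",
            removedSelfLoops = "integer"),
  prototype = list(
    edges = data.frame(source = character(), target = character(),
                       edge_class = character(), provenance = character(),
                       stringsAsFactors = FALSE),
    nodes = data.frame(id = character(), node_class = character(),
                       stringsAsFactors = FALSE),
    removedSelfLoops = 0L))

setValidity("RegulatoryNetwork", function(object) {
  e <- object@edges; n <- object@nodes
  msg <- character()
  if (!all(c("source", "target", "edge_class", "provenance") %in% names(e)))
    msg <- c(msg, "edges must have source/target/edge_class/provenance")
  if (!all(c("id", "node_class") %in% names(n)))
    msg <- c(msg, "nodes must have id/node_class")
  if (length(msg)) return(msg)
  if (anyDuplicated(n$id))
    msg <- c(msg, "a node id may carry only one node class")
  if (!all(e$edge_class %in% .EDGE_CLASSES))
    msg <- c(msg, "unknown edge_class")
  if (!all(n$node_class %in% .NODE_CLASSES))
    msg <- c(msg, "unknown node_class")
  if (any(e$source == e$target))
    msg <- c(msg, "self-loops are not allowed")
  if (anyDuplicated(e[c("source", "target", "edge_class")]))
    msg <- c(msg, "duplicate (source, target, edge_class) edges")
  if (!all(c(e$source, e$target) %in% n$id))
    msg <- c(msg, "edge endpoint not declared in nodes")
  if (length(msg)) msg else TRUE
})

#' GeneSetCollection: named gene/miRNA sets with an optional universe
#'
#' Lightweight container for GMT-style annotation: a named list of unique
#' member identifier vectors plus an optional universe. Used both for pathway
#' enrichment and for mapping pathways to body systems.
#'
#' @slot sets named list of character vectors (no empty sets).
#' @slot universe character vector; length 0 means unset.
#' @seealso [readGeneSets()], [hypergeomEnrichment()]
#' @export
setClass("GeneSetCollection",
  slots = c(sets = "list", universe = "character"),
  prototype = list(sets = list(), universe = character()))

setValidity("GeneSetCollection", function(object) {
  s <- object@sets
  msg <- character()
  if (length(s)) {
    if (is.null(names(s)) || any(names(s) == "") || anyDuplicated(names(s)))
      msg <- c(msg, "sets must have unique non-empty names")
    if (!all(vapply(s, is.character, logical(1))))
      msg <- c(msg, "set members must be character")
    if (any(vapply(s, length, integer(1)) == 0L))
      msg <- c(msg, "empty sets are not allowed")
    if (any(vapply(s, anyDuplicated, integer(1)) > 0L))
      msg <- c(msg, "duplicate members within a set")
  }
  if (length(msg)) msg else TRUE
})

#' ExpressionStudy: paired two-condition expression data
#'
#' A \linkS4class{SummarizedExperiment} carrying log2-scale expression for
#' genes and miRNAs together (one assay, \code{"exprs"}), with
#' \code{rowData(x)$featureClass} in \code{{"gene","miRNA"}} and
#' \code{colData} columns \code{condition} (\code{case}/\code{control}) and
#' \code{pairId} (donor). Every donor must appear exactly once per condition;
#' edge differential-coexpression scoring additionally requires more than 3
#' samples per condition (the standardised-difference denominator uses
#' \eqn{n - 3}).
#'
#' @seealso [ExpressionStudy()], [moderatedDE()], [scoreFFLs()]
#' @export
setClass("ExpressionStudy", contains = "SummarizedExperiment")

setValidity("ExpressionStudy", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("condition", "pairId") %in% names(cd)))
    return("colData must have 'condition' and 'pairId'")
  if (!"featureClass" %in% names(rd))
    return("rowData must have 'featureClass'")
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    return("assay 'exprs' is required")
  if (!all(cd$condition %in% c("case", "control")))
    msg <- c(msg, "condition must be 'case' or 'control'")
  if (!all(rd$featureClass %in% c("gene", "miRNA")))
    msg <- c(msg, "featureClass must be 'gene' or 'miRNA'")
  tab <- table(cd$pairId, cd$condition)
  if (length(tab) && !all(tab == 1L))
    msg <- c(msg, "every pairId must appear exactly once per condition")
  if (anyNA(SummarizedExperiment::assay(object, "exprs")))
    msg <- c(msg, "missing expression values are not allowed")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "unique feature identifiers (rownames) are required")
  if (length(msg)) msg else TRUE
})

#' FFLNull: permutation null distribution of FFL scores
#'
#' Scores of composition-matched random (TF, miRNA, gene) triples, scored
#' identically to observed FFLs; one shared null serves all FFLs.
#'
#' @slot scores numeric vector, one score per random triple.
#' @slot nDraws integer number of draws.
#' @slot seed integer seed the draw is reproducible from.
#' @seealso [permutationNull()], [empiricalPvalues()]
#' @export
setClass("FFLNull",
  slots = c(scores = "numeric", nDraws = "integer", seed = "integer"))

setValidity("FFLNull", function(object) {
  if (length(object@scores) != object@nDraws)
    return("length(scores) must equal nDraws")
  if (anyNA(object@scores)) return("null scores must be finite")
  TRUE
})
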