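# Regulatory-network and gene-set input/output.

#' Read a regulation edge list
#'
#' Reads a tab-separated edge list (source, target, optional provenance) and
#' stamps every row with one regulation class. Lines starting with \code{#}
#' and blank lines are skipped; a header line whose first two fields are
#' \code{source} and \code{target} (any case) is detected and dropped.
#' Self-loops are \emph{not} removed here — that happens in
#' [buildNetwork()] so removal can be counted once over the union.
#'
#' @param path TSV file path.
#' @param edge_class one of \code{"tf_gene"}, \code{"tf_mirna"},
#'   \code{"mirna_gene"}, \code{"mirna_tf"}.
#' @param provenance free-text source label recorded per edge; defaults to
#'   the file's base name.
#' @return data.frame with columns \code{source}, \code{target},
#'   \code{edge_class}, \code{provenance} (zero rows for an empty file).
#' @export
readRegulations <- function(path, edge_class, provenance = basename(path)) {
  edge_class <- match.arg(edge_class, .EDGE_CLASSES)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(source = character(), target = character(),
                      edge_class = character(), provenance = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L))
    stop("line ", lineno[which(nf < 2L)[1L]], " of ", path,
         " has fewer than 2 tab-separated fields", call. = FALSE)
  first <- tolower(trimws(fields[[1L]][1:2]))
  if (identical(first, c("source", "target"))) {
    fields <- fields[-1L]
    if (!length(fields)) return(empty)
  }
  src <- trimws(vapply(fields, `[[`, character(1), 1L))
  tgt <- trimws(vapply(fields, `[[`, character(1), 2L))
  data.frame(source = src, target = tgt, edge_class = edge_class,
             provenance = provenance, stringsAsFactors = FALSE)
}

# Derive the node class table for a set of regulations, enforcing disjoint
# TF/miRNA/gene roles. A TF appearing as a tf_gene *target* stays a TF
# (TF-TF transcriptional regulation); every other cross-class appearance is
# a modelling error we refuse to repair silently.
.deriveNodeClasses <- function(reg) {
  tf <- unique(c(reg$source[reg$edge_class %in% c("tf_gene", "tf_mirna")],
                 reg$target[reg$edge_class == "mirna_tf"]))
  mir <- unique(c(reg$source[reg$edge_class %in% c("mirna_gene", "mirna_tf")],
                  reg$target[reg$edge_class == "tf_mirna"]))
  gene_tf_target <- unique(reg$target[reg$edge_class == "tf_gene"])
  gene_mir_target <- unique(reg$target[reg$edge_class == "mirna_gene"])
  conflicts <- .lexSort(unique(c(
    intersect(tf, mir),
    intersect(mir, c(gene_tf_target, gene_mir_target)),
    intersect(tf, gene_mir_target))))
  if (length(conflicts))
    stop("node class conflict for: ", paste(conflicts, collapse = ", "),
         " (a node id must have exactly one of TF/miRNA/gene;",
         " miRNA->TF regulation must use edge class 'mirna_tf')",
         call. = FALSE)
  gene <- setdiff(unique(c(gene_tf_target, gene_mir_target)), tf)
  nodes <- data.frame(
    id = c(tf, mir, gene),
    node_class = rep(c("TF", "miRNA", "gene"),
                     c(length(tf), length(mir), length(gene))),
    stringsAsFactors = FALSE)
  nodes[.lexOrder(nodes$node_class, nodes$id), , drop = FALSE]
}

#' Build a RegulatoryNetwork from regulation tables
#'
#' Takes the union of one or more regulation tables (as returned by
#' [readRegulations()]), removes self-loops, collapses duplicate
#' (source, target, class) edges while concatenating their provenance, and
#' derives node classes from the edge classes. Conflicting node classes
#' raise an error listing the offending identifiers.
#'
#' @param regulations a data.frame of regulations or a list of them.
#' @return a \linkS4class{RegulatoryNetwork}.
#' @examples
#' reg <- data.frame(source = c("T1", "T1", "m1"),
#'                   target = c("G1", "m1", "G1"),
#'                   edge_class = c("tf_gene", "tf_mirna", "mirna_gene"),
#'                   provenance = "toy")
#' buildNetwork(reg)
#' @export
buildNetwork <- function(regulations) {
  if (is.data.frame(regulations)) regulations <- list(regulations)
  reg <- do.call(rbind, regulations)
  need <- c("source", "target", "edge_class")
  if (is.null(reg) || !all(need %in% names(reg)))
    stop("regulations need source/target/edge_class columns", call. = FALSE)
  if (!"provenance" %in% names(reg)) reg$provenance <- ""
  if (!all(reg$edge_class %in% .EDGE_CLASSES))
    stop("unknown edge_class value(s)", call. = FALSE)
  self <- reg$source == reg$target
  n_self <- sum(self)
  reg <- reg[!self, , drop = FALSE]
  if (nrow(reg)) {
    key <- paste(reg$source, reg$target, reg$edge_class, sep = "\r")
    prov <- vapply(split(reg$provenance, key), function(p)
      paste(.lexSort(unique(p[nzchar(p)])), collapse = ";"), character(1))
    reg <- reg[!duplicated(key), , drop = FALSE]
    reg$provenance <- as.character(prov[paste(reg$source, reg$target,
                                              reg$edge_class, sep = "\r")])
    reg <- reg[.lexOrder(reg$edge_class, reg$source, reg$target), ,
               drop = FALSE]
  }
  rownames(reg) <- NULL
  nodes <- .deriveNodeClasses(reg)
  methods::new("RegulatoryNetwork", edges = reg, nodes = nodes,
               removedSelfLoops = as.integer(n_self))
}

#' Total-degree table and power-law fit
#'
#' Computes each node's total degree (in + out over all edge classes) and a
#' least-squares fit of log10(frequency) on log10(degree) over the non-empty
#' degree bins — the conventional check that a regulatory network's degree
#' distribution is approximately scale-free.
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @return list with \code{degrees} (data.frame id, node_class, degree) and
#'   \code{fit} (list slope, intercept, r_squared, n_bins) — \code{fit} is
#'   \code{NULL} with a warning when fewer than 2 distinct degree values
#'   exist.
#' @export
degreeDistribution <- function(network) {
  stopifnot(is(network, "RegulatoryNetwork"))
  e <- networkEdges(network)
  nodes <- networkNodes(network)
  deg <- table(factor(c(e$source, e$target), levels = nodes$id))
  degrees <- data.frame(id = nodes$id, node_class = nodes$node_class,
                        degree = as.integer(deg[nodes$id]),
                        stringsAsFactors = FALSE)
  pos <- degrees$degree[degrees$degree > 0L]
  fit <- NULL
  if (length(unique(pos)) >= 2L) {
    freq <- table(pos)
    x <- log10(as.numeric(names(freq)))
    y <- log10(as.numeric(freq))
    fit_lm <- stats::lm.fit(cbind(1, x), y)
    ss_res <- sum(fit_lm$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    fit <- list(slope = unname(fit_lm$coefficients[2L]),
                intercept = unname(fit_lm$coefficients[1L]),
                r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                n_bins = length(x))
  } else {
    warning("fewer than 2 distinct positive degrees; power-law fit undefined")
  }
  list(degrees = degrees, fit = fit)
}

#' Read a GMT gene-set file
#'
#' GMT dialect: one set per line, tab-separated \code{name}, \code{description},
#' then members. Members are de-duplicated within a set; descriptions are
#' stored as an attribute but unused downstream.
#'
#' @param path GMT file path.
#' @param universe optional character vector of identifiers.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGeneSets <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("GMT line with fewer than 3 fields (name, description, members)",
         call. = FALSE)
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate gene-set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- nm
  out <- GeneSetCollection(sets, universe = universe)
  attr(out@sets, "description") <- setNames(desc, nm)
  out
}

#' Construct a GeneSetCollection
#'
#' @param sets named list of character member vectors.
#' @param universe optional identifier universe.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
GeneSetCollection <- function(sets, universe = NULL) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  methods::new("GeneSetCollection", sets = sets,
               universe = if (is.null(universe)) character()
                          else as.character(universe))
}

#' Write a network to disk
#'
#' \code{tsv} writes the full edge table (round-trip safe via
#' [readNetworkTSV()]); \code{sif} writes Cytoscape SIF lines
#' \code{source<TAB>edge_class<TAB>target}; \code{graphml} delegates to
#' \pkg{igraph} with node class and edge class attributes.
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param path output file.
#' @param format one of \code{"tsv"}, \code{"sif"}, \code{"graphml"}.
#' @return the path, invisibly.
#' @export
writeNetwork <- function(network, path, format = c("tsv", "sif", "graphml")) {
  stopifnot(is(network, "RegulatoryNetwork"))
  format <- match.arg(format)
  e <- networkEdges(network)
  if (format == "tsv") {
    .writeTsv(e, path)
  } else if (format == "sif") {
    writeLines(if (nrow(e)) paste(e$source, e$edge_class, e$target,
                                  sep = "\t") else character(), path)
  } else {
    g <- .asIgraph(network)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

.asIgraph <- function(network) {
  n <- networkNodes(network)
  e <- networkEdges(network)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = e$source, to = e$target,
                   edge_class = e$edge_class, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = n$id, node_class = n$node_class,
                          stringsAsFactors = FALSE))
  g
}

#' Read back a TSV network written by [writeNetwork()]
#'
#' @param path TSV file with header source/target/edge_class/provenance.
#' @return a \linkS4class{RegulatoryNetwork}.
#' @export
readNetworkTSV <- function(path) {
  df <- .readTsv(path, header = TRUE)
  if (nrow(df) == 0L)
    return(methods::new("RegulatoryNetwork"))
  if (!"provenance" %in% names(df)) df$provenance <- ""
  df$provenance[is.na(df$provenance)] <- ""
  buildNetwork(df)
}
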