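# Body-system assignment of FFLs, subnetwork merging, sharing analysis,
# and hypergeometric gene-set enrichment.

#' Assign dysregulated FFLs to body systems
#'
#' An FFL belongs to a body system when \emph{all three} of its nodes (TF,
#' miRNA, gene) are members of at least one annotation set mapped to that
#' system. Gene and miRNA annotations travel through the same
#' \linkS4class{GeneSetCollection} mechanism.
#'
#' @param ffls FFL rows (tf, mirna, gene, ...).
#' @param annotations a \linkS4class{GeneSetCollection} of pathway-like sets.
#' @param system_map named list: system name -> character vector of set
#'   names in \code{annotations}. A mapped set name absent from
#'   \code{annotations} is an error.
#' @return list: \code{systems} (character vector of system names),
#'   \code{membership} (logical matrix FFLs x systems), \code{counts}
#'   (named integer per system), \code{ffls} (the input, with a
#'   \code{systems} column of semicolon-joined assignments).
#' @export
assignSystemFFLs <- function(ffls, annotations, system_map) {
  stopifnot(is(annotations, "GeneSetCollection"))
  if (!length(system_map) || is.null(names(system_map)))
    stop("system_map must be a named list", call. = FALSE)
  sets <- geneSets(annotations)
  unknown <- setdiff(unique(unlist(system_map)), names(sets))
  if (length(unknown))
    stop("system_map references unknown set(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  systems <- names(system_map)
  membership <- matrix(FALSE, nrow(ffls), length(systems),
                       dimnames = list(NULL, systems))
  for (s in systems) {
    members <- unique(unlist(sets[system_map[[s]]]))
    membership[, s] <- ffls$tf %in% members & ffls$mirna %in% members &
      ffls$gene %in% members
  }
  ffls$systems <- apply(membership, 1L, function(row)
    paste(systems[row], collapse = ";"))
  list(systems = systems, membership = membership,
       counts = setNames(as.integer(colSums(membership)), systems),
       ffls = ffls)
}

#' System-specific vs system-general FFLs
#'
#' Partitions system-assigned FFLs by how many systems they serve: specific
#' FFLs belong to exactly one system; general FFLs are shared by at least
#' \code{general_min} systems (default 3).
#'
#' @param assignment result of [assignSystemFFLs()].
#' @param general_min minimum number of systems for "general".
#' @return list: \code{n_systems} per FFL, \code{specific} and
#'   \code{general} (row indices into \code{assignment$ffls}), and
#'   \code{breakdown} (named counts: unassigned, specific, intermediate,
#'   general — a partition of all FFLs when \code{general_min >= 2}).
#' @export
sharingAnalysis <- function(assignment, general_min = 3L) {
  m <- assignment$membership
  if (ncol(m) < 2L) stop("need at least 2 systems", call. = FALSE)
  n_sys <- rowSums(m)
  specific <- which(n_sys == 1L)
  general <- which(n_sys >= general_min)
  breakdown <- c(
    unassigned = sum(n_sys == 0L),
    specific = length(specific),
    intermediate = sum(n_sys > 1L & n_sys < general_min),
    general = length(general))
  list(n_systems = n_sys, specific = specific, general = general,
       breakdown = breakdown)
}

#' Merge per-system subnetworks and their overlaps
#'
#' For each system, merges the nodes and typed edges of its FFLs into a
#' \linkS4class{RegulatoryNetwork}; also reports cross-system node and edge
#' overlap counts (how many nodes/edges appear in >= 2 subnetworks) and the
#' pairwise overlap matrices.
#'
#' @param assignment result of [assignSystemFFLs()].
#' @return list: \code{subnetworks} (named list, NULL where a system has no
#'   FFL), \code{node_overlap}, \code{edge_overlap} (lists with
#'   \code{shared}, \code{total}, \code{fraction}, \code{pairwise}).
#' @export
mergeSystemSubnetworks <- function(assignment) {
  systems <- assignment$systems
  ffls <- assignment$ffls
  subnetworks <- setNames(vector("list", length(systems)), systems)
  node_sets <- edge_sets <- setNames(vector("list", length(systems)), systems)
  for (s in systems) {
    rows <- ffls[assignment$membership[, s], , drop = FALSE]
    if (!nrow(rows)) next
    e <- .fflEdges(rows)
    e$provenance <- ""
    net <- buildNetwork(e)
    subnetworks[[s]] <- net
    node_sets[[s]] <- networkNodes(net)$id
    ee <- networkEdges(net)
    edge_sets[[s]] <- paste(ee$source, ee$target, ee$edge_class, sep = "\r")
  }
  overlap <- function(sets) {
    sets <- sets[!vapply(sets, is.null, logical(1))]
    items <- unlist(sets, use.names = FALSE)
    total <- length(unique(items))
    shared <- sum(table(unlist(lapply(sets, unique))) >= 2L)
    pairwise <- outer(seq_along(sets), seq_along(sets),
                      Vectorize(function(i, j)
                        length(intersect(sets[[i]], sets[[j]]))))
    dimnames(pairwise) <- list(names(sets), names(sets))
    list(shared = shared, total = total,
         fraction = if (total) shared / total else NA_real_,
         pairwise = pairwise)
  }
  list(subnetworks = subnetworks,
       node_overlap = overlap(node_sets),
       edge_overlap = overlap(edge_sets))
}

#' Top-degree nodes of a subnetwork
#'
#' Ranks nodes by total degree, descending, ties broken lexicographically by
#' identifier (deterministic across runs), and returns the top \code{k}.
#'
#' @param subnetwork a \linkS4class{RegulatoryNetwork}.
#' @param k number of nodes (truncated to the node count).
#' @return data.frame: id, node_class, degree.
#' @export
topDegreeNodes <- function(subnetwork, k) {
  stopifnot(k >= 1)
  dd <- degreeDistribution(subnetwork)$degrees
  dd <- dd[.lexOrder(-dd$degree, dd$id), , drop = FALSE]
  out <- head(dd, k)
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set over-representation
#'
#' Local stand-in for web enrichment services: for each set, the upper-tail
#' hypergeometric probability of drawing at least the observed overlap when
#' \code{|query|} identifiers are drawn from the universe, with BH
#' correction across sets. Set membership outside the universe is ignored.
#'
#' @param query character identifiers (must lie inside \code{universe}).
#' @param gene_sets a \linkS4class{GeneSetCollection}.
#' @param universe character identifiers; defaults to the collection's own
#'   universe.
#' @return data.frame: set, set_size, overlap, p_value, fdr — sorted by
#'   p then set name.
#' @export
hypergeomEnrichment <- function(query, gene_sets, universe = NULL) {
  stopifnot(is(gene_sets, "GeneSetCollection"))
  if (is.null(universe)) universe <- setUniverse(gene_sets)
  if (is.null(universe))
    stop("a universe is required (argument or collection slot)",
         call. = FALSE)
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query must be a subset of the universe", call. = FALSE)
  N <- length(universe)
  n <- length(query)
  res <- lapply(names(geneSets(gene_sets)), function(nm) {
    members <- intersect(geneSets(gene_sets)[[nm]], universe)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- if (k == 0L) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out <- out[.lexOrder(out$p_value, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a system map TSV
#'
#' Two tab-separated columns: system name, pathway/set name; '#' comments
#' allowed. Returns the named list [assignSystemFFLs()] expects.
#'
#' @param path TSV path.
#' @return named list of character vectors.
#' @export
readSystemMap <- function(path) {
  df <- .readTsv(path, header = FALSE)
  if (ncol(df) < 2L) stop("system map needs 2 columns", call. = FALSE)
  lapply(split(as.character(df[[2L]]), as.character(df[[1L]])), unique)
}
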