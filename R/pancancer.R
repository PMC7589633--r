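# Rank-shift concordance between the perturbation signature and external
# cancer differential-expression lists.

#' Rank a DE table into a perturbation signature
#'
#' Orders genes by descending log2 fold change (rank 1 = most upregulated in
#' the perturbation); ties are broken lexicographically by feature id so the
#' ranking is deterministic.
#'
#' @param de_table data.frame with \code{feature} and \code{log2FC} columns
#'   (duplicated features are an error).
#' @return data.frame: feature, log2FC, rank.
#' @export
rankSignature <- function(de_table) {
  if (anyDuplicated(de_table$feature))
    stop("duplicate feature ids in the DE table", call. = FALSE)
  ord <- .lexOrder(-de_table$log2FC, de_table$feature)
  out <- data.frame(feature = de_table$feature[ord],
                    log2FC = de_table$log2FC[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' One-sided rank-shift Wilcoxon test
#'
#' Tests whether a gene set sits toward the top (most upregulated) or the
#' bottom of a ranked perturbation signature, via a one-sided Wilcoxon
#' rank-sum (Mann-Whitney) test of the set's ranks against the remaining
#' ranks. The exact distribution is used when the smaller group has at most
#' 25 members (ranks are distinct, so no ties arise); otherwise the normal
#' approximation with continuity correction. Set members absent from the
#' signature are dropped; the count is reported via
#' \code{attr(p, "n_dropped")}.
#'
#' @param signature data.frame from [rankSignature()].
#' @param de_set character gene ids.
#' @param side \code{"top"} tests for smaller ranks, \code{"bottom"} for
#'   larger ranks.
#' @return one-sided p-value with attribute \code{n_dropped}.
#' @export
rankShiftTest <- function(signature, de_set, side = c("top", "bottom")) {
  side <- match.arg(side)
  de_set <- unique(de_set)
  in_sig <- de_set %in% signature$feature
  n_dropped <- sum(!in_sig)
  hits <- de_set[in_sig]
  if (!length(hits))
    stop("no DE-set gene is present in the signature universe",
         call. = FALSE)
  if (length(hits) == nrow(signature))
    stop("DE set equals the whole universe; rank-shift undefined",
         call. = FALSE)
  is_hit <- signature$feature %in% hits
  x <- signature$rank[is_hit]
  y <- signature$rank[!is_hit]
  exact <- min(length(x), length(y)) <= 25L
  wt <- suppressWarnings(wilcox.test(
    x, y, alternative = if (side == "top") "less" else "greater",
    exact = exact, correct = TRUE))
  p <- wt$p.value
  attr(p, "n_dropped") <- n_dropped
  p
}

#' Run all four rank-shift patterns for one cancer
#'
#' Computes up-top, up-bottom, down-top and down-bottom one-sided p-values
#' for a cancer's up/down DE gene sets against the perturbation signature.
#' An empty (or fully absent) up or down set yields p = 1 for its two
#' patterns, flagged in \code{undefined}.
#'
#' @param signature data.frame from [rankSignature()].
#' @param cancer_de list with character vectors \code{up} and \code{down}.
#' @return named numeric vector (up_top, up_bottom, down_top, down_bottom)
#'   with attributes \code{undefined} and \code{n_dropped}.
#' @export
patternTest <- function(signature, cancer_de) {
  p <- c(up_top = 1, up_bottom = 1, down_top = 1, down_bottom = 1)
  undefined <- character()
  dropped <- 0L
  for (dir in c("up", "down")) {
    set <- intersect(unique(cancer_de[[dir]]), signature$feature)
    dropped <- dropped + length(unique(cancer_de[[dir]])) - length(set)
    if (!length(set) || length(set) == nrow(signature)) {
      undefined <- c(undefined, paste0(dir, "_top"), paste0(dir, "_bottom"))
      next
    }
    p[paste0(dir, "_top")] <- as.numeric(rankShiftTest(signature, set, "top"))
    p[paste0(dir, "_bottom")] <-
      as.numeric(rankShiftTest(signature, set, "bottom"))
  }
  attr(p, "undefined") <- undefined
  attr(p, "n_dropped") <- dropped
  p
}

#' Classify rank-shift patterns as consistent / reverse
#'
#' Significant up-top or down-bottom patterns mean the cancer's DE genes move
#' with the perturbation ("consistent"); significant up-bottom or down-top
#' mean they move against it ("reverse"). Both labels can co-occur (a
#' conflicting trend). Default alpha 0.1.
#'
#' @param p_values named numeric vector as returned by [patternTest()].
#' @param alpha significance cutoff in (0,1).
#' @return list: \code{significant} (pattern names with p <= alpha),
#'   \code{consistent}, \code{reverse} (logical), \code{labels}
#'   (character vector, possibly empty).
#' @export
classifyPatterns <- function(p_values, alpha = 0.1) {
  stopifnot(alpha > 0, alpha < 1)
  need <- c("up_top", "up_bottom", "down_top", "down_bottom")
  if (!all(need %in% names(p_values)))
    stop("p_values must be named: ", paste(need, collapse = ", "),
         call. = FALSE)
  sig <- names(p_values)[p_values <= alpha]
  consistent <- any(c("up_top", "down_bottom") %in% sig)
  reverse <- any(c("up_bottom", "down_top") %in% sig)
  labels <- c(if (consistent) "consistent", if (reverse) "reverse")
  list(significant = sig, consistent = consistent, reverse = reverse,
       labels = if (is.null(labels)) character() else labels)
}

#' Same-direction overlap of two DE signatures
#'
#' Genes differentially expressed in both sources with matching direction:
#' \code{(pert.up intersect cancer.up) union (pert.down intersect
#' cancer.down)}.
#'
#' @param pert_de,cancer_de lists with disjoint \code{up}/\code{down}
#'   character vectors.
#' @return character vector of shared same-direction genes.
#' @export
sameDirectionOverlap <- function(pert_de, cancer_de) {
  for (s in list(pert_de, cancer_de))
    if (length(intersect(s$up, s$down)))
      stop("up and down sets must be disjoint within a source",
           call. = FALSE)
  .lexSort(union(intersect(pert_de$up, cancer_de$up),
                 intersect(pert_de$down, cancer_de$down)))
}

#' Read a cancer DE gene list
#'
#' TSV with header columns \code{gene}, \code{log2FC}, \code{FDR},
#' \code{direction} (\code{up}/\code{down}).
#'
#' @param path TSV path.
#' @return list: \code{table} (data.frame), \code{up}, \code{down}
#'   (character vectors).
#' @export
readCancerDE <- function(path) {
  df <- .readTsv(path, header = TRUE)
  need <- c("gene", "log2FC", "FDR", "direction")
  if (!all(need %in% names(df)))
    stop("cancer DE list needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  list(table = df,
       up = unique(df$gene[df$direction == "up"]),
       down = unique(df$gene[df$direction == "down"]))
}
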