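# Signature-reversal drug screening: miRNA-expression inhibitors by target
# coverage, and gene-signature reversers by opposite-direction counting.

#' Screen drugs that inhibit a set of miRNAs
#'
#' Given a drug-to-miRNA effect table, counts for each drug how many of the
#' target miRNAs it shifts in \code{target_direction} (default \code{down} —
#' inhibition of perturbation-elevated miRNAs). (drug, miRNA) pairs recorded
#' with \emph{both} directions are contradictory evidence and are excluded
#' from coverage with a warning. Drugs with coverage >= 1 are returned,
#' ranked by descending coverage, ties broken lexicographically by drug name.
#'
#' @param table data.frame with columns \code{drug}, \code{mirna},
#'   \code{effect} (\code{up}/\code{down}); extra columns ignored.
#' @param target_mirnas non-empty character vector of miRNA ids.
#' @param target_direction effect direction that counts (default
#'   \code{"down"}).
#' @return data.frame: drug, coverage, covered (semicolon-joined miRNAs).
#' @export
screenMirnaInhibitors <- function(table, target_mirnas,
                                  target_direction = c("down", "up")) {
  target_direction <- match.arg(target_direction)
  if (!length(target_mirnas))
    stop("target_mirnas must be non-empty", call. = FALSE)
  stopifnot(all(c("drug", "mirna", "effect") %in% names(table)))
  if (!all(table$effect %in% c("up", "down")))
    stop("effect must be 'up' or 'down'", call. = FALSE)
  tab <- unique(table[c("drug", "mirna", "effect")])
  key <- paste(tab$drug, tab$mirna, sep = "\r")
  conflicted <- unique(key[duplicated(key)])
  if (length(conflicted)) {
    warning(length(conflicted), " (drug, miRNA) pair(s) with contradictory ",
            "up/down records excluded from coverage")
    tab <- tab[!key %in% conflicted, , drop = FALSE]
  }
  hits <- tab[tab$effect == target_direction &
                tab$mirna %in% target_mirnas, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(drug = character(), coverage = integer(),
                      covered = character(), stringsAsFactors = FALSE))
  cov <- lapply(split(hits$mirna, hits$drug), function(m) .lexSort(unique(m)))
  out <- data.frame(drug = names(cov),
                    coverage = vapply(cov, length, integer(1)),
                    covered = vapply(cov, paste, character(1),
                                     collapse = ";"),
                    stringsAsFactors = FALSE)
  out <- out[.lexOrder(-out$coverage, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen drugs that reverse a gene signature
#'
#' A drug reverses gene g when g is up in the perturbation and the drug
#' pushes it down, or vice versa. Drugs reversing at least
#' \code{min_reversed} genes (default 3) pass; results are ranked by
#' descending reversal count, ties lexicographic.
#'
#' @param signatures data.frame with columns \code{drug}, \code{gene},
#'   \code{direction} (\code{up}/\code{down}), one direction per
#'   (drug, gene).
#' @param pert_de list with disjoint \code{up}/\code{down} character
#'   vectors (non-empty overall).
#' @param min_reversed pass threshold (default 3).
#' @return list: \code{all} (data.frame drug, n_reversed, reversed),
#'   \code{passing} (subset with n_reversed >= min_reversed).
#' @export
signatureReversal <- function(signatures, pert_de, min_reversed = 3L) {
  if (!length(pert_de$up) && !length(pert_de$down))
    stop("perturbation DE sets are empty", call. = FALSE)
  if (length(intersect(pert_de$up, pert_de$down)))
    stop("perturbation up/down sets must be disjoint", call. = FALSE)
  stopifnot(all(c("drug", "gene", "direction") %in% names(signatures)))
  sig <- unique(signatures[c("drug", "gene", "direction")])
  key <- paste(sig$drug, sig$gene, sep = "\r")
  if (anyDuplicated(key))
    stop("a (drug, gene) pair carries two directions", call. = FALSE)
  reversed <- (sig$gene %in% pert_de$up & sig$direction == "down") |
    (sig$gene %in% pert_de$down & sig$direction == "up")
  rev_sets <- lapply(split(sig$gene[reversed], sig$drug[reversed]),
                     function(g) .lexSort(unique(g)))
  drugs <- .lexSort(unique(sig$drug))
  n_rev <- vapply(drugs, function(d) length(rev_sets[[d]]), integer(1))
  all_df <- data.frame(
    drug = drugs, n_reversed = n_rev,
    reversed = vapply(drugs, function(d)
      paste(rev_sets[[d]], collapse = ";"), character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  all_df <- all_df[.lexOrder(-all_df$n_reversed, all_df$drug), , drop = FALSE]
  rownames(all_df) <- NULL
  list(all = all_df,
       passing = all_df[all_df$n_reversed >= min_reversed, , drop = FALSE])
}

#' Read a drug-to-miRNA effect table
#'
#' TSV with header columns \code{drug}, \code{mirna}, \code{effect}
#' (\code{up}/\code{down}) and optional \code{source}.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readDrugMirnaTable <- function(path) {
  df <- .readTsv(path, header = TRUE)
  if (!all(c("drug", "mirna", "effect") %in% names(df)))
    stop("drug-miRNA table needs drug/mirna/effect columns", call. = FALSE)
  df
}

#' Read drug gene-direction signatures
#'
#' TSV with header columns \code{drug}, \code{gene}, \code{direction}.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readDrugSignatures <- function(path) {
  df <- .readTsv(path, header = TRUE)
  if (!all(c("drug", "gene", "direction") %in% names(df)))
    stop("drug signature table needs drug/gene/direction columns",
         call. = FALSE)
  df
}
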