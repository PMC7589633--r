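# Expression preprocessing and paired moderated-t differential expression.

#' Construct an ExpressionStudy
#'
#' Binds a gene matrix and a miRNA matrix (same columns: samples) into one
#' \linkS4class{ExpressionStudy} with per-row feature classes and per-column
#' condition/donor metadata. Values are expected on the log2 scale, already
#' normalised (see [quantileNormalize()]).
#'
#' @param gene_matrix,mirna_matrix numeric matrices, features x samples, with
#'   rownames; \code{mirna_matrix} may be \code{NULL}.
#' @param condition character/factor per sample: \code{"case"} or
#'   \code{"control"}.
#' @param pair_id character per sample: donor identifier; each donor must
#'   appear exactly once per condition.
#' @return an \linkS4class{ExpressionStudy}.
#' @export
ExpressionStudy <- function(gene_matrix, mirna_matrix = NULL, condition,
                            pair_id) {
  gene_matrix <- as.matrix(gene_matrix)
  mats <- list(gene_matrix)
  fclass <- rep("gene", nrow(gene_matrix))
  if (!is.null(mirna_matrix)) {
    mirna_matrix <- as.matrix(mirna_matrix)
    if (ncol(mirna_matrix) != ncol(gene_matrix))
      stop("gene and miRNA matrices must share the same samples",
           call. = FALSE)
    mats <- c(mats, list(mirna_matrix))
    fclass <- c(fclass, rep("miRNA", nrow(mirna_matrix)))
  }
  mat <- do.call(rbind, mats)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = mat),
    rowData = S4Vectors::DataFrame(featureClass = fclass),
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   pairId = as.character(pair_id)))
  methods::as(se, "ExpressionStudy")
}

#' Quantile-normalise an expression matrix
#'
#' Forces every column onto the common reference distribution of per-rank row
#' means: after normalisation every column's sorted value vector equals the
#' reference exactly, except that tied values within a column receive the
#' mean of their tied ranks' reference values (average-rank convention).
#'
#' @param mat numeric matrix, features x samples, no missing values,
#'   at least 2 columns.
#' @return matrix of the same shape and dimnames.
#' @examples
#' quantileNormalize(matrix(c(1, 5, 3, 7), 2))  # both columns become (2, 6)
#' @export
quantileNormalize <- function(mat) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("missing values are not allowed", call. = FALSE)
  if (ncol(mat) < 2L) stop("need at least 2 columns", call. = FALSE)
  ref <- rowMeans(apply(mat, 2L, sort))
  out <- apply(mat, 2L, function(col) {
    rk <- rank(col, ties.method = "average")
    lo <- ref[floor(rk)]
    hi <- ref[ceiling(rk)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Collapse probe-level rows to feature-level rows
#'
#' Replaces the probe rows mapping to one feature by their arithmetic mean,
#' per sample — the conventional multiple-probe summarisation for two-colour
#' and one-colour arrays.
#'
#' @param mat numeric matrix with probe rownames.
#' @param probe_to_feature named character vector \code{probe -> feature}, or
#'   a 2-column data.frame (probe, feature). A probe mapping to two distinct
#'   features is an error.
#' @param unmapped \code{"error"} (default) or \code{"drop"} for probes
#'   absent from the map.
#' @return numeric matrix with feature rownames, rows sorted lexicographically.
#' @export
collapseProbes <- function(mat, probe_to_feature,
                           unmapped = c("error", "drop")) {
  unmapped <- match.arg(unmapped)
  mat <- as.matrix(mat)
  if (is.data.frame(probe_to_feature)) {
    map <- setNames(as.character(probe_to_feature[[2L]]),
                    as.character(probe_to_feature[[1L]]))
  } else map <- probe_to_feature
  pairs <- unique(data.frame(probe = names(map), feature = unname(map),
                             stringsAsFactors = FALSE))
  bad <- unique(pairs$probe[duplicated(pairs$probe)])
  if (length(bad))
    stop("probe(s) mapped to two features: ", paste(bad, collapse = ", "),
         call. = FALSE)
  map <- setNames(pairs$feature, pairs$probe)
  missing <- setdiff(rownames(mat), names(map))
  if (length(missing)) {
    if (unmapped == "error")
      stop(length(missing), " probe(s) not mapped, e.g. ",
           paste(head(missing, 3L), collapse = ", "),
           "; use unmapped = 'drop' to discard them", call. = FALSE)
    mat <- mat[setdiff(rownames(mat), missing), , drop = FALSE]
  }
  grp <- map[rownames(mat)]
  sums <- rowsum(mat, group = grp, reorder = TRUE)
  counts <- as.vector(table(grp)[rownames(sums)])
  out <- sums / counts
  out[.lexOrder(rownames(out)), , drop = FALSE]
}

# Squeeze per-feature variances toward a common prior (empirical Bayes).
# prior_df NULL -> estimated by limma::squeezeVar; 0 -> no squeeze (ordinary
# t); Inf -> fully pooled variance (z-like test).
.squeeze <- function(s2, df, prior_df = NULL) {
  if (!is.null(prior_df) && prior_df == 0)
    return(list(var_post = s2, df_prior = 0))
  if (!is.null(prior_df) && is.infinite(prior_df))
    return(list(var_post = rep(mean(s2), length(s2)), df_prior = Inf))
  sq <- limma::squeezeVar(s2, df = df)
  if (!is.null(prior_df)) {
    vp <- sq$var.prior
    return(list(var_post = (prior_df * vp + df * s2) / (prior_df + df),
                df_prior = prior_df))
  }
  list(var_post = sq$var.post, df_prior = sq$df.prior)
}

#' Moderated differential expression for a paired two-condition study
#'
#' For each feature, computes the log2 fold change (case minus control) and an
#' empirical-Bayes moderated t statistic: per-feature variances are squeezed
#' toward a pooled prior with estimated prior degrees of freedom, and the
#' two-sided p-value uses the augmented degrees of freedom. In the paired
#' default the unit of analysis is the within-donor difference. BH FDR is
#' computed separately within each feature class (gene, miRNA), matching the
#' two separate array platforms such studies use. The per-feature
#' dysregulation contribution is \code{diff_score = (-log10 p) * |log2FC|}.
#'
#' @param study an \linkS4class{ExpressionStudy}.
#' @param paired logical; \code{TRUE} (default) pairs samples by donor.
#' @param prior_df \code{NULL} to estimate the prior degrees of freedom
#'   (default); \code{0} recovers the ordinary t-test; \code{Inf} the fully
#'   pooled-variance z-like test.
#' @return data.frame: feature, class, log2FC, t, p_value, fdr, diff_score.
#' @export
moderatedDE <- function(study, paired = TRUE, prior_df = NULL) {
  stopifnot(is(study, "ExpressionStudy"))
  mat <- SummarizedExperiment::assay(study, "exprs")
  cond <- sampleCondition(study)
  pair <- samplePair(study)
  case <- mat[, cond == "case", drop = FALSE]
  ctrl <- mat[, cond == "control", drop = FALSE]
  if (paired) {
    ctrl <- ctrl[, match(pair[cond == "case"], pair[cond == "control"]),
                 drop = FALSE]
    d <- case - ctrl
    n <- ncol(d)
    if (n < 2L) stop("paired design needs >= 2 pairs", call. = FALSE)
    lfc <- rowMeans(d)
    s2 <- apply(d, 1L, var)
    df <- n - 1L
    se2_scale <- 1 / n
  } else {
    n1 <- ncol(case); n2 <- ncol(ctrl)
    if (n1 < 2L || n2 < 2L)
      stop("unpaired design needs >= 2 samples per group", call. = FALSE)
    lfc <- rowMeans(case) - rowMeans(ctrl)
    s2 <- ((n1 - 1L) * apply(case, 1L, var) +
           (n2 - 1L) * apply(ctrl, 1L, var)) / (n1 + n2 - 2L)
    df <- n1 + n2 - 2L
    se2_scale <- 1 / n1 + 1 / n2
  }
  if (df < 1L) stop("zero residual degrees of freedom", call. = FALSE)
  constant <- s2 == 0 & lfc == 0
  sq <- .squeeze(pmax(s2, .Machine$double.xmin), df, prior_df)
  tstat <- lfc / sqrt(sq$var_post * se2_scale)
  df_total <- df + sq$df_prior
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(tstat))
       else 2 * pt(-abs(tstat), df = df_total)
  p[constant] <- 1
  tstat[constant] <- 0
  lfc[constant] <- 0
  fclass <- featureClass(study)
  fdr <- rep(NA_real_, length(p))
  for (cl in unique(fclass))
    fdr[fclass == cl] <- p.adjust(p[fclass == cl], method = "BH")
  diff_score <- (-log10(pmax(p, .Machine$double.xmin))) * abs(lfc)
  data.frame(feature = rownames(mat), class = unname(fclass),
             log2FC = unname(lfc), t = unname(tstat), p_value = unname(p),
             fdr = fdr, diff_score = unname(diff_score),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Threshold a DE table into up/down sets
#'
#' @param records data.frame from [moderatedDE()] (needs \code{feature},
#'   \code{log2FC}, \code{p_value}).
#' @param p_max p-value cutoff (default 0.05).
#' @param lfc_min minimum |log2FC| (default 1).
#' @param use_fdr use the \code{fdr} column instead of \code{p_value}.
#' @return list with disjoint character vectors \code{up} and \code{down}.
#' @export
deSets <- function(records, p_max = 0.05, lfc_min = 1, use_fdr = FALSE) {
  stopifnot(p_max > 0, lfc_min > 0)
  p <- if (use_fdr) records$fdr else records$p_value
  list(up = records$feature[p <= p_max & records$log2FC >= lfc_min],
       down = records$feature[p <= p_max & records$log2FC <= -lfc_min])
}
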