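# FFL enumeration, dysregulation scoring, permutation significance,
# dysregulated-network assembly, hubs, cancer-gene enrichment.

#' Scoring parameters
#'
#' \code{gamma} weights node against edge scores in the combined FFL score
#' (0.5 gives them equal weight, the published default). \code{clamp_eps}
#' floors/caps the inner probability of the inverse-normal transforms so the
#' scores stay finite at their boundaries (a null node with Diff = 0 maps to
#' the finite floor \code{qnorm(clamp_eps)}). \code{spearman_clamp} bounds
#' |r| away from 1 before the Fisher transform.
#'
#' @param gamma node-vs-edge weight in (0,1); default 0.5.
#' @param clamp_eps probability floor in (0, 0.5); default 1e-15.
#' @param spearman_clamp correlation bound < 1; default 1 - 1e-9.
#' @return list of validated parameters.
#' @export
scoreParams <- function(gamma = 0.5, clamp_eps = 1e-15,
                        spearman_clamp = 1 - 1e-9) {
  if (!(gamma > 0 && gamma < 1)) stop("gamma must be in (0,1)", call. = FALSE)
  if (!(clamp_eps > 0 && clamp_eps < 0.5))
    stop("clamp_eps must be in (0, 0.5)", call. = FALSE)
  if (!(spearman_clamp > 0 && spearman_clamp < 1))
    stop("spearman_clamp must be in (0,1)", call. = FALSE)
  list(gamma = gamma, clamp_eps = clamp_eps, spearman_clamp = spearman_clamp)
}

#' Enumerate feed-forward loops
#'
#' Finds every (TF, miRNA, gene) triple where the TF and the miRNA both
#' regulate the gene and at least one regulates the other, and classifies it:
#' \code{TF_FFL} (TF regulates miRNA), \code{MIRNA_FFL} (miRNA represses TF),
#' \code{FB_FFL} (both — the pair mutually regulate each other). Each triple
#' is emitted exactly once with exactly one type.
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @return data.frame: tf, mirna, gene, type (zero rows if no motif exists).
#' @export
enumerateFFLs <- function(network) {
  stopifnot(is(network, "RegulatoryNetwork"))
  e <- networkEdges(network)
  empty <- data.frame(tf = character(), mirna = character(),
                      gene = character(), type = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(e)) return(empty)
  split_targets <- function(cls) {
    sel <- e$edge_class == cls
    split(e$target[sel], e$source[sel])
  }
  tf2gene <- split_targets("tf_gene")
  mir2gene <- split_targets("mirna_gene")
  tf2mir <- e[e$edge_class == "tf_mirna", c("source", "target")]
  mir2tf <- e[e$edge_class == "mirna_tf", c("source", "target")]
  # candidate regulator pairs: any TF-miRNA pair linked in either direction
  pairs <- unique(rbind(
    data.frame(tf = tf2mir$source, mirna = tf2mir$target,
               stringsAsFactors = FALSE),
    data.frame(tf = mir2tf$target, mirna = mir2tf$source,
               stringsAsFactors = FALSE)))
  if (!nrow(pairs)) return(empty)
  fwd <- paste(tf2mir$source, tf2mir$target, sep = "\r")
  rev <- paste(mir2tf$target, mir2tf$source, sep = "\r")
  key <- paste(pairs$tf, pairs$mirna, sep = "\r")
  has_fwd <- key %in% fwd
  has_rev <- key %in% rev
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    genes <- intersect(tf2gene[[pairs$tf[i]]], mir2gene[[pairs$mirna[i]]])
    if (!length(genes)) next
    type <- if (has_fwd[i] && has_rev[i]) "FB_FFL"
            else if (has_fwd[i]) "TF_FFL" else "MIRNA_FFL"
    out[[i]] <- data.frame(tf = pairs$tf[i], mirna = pairs$mirna[i],
                           gene = genes, type = type,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[.lexOrder(out$tf, out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Node dysregulation score
#'
#' Maps a non-negative differential-expression magnitude
#' \code{Diff = (-log10 p) * |log2FC|} through the inverse-normal transform
#' \code{S = qnorm(2 * pnorm(Diff) - 1)} (the inner probability is clamped to
#' \code{[clamp_eps, 1 - clamp_eps]} so the score is always finite).
#' Strictly increasing in \code{Diff} over the unclamped range.
#'
#' @param diff_score non-negative Diff value(s).
#' @param clamp_eps probability floor; see [scoreParams()].
#' @return numeric score(s).
#' @examples
#' nodeScore(1.959964)  # ~ qnorm(0.95) = 1.644854
#' @export
nodeScore <- function(diff_score, clamp_eps = 1e-15) {
  if (any(diff_score < 0)) stop("diff_score must be >= 0", call. = FALSE)
  qnorm(.clampProb(2 * pnorm(diff_score) - 1, clamp_eps))
}

#' Fisher z-transform of a correlation
#'
#' \code{F(r) = atanh(r) = 0.5 * log((1 + r) / (1 - r))}; odd and strictly
#' increasing. Callers must clamp |r| below 1 first (see [scoreParams()]).
#'
#' @param r correlation(s), |r| < 1.
#' @return transformed value(s).
#' @export
fisherZ <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 after clamping", call. = FALSE)
  atanh(r)
}

.spearman <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

# Standardised difference of Fisher-z correlations; the 1.06/(n-3) terms are
# the conventional variance of a Fisher-z-transformed Spearman correlation.
.zDiff <- function(r_case, r_control, n_case, n_control, params) {
  rc <- pmin(pmax(r_case, -params$spearman_clamp), params$spearman_clamp)
  rn <- pmin(pmax(r_control, -params$spearman_clamp), params$spearman_clamp)
  z_case <- atanh(rc)
  z_control <- atanh(rn)
  D <- (z_case - z_control) /
    sqrt(1.06 / (n_case - 3) + 1.06 / (n_control - 3))
  list(z_case = z_case, z_control = z_control, D = D)
}

#' Edge differential-coexpression score
#'
#' Scores the change of coexpression of two features between conditions:
#' within-condition Spearman correlations are Fisher-z transformed, their
#' standardised difference \code{D} uses the variance
#' \code{1.06/(n_case - 3) + 1.06/(n_control - 3)}, and
#' \code{S_edge = qnorm(clamp(2 * pnorm(|D|) - 1))}, the same inverse-normal
#' transform as [nodeScore()]. A constant vector within a condition has an
#' undefined correlation and is treated as r = 0 with a warning.
#'
#' @param x_src,x_tgt expression vectors over the same samples.
#' @param condition per-sample \code{"case"}/\code{"control"} labels.
#' @param params see [scoreParams()]; both conditions need > 3 samples.
#' @return list: r_case, r_control, z_case, z_control, D, s_edge.
#' @export
edgeScore <- function(x_src, x_tgt, condition, params = scoreParams()) {
  stopifnot(length(x_src) == length(x_tgt),
            length(condition) == length(x_src))
  is_case <- condition == "case"
  n_case <- sum(is_case); n_control <- sum(!is_case)
  if (n_case <= 3L || n_control <= 3L)
    stop("edge scoring needs > 3 samples per condition", call. = FALSE)
  r_case <- .spearman(x_src[is_case], x_tgt[is_case])
  r_control <- .spearman(x_src[!is_case], x_tgt[!is_case])
  if (anyNA(c(r_case, r_control))) {
    warning("constant expression vector within a condition; correlation ",
            "treated as 0")
    if (is.na(r_case)) r_case <- 0
    if (is.na(r_control)) r_control <- 0
  }
  zd <- .zDiff(r_case, r_control, n_case, n_control, params)
  s_edge <- qnorm(.clampProb(2 * pnorm(abs(zd$D)) - 1, params$clamp_eps))
  list(r_case = r_case, r_control = r_control, z_case = zd$z_case,
       z_control = zd$z_control, D = zd$D, s_edge = s_edge)
}

#' Combined FFL score
#'
#' Weighted sum of the mean node score and the mean edge score:
#' \code{s = gamma * mean(node_scores) + (1 - gamma) * mean(edge_scores)}.
#' Every FFL contributes exactly 3 nodes and 3 edge pairs (in an FB-FFL the
#' mutual TF/miRNA pair is scored once — pairwise coexpression is
#' direction-free).
#'
#' @param node_scores,edge_scores numeric vectors of length 3.
#' @param gamma weight in (0,1).
#' @return scalar score.
#' @export
fflScore <- function(node_scores, edge_scores, gamma = 0.5) {
  if (length(node_scores) != 3L || length(edge_scores) != 3L)
    stop("exactly 3 node scores and 3 edge scores expected", call. = FALSE)
  if (!(gamma > 0 && gamma < 1)) stop("gamma must be in (0,1)", call. = FALSE)
  gamma * mean(node_scores) + (1 - gamma) * mean(edge_scores)
}

# --- internal vectorised scoring engine ------------------------------------
# Precompute, per condition, the centred/normalised within-condition rank
# matrix so any pair's Spearman correlation is a single dot product.
.rankEngine <- function(study, de_table, params) {
  mat <- SummarizedExperiment::assay(study, "exprs")
  cond <- sampleCondition(study)
  norm_ranks <- function(m) {
    rk <- t(apply(m, 1L, rank, ties.method = "average"))
    rk <- rk - rowMeans(rk)
    ss <- sqrt(rowSums(rk^2))
    flat <- ss == 0
    rk[flat, ] <- 0
    ss[flat] <- 1
    list(r = rk / ss, flat = flat)
  }
  case <- norm_ranks(mat[, cond == "case", drop = FALSE])
  ctrl <- norm_ranks(mat[, cond == "control", drop = FALSE])
  s_node <- setNames(nodeScore(de_table$diff_score, params$clamp_eps),
                     de_table$feature)
  list(case = case$r, ctrl = ctrl$r,
       flat = rownames(mat)[case$flat | ctrl$flat],
       n_case = sum(cond == "case"), n_control = sum(cond == "control"),
       s_node = s_node, features = rownames(mat))
}

.pairEdgeScore <- function(engine, a, b, params) {
  r_case <- rowSums(engine$case[a, , drop = FALSE] *
                    engine$case[b, , drop = FALSE])
  r_ctrl <- rowSums(engine$ctrl[a, , drop = FALSE] *
                    engine$ctrl[b, , drop = FALSE])
  zd <- .zDiff(r_case, r_ctrl, engine$n_case, engine$n_control, params)
  qnorm(.clampProb(2 * pnorm(abs(zd$D)) - 1, params$clamp_eps))
}

.scoreTriples <- function(engine, tf, mirna, gene, params) {
  s_tf <- engine$s_node[tf]
  s_mi <- engine$s_node[mirna]
  s_ge <- engine$s_node[gene]
  e_tm <- .pairEdgeScore(engine, tf, mirna, params)
  e_tg <- .pairEdgeScore(engine, tf, gene, params)
  e_mg <- .pairEdgeScore(engine, mirna, gene, params)
  data.frame(
    s_node_tf = unname(s_tf), s_node_mirna = unname(s_mi),
    s_node_gene = unname(s_ge),
    s_edge_tm = e_tm, s_edge_tg = e_tg, s_edge_mg = e_mg,
    score = params$gamma * (s_tf + s_mi + s_ge) / 3 +
      (1 - params$gamma) * (e_tm + e_tg + e_mg) / 3,
    row.names = NULL)
}

#' Score enumerated FFLs on an expression study
#'
#' Attaches to each FFL its 3 node scores (from the DE table's
#' \code{diff_score}), its 3 edge differential-coexpression scores for the
#' pairs (TF, miRNA), (TF, gene), (miRNA, gene), and the combined score.
#' FFLs with any node absent from the expression matrix or DE table are
#' skipped; the count is reported via \code{attr(result, "n_skipped")} and a
#' message. If any used feature is constant within a condition its
#' correlations are treated as 0 with a warning.
#'
#' @param ffls data.frame from [enumerateFFLs()].
#' @param study an \linkS4class{ExpressionStudy} with > 3 samples per
#'   condition.
#' @param de_table data.frame from [moderatedDE()] covering both classes.
#' @param params see [scoreParams()].
#' @return \code{ffls} with score columns appended.
#' @export
scoreFFLs <- function(ffls, study, de_table, params = scoreParams()) {
  stopifnot(is(study, "ExpressionStudy"))
  cond <- sampleCondition(study)
  if (sum(cond == "case") <= 3L || sum(cond == "control") <= 3L)
    stop("edge scoring needs > 3 samples per condition", call. = FALSE)
  engine <- .rankEngine(study, de_table, params)
  known <- intersect(engine$features, names(engine$s_node))
  ok <- ffls$tf %in% known & ffls$mirna %in% known & ffls$gene %in% known
  n_skipped <- sum(!ok)
  if (n_skipped)
    message(n_skipped, " FFL(s) skipped: node(s) missing expression or DE")
  kept <- ffls[ok, , drop = FALSE]
  used <- unique(c(kept$tf, kept$mirna, kept$gene))
  flat_used <- intersect(engine$flat, used)
  if (length(flat_used))
    warning(length(flat_used), " feature(s) constant within a condition; ",
            "their correlations treated as 0")
  scored <- cbind(kept,
                  .scoreTriples(engine, kept$tf, kept$mirna, kept$gene,
                                params))
  rownames(scored) <- NULL
  attr(scored, "n_skipped") <- n_skipped
  scored
}

#' Permutation null distribution of FFL scores
#'
#' Draws \code{n_draws} random triples — by default composition-matched: one
#' TF, one miRNA, one gene, sampled uniformly from the network's node classes
#' (restricted to nodes with expression and DE records, the same eligibility
#' real FFLs need) — and scores each exactly as [scoreFFLs()] does, whether
#' or not the regulations exist. One shared null serves all observed FFLs.
#'
#' @param network a \linkS4class{RegulatoryNetwork}.
#' @param study an \linkS4class{ExpressionStudy}.
#' @param de_table data.frame from [moderatedDE()].
#' @param n_draws number of random triples (published analyses use 1e5).
#' @param seed integer seed; the null is reproducible from it.
#' @param params see [scoreParams()].
#' @param composition \code{"matched"} (one node per class, default) or
#'   \code{"free"} (any three distinct eligible nodes).
#' @return an \linkS4class{FFLNull}.
#' @export
permutationNull <- function(network, study, de_table, n_draws = 1e5,
                            seed = 1L, params = scoreParams(),
                            composition = c("matched", "free")) {
  composition <- match.arg(composition)
  stopifnot(n_draws >= 1)
  engine <- .rankEngine(study, de_table, params)
  eligible <- function(ids) intersect(ids,
    intersect(engine$features, names(engine$s_node)))
  tfs <- eligible(nodeIds(network, "TF"))
  mirs <- eligible(nodeIds(network, "miRNA"))
  genes <- eligible(nodeIds(network, "gene"))
  if (!length(tfs) || !length(mirs) || !length(genes))
    stop("empty eligible node class for the permutation null", call. = FALSE)
  n_draws <- as.integer(n_draws)
  triples <- .withSeed(seed, {
    if (composition == "matched") {
      data.frame(tf = sample(tfs, n_draws, replace = TRUE),
                 mirna = sample(mirs, n_draws, replace = TRUE),
                 gene = sample(genes, n_draws, replace = TRUE),
                 stringsAsFactors = FALSE)
    } else {
      all_ids <- c(tfs, mirs, genes)
      t(replicate(n_draws, sample(all_ids, 3L))) |>
        (\(m) data.frame(tf = m[, 1L], mirna = m[, 2L], gene = m[, 3L],
                         stringsAsFactors = FALSE))()
    }
  })
  scores <- .scoreTriples(engine, triples$tf, triples$mirna, triples$gene,
                          params)$score
  methods::new("FFLNull", scores = as.numeric(scores), nDraws = n_draws,
               seed = as.integer(seed))
}

#' Empirical p-values against a permutation null
#'
#' \code{p = #\{null > s\} / n_draws}: the plain proportion of random-triple
#' scores strictly larger than the observed score. With
#' \code{pseudocount = TRUE} the conservative \code{(# + 1) / (n + 1)}
#' variant is returned instead.
#'
#' @param scores observed FFL scores.
#' @param null an \linkS4class{FFLNull}.
#' @param pseudocount use the +1/(N+1) estimator.
#' @return numeric p-values in [0, 1].
#' @export
empiricalPvalues <- function(scores, null, pseudocount = FALSE) {
  stopifnot(is(null, "FFLNull"))
  srt <- sort(null@scores)
  n_gt <- null@nDraws - findInterval(scores, srt)
  if (pseudocount) (n_gt + 1) / (null@nDraws + 1) else n_gt / null@nDraws
}

#' Flag dysregulated FFLs
#'
#' Convenience wrapper: attaches \code{empirical_p} and the
#' \code{dysregulated} flag (\code{p <= alpha}, default 0.05).
#'
#' @param scored_ffls data.frame from [scoreFFLs()].
#' @param null an \linkS4class{FFLNull}.
#' @param alpha significance cutoff.
#' @param pseudocount see [empiricalPvalues()].
#' @return the input with \code{empirical_p} and \code{dysregulated} added.
#' @export
flagDysregulated <- function(scored_ffls, null, alpha = 0.05,
                             pseudocount = FALSE) {
  p <- empiricalPvalues(scored_ffls$score, null, pseudocount)
  scored_ffls$empirical_p <- p
  scored_ffls$dysregulated <- p <= alpha
  scored_ffls
}

# Edge table implied by one FFL row, following its type.
.fflEdges <- function(ffls) {
  base <- rbind(
    data.frame(source = ffls$tf, target = ffls$gene, edge_class = "tf_gene",
               stringsAsFactors = FALSE),
    data.frame(source = ffls$mirna, target = ffls$gene,
               edge_class = "mirna_gene", stringsAsFactors = FALSE))
  fwd <- ffls$type %in% c("TF_FFL", "FB_FFL")
  rev <- ffls$type %in% c("MIRNA_FFL", "FB_FFL")
  rbind(base,
        data.frame(source = ffls$tf[fwd], target = ffls$mirna[fwd],
                   edge_class = rep("tf_mirna", sum(fwd)),
                   stringsAsFactors = FALSE),
        data.frame(source = ffls$mirna[rev], target = ffls$tf[rev],
                   edge_class = rep("mirna_tf", sum(rev)),
                   stringsAsFactors = FALSE))
}

#' Merge flagged FFLs into the dysregulated network
#'
#' Union of the nodes and typed edges of all dysregulated FFLs, plus the
#' per-type motif counts (whose sum always equals the number of flagged
#' FFLs).
#'
#' @param ffls data.frame with a logical \code{dysregulated} column (from
#'   [flagDysregulated()]), or already-filtered FFL rows.
#' @return list: \code{network} (\linkS4class{RegulatoryNetwork}),
#'   \code{counts} (named integer: TF_FFL, MIRNA_FFL, FB_FFL, total).
#' @export
dysregulatedNetwork <- function(ffls) {
  if ("dysregulated" %in% names(ffls))
    ffls <- ffls[ffls$dysregulated, , drop = FALSE]
  if (!nrow(ffls)) stop("no dysregulated FFLs to merge", call. = FALSE)
  edges <- .fflEdges(ffls)
  edges$provenance <- ""
  counts <- table(factor(ffls$type, levels = .FFL_TYPES))
  counts <- c(setNames(as.integer(counts), .FFL_TYPES), total = nrow(ffls))
  list(network = buildNetwork(edges), counts = counts)
}

#' Hub FFLs of the dysregulated network
#'
#' An FFL is a hub FFL when its TF, miRNA and gene all have total degree of
#' at least \code{min_degree} in the merged dysregulated network
#' ("no fewer than" — the threshold itself qualifies).
#'
#' @param ffls dysregulated FFL rows.
#' @param merged the \linkS4class{RegulatoryNetwork} merged from the same
#'   FFLs (see [dysregulatedNetwork()]).
#' @param min_degree degree threshold (default 10).
#' @return list: \code{hub_ffls} (rows of \code{ffls}), \code{subnetwork}
#'   (\linkS4class{RegulatoryNetwork} or NULL), \code{degrees} (named
#'   integer per node).
#' @export
hubFFLs <- function(ffls, merged, min_degree = 10L) {
  if ("dysregulated" %in% names(ffls))
    ffls <- ffls[ffls$dysregulated, , drop = FALSE]
  dd <- degreeDistribution(merged)$degrees
  deg <- setNames(dd$degree, dd$id)
  is_hub <- deg[ffls$tf] >= min_degree & deg[ffls$mirna] >= min_degree &
    deg[ffls$gene] >= min_degree
  hub <- ffls[!is.na(is_hub) & is_hub, , drop = FALSE]
  sub <- if (nrow(hub)) dysregulatedNetwork(hub)$network else NULL
  list(hub_ffls = hub, subnetwork = sub, degrees = deg)
}

#' Cancer-gene enrichment of a gene subset (Fisher's exact test)
#'
#' Builds the 2x2 table of known-cancer-gene membership inside and outside a
#' subset of a background gene set and tests it two-sidedly by exact
#' hypergeometric summation.
#'
#' @param subset_genes genes of interest (must be a subset of
#'   \code{background_genes}).
#' @param background_genes the reference gene universe.
#' @param known_cancer_genes the curated cancer-gene list.
#' @return list: \code{table} (2x2 matrix), \code{odds_ratio},
#'   \code{p_value}.
#' @export
cancerGeneEnrichment <- function(subset_genes, background_genes,
                                 known_cancer_genes) {
  subset_genes <- unique(subset_genes)
  background_genes <- unique(background_genes)
  if (!all(subset_genes %in% background_genes))
    stop("subset_genes must be contained in background_genes", call. = FALSE)
  rest <- setdiff(background_genes, subset_genes)
  tab <- matrix(c(
    sum(subset_genes %in% known_cancer_genes),
    sum(!subset_genes %in% known_cancer_genes),
    sum(rest %in% known_cancer_genes),
    sum(!rest %in% known_cancer_genes)), nrow = 2L, byrow = TRUE,
    dimnames = list(c("subset", "rest"), c("cancer", "other")))
  ft <- fisher.test(tab, alternative = "two.sided")
  list(table = tab, odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}
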