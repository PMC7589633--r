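# Independent oracles and small fixture builders used across test files.

# Brute-force FFL scan: checks every (TF, miRNA, gene) triple against the
# edge list directly; deliberately naive and independent of enumerateFFLs.
bruteForceFFLs <- function(network) {
  e <- networkEdges(network)
  keys <- paste(e$source, e$target, e$edge_class)
  has <- function(s, t, cls) paste(s, t, cls) %in% keys
  res <- list()
  for (t in nodeIds(network, "TF")) {
    for (m in nodeIds(network, "miRNA")) {
      fwd <- has(t, m, "tf_mirna")
      rev <- has(m, t, "mirna_tf")
      if (!fwd && !rev) next
      for (g in nodeIds(network, "gene")) {
        if (has(t, g, "tf_gene") && has(m, g, "mirna_gene")) {
          type <- if (fwd && rev) "FB_FFL" else if (fwd) "TF_FFL"
                  else "MIRNA_FFL"
          res[[length(res) + 1L]] <- data.frame(
            tf = t, mirna = m, gene = g, type = type,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(tf = character(), mirna = character(),
                      gene = character(), type = character()))
  out[order(out$tf, out$mirna, out$gene, method = "radix"), ]
}

# Exact one-sided rank-sum p by exhausting all rank subsets of size m.
enumRankShift <- function(N, hit_ranks, side) {
  combs <- utils::combn(N, length(hit_ranks))
  stat <- colSums(combs)
  obs <- sum(hit_ranks)
  if (side == "top") mean(stat <= obs) else mean(stat >= obs)
}

# Two-sided Fisher exact p by hand-rolled hypergeometric summation
# (choose(), not dhyper/fisher.test).
bruteFisher2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # subset size
  K <- a + c_         # known positives
  N <- a + b + c_ + d
  ks <- max(0, m + K - N):min(m, K)
  pk <- choose(K, ks) * choose(N - K, m - ks) / choose(N, m)
  p_obs <- pk[ks == a]
  sum(pk[pk <= p_obs * (1 + 1e-7)])
}

# Mann-Whitney AUC of a score for recovering positives.
rankAUC <- function(score, positive) {
  r <- rank(score)
  np <- sum(positive); nn <- sum(!positive)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

# Tiny paired study: `effects` features get a case-shift of that size.
toyStudy <- function(n_feat = 20L, n_pairs = 5L, effects = numeric(),
                     n_mirna = 0L, seed = 42L, noise_sd = 0.5) {
  set.seed(seed)
  n <- n_feat + n_mirna
  mat <- matrix(rnorm(n * 2 * n_pairs, 8, noise_sd), n, 2 * n_pairs)
  condition <- rep(c("case", "control"), each = n_pairs)
  if (length(effects))
    mat[seq_along(effects), condition == "case"] <-
      mat[seq_along(effects), condition == "case"] + effects
  rownames(mat) <- c(sprintf("G%03d", seq_len(n_feat)),
                     if (n_mirna) sprintf("miR%03d", seq_len(n_mirna)))
  colnames(mat) <- paste0(condition, "_", rep(seq_len(n_pairs), 2))
  ExpressionStudy(
    gene_matrix = mat[seq_len(n_feat), , drop = FALSE],
    mirna_matrix = if (n_mirna) mat[n_feat + seq_len(n_mirna), ,
                                    drop = FALSE] else NULL,
    condition = condition,
    pair_id = rep(sprintf("D%02d", seq_len(n_pairs)), 2))
}

# Minimal 4-edge network holding one FB-FFL (drop edges to retype).
toyFFLNetwork <- function(drop = character()) {
  e <- data.frame(
    source = c("T1", "m1", "T1", "m1"),
    target = c("G1", "G1", "m1", "T1"),
    edge_class = c("tf_gene", "mirna_gene", "tf_mirna", "mirna_tf"),
    provenance = "toy", stringsAsFactors = FALSE)
  buildNetwork(e[!e$edge_class %in% drop, ])
}

writeTempTsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
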