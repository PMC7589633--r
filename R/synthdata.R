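# Synthetic data with planted ground truth for every pipeline stage.
# Defaults emulate the seed study's shape: a paired microarray design with
# 5 donors x 2 conditions and a heavy-tailed mixed regulatory network.

#' Generate a random regulatory network with planted FFLs
#'
#' Draws edges per regulation class with heavy-tailed target popularity
#' (approximating preferential attachment, so degree distributions are
#' power-law-like), then injects \code{n_planted_ffls} guaranteed motifs
#' cycling through the three FFL types. For a planted TF-FFL or miRNA-FFL
#' any pre-existing opposite TF/miRNA link is removed so the planted type is
#' what enumeration reports.
#'
#' @param n_tf,n_mirna,n_gene node counts (defaults 50/80/300).
#' @param edge_density expected edges as a fraction of possible
#'   source-target pairs per class (default 0.05).
#' @param n_planted_ffls number of guaranteed motifs (default 10; must be
#'   feasible given the node counts).
#' @param seed integer seed; identical seeds give identical networks.
#' @return list: \code{network} (\linkS4class{RegulatoryNetwork}),
#'   \code{truth} (list with \code{planted_ffls} data.frame).
#' @export
synthNetwork <- function(n_tf = 50L, n_mirna = 80L, n_gene = 300L,
                         edge_density = 0.05, n_planted_ffls = 10L,
                         seed = 1L) {
  stopifnot(n_tf >= 1L, n_mirna >= 1L, n_gene >= 1L,
            edge_density >= 0, edge_density < 1)
  if (n_planted_ffls > n_tf * n_mirna)
    stop("infeasible planted FFL count for these node counts",
         call. = FALSE)
  tfs <- sprintf("TF%03d", seq_len(n_tf))
  mirs <- sprintf("miR%03d", seq_len(n_mirna))
  genes <- sprintf("G%04d", seq_len(n_gene))
  .withSeed(seed, {
    # heavy-tailed target weights emulate preferential attachment
    draw_class <- function(src, tgt, cls, frac = 1) {
      n_edges <- round(edge_density * frac * length(src) * length(tgt))
      if (n_edges == 0L)
        return(data.frame(source = character(), target = character(),
                          edge_class = character(),
                          stringsAsFactors = FALSE))
      w_tgt <- (seq_along(tgt))^(-0.8)
      w_src <- (seq_along(src))^(-0.5)
      data.frame(source = sample(src, n_edges, replace = TRUE,
                                 prob = w_src),
                 target = sample(tgt, n_edges, replace = TRUE,
                                 prob = w_tgt),
                 edge_class = cls, stringsAsFactors = FALSE)
    }
    e <- rbind(draw_class(tfs, genes, "tf_gene"),
               draw_class(tfs, mirs, "tf_mirna"),
               draw_class(mirs, genes, "mirna_gene"),
               draw_class(mirs, tfs, "mirna_tf", frac = 0.3))
    planted <- NULL
    if (n_planted_ffls > 0L) {
      # distinct (TF, miRNA) regulator pairs; genes cycle if scarce
      pair_idx <- sample(n_tf * n_mirna, n_planted_ffls)
      p_tf <- tfs[(pair_idx - 1L) %% n_tf + 1L]
      p_mir <- mirs[(pair_idx - 1L) %/% n_tf + 1L]
      p_gene <- genes[sample(n_gene, n_planted_ffls,
                             replace = n_planted_ffls > n_gene)]
      p_type <- rep(.FFL_TYPES, length.out = n_planted_ffls)
      planted <- data.frame(tf = p_tf, mirna = p_mir, gene = p_gene,
                            type = p_type, stringsAsFactors = FALSE)
      add <- list(
        data.frame(source = p_tf, target = p_gene, edge_class = "tf_gene",
                   stringsAsFactors = FALSE),
        data.frame(source = p_mir, target = p_gene,
                   edge_class = "mirna_gene", stringsAsFactors = FALSE),
        data.frame(source = p_tf[p_type != "MIRNA_FFL"],
                   target = p_mir[p_type != "MIRNA_FFL"],
                   edge_class = "tf_mirna", stringsAsFactors = FALSE),
        data.frame(source = p_mir[p_type != "TF_FFL"],
                   target = p_tf[p_type != "TF_FFL"],
                   edge_class = "mirna_tf", stringsAsFactors = FALSE))
      e <- rbind(e, do.call(rbind, add))
      # strip opposite-direction regulator links that would retype a
      # planted TF-FFL or miRNA-FFL as FB-FFL
      tf_only <- p_type == "TF_FFL"
      drop_rev <- paste(p_mir[tf_only], p_tf[tf_only], "mirna_tf",
                        sep = "\r")
      mir_only <- p_type == "MIRNA_FFL"
      drop_fwd <- paste(p_tf[mir_only], p_mir[mir_only], "tf_mirna",
                        sep = "\r")
      key <- paste(e$source, e$target, e$edge_class, sep = "\r")
      e <- e[!key %in% c(drop_rev, drop_fwd), , drop = FALSE]
    }
    e$provenance <- "synthetic"
    net <- buildNetwork(e)
    list(network = net, truth = list(planted_ffls = planted))
  })
}

#' Generate paired two-condition expression with planted effects
#'
#' Emulates a paired microarray design: per-feature baseline log2 intensity
#' ~ N(8, 1.5), a per-donor baseline shift ~ N(0, 0.3), and residual noise
#' ~ N(0, noise_sd). Nodes of planted FFLs receive a mean shift of
#' \code{+/- effect_lfc} in the case condition (sign alternating across
#' planted nodes). Each planted FFL additionally gets a per-donor latent
#' factor inducing within-condition coexpression: in the case condition all
#' three nodes load positively (all pairwise correlations ~ +coexpr_delta);
#' in the control condition the loadings are (+, -, -) for (TF, miRNA,
#' gene), so the TF-miRNA and TF-gene pairs sit near -coexpr_delta (the
#' miRNA-gene pair is constrained to +delta: all three pairwise
#' correlations cannot be negative simultaneously).
#'
#' @param network_truth list from [synthNetwork()].
#' @param n_pairs donors per condition (default 5; minimum 4 — edge scoring
#'   needs more than 3 samples per condition).
#' @param effect_lfc planted absolute log2 fold change (default 2).
#' @param coexpr_delta target within-condition correlation magnitude for
#'   planted pairs (default 0.8).
#' @param noise_sd residual log2-intensity noise (default 0.5).
#' @param seed integer seed.
#' @return list: \code{study} (\linkS4class{ExpressionStudy}),
#'   \code{truth} (planted_ffls, node_effects, pair_targets).
#' @export
synthExpression <- function(network_truth, n_pairs = 5L, effect_lfc = 2,
                            coexpr_delta = 0.8, noise_sd = 0.5, seed = 1L) {
  if (n_pairs < 4L)
    stop("n_pairs must be >= 4 (edge scoring needs n > 3 per condition)",
         call. = FALSE)
  stopifnot(noise_sd > 0, coexpr_delta >= 0, coexpr_delta < 1,
            effect_lfc >= 0)
  network <- network_truth$network
  planted <- network_truth$truth$planted_ffls
  nodes <- networkNodes(network)
  is_mirna <- nodes$node_class == "miRNA"
  feats_gene <- nodes$id[!is_mirna]   # TFs are measured on the gene platform
  feats_mir <- nodes$id[is_mirna]
  n_feat <- nrow(nodes)
  n_samp <- 2L * n_pairs
  .withSeed(seed, {
    all_feats <- c(feats_gene, feats_mir)
    mu <- rnorm(n_feat, mean = 8, sd = 1.5)
    donor <- rnorm(n_pairs, 0, 0.3)
    mat <- matrix(rnorm(n_feat * n_samp, 0, noise_sd), n_feat, n_samp)
    mat <- mat + mu + rep(rep(donor, 2L), each = n_feat)
    rownames(mat) <- all_feats
    condition <- rep(c("case", "control"), each = n_pairs)
    pair_id <- rep(sprintf("D%02d", seq_len(n_pairs)), 2L)
    colnames(mat) <- paste(condition, pair_id, sep = "_")
    node_effects <- data.frame(feature = character(), true_lfc = numeric(),
                               stringsAsFactors = FALSE)
    pair_targets <- NULL
    if (!is.null(planted) && nrow(planted)) {
      p_nodes <- unique(c(rbind(planted$tf, planted$mirna, planted$gene)))
      signs <- rep_len(c(1, -1), length(p_nodes))
      node_effects <- data.frame(feature = p_nodes,
                                 true_lfc = signs * effect_lfc,
                                 stringsAsFactors = FALSE)
      mat[p_nodes, condition == "case"] <-
        mat[p_nodes, condition == "case"] + signs * effect_lfc
      # one latent factor per planted FFL and condition
      lambda <- noise_sd * sqrt(coexpr_delta / (1 - coexpr_delta))
      loads_ctrl <- c(1, -1, -1)
      for (i in seq_len(nrow(planted))) {
        trip <- c(planted$tf[i], planted$mirna[i], planted$gene[i])
        z_case <- rnorm(n_pairs)
        z_ctrl <- rnorm(n_pairs)
        mat[trip, condition == "case"] <-
          mat[trip, condition == "case"] +
          lambda * matrix(z_case, 3L, n_pairs, byrow = TRUE)
        mat[trip, condition == "control"] <-
          mat[trip, condition == "control"] +
          lambda * loads_ctrl * matrix(z_ctrl, 3L, n_pairs, byrow = TRUE)
      }
      pair_targets <- do.call(rbind, lapply(seq_len(nrow(planted)),
        function(i) data.frame(
          ffl = i,
          pair = c("tf_mirna", "tf_gene", "mirna_gene"),
          r_case = coexpr_delta,
          r_control = c(-coexpr_delta, -coexpr_delta, coexpr_delta),
          stringsAsFactors = FALSE)))
    }
    study <- ExpressionStudy(
      gene_matrix = mat[feats_gene, , drop = FALSE],
      mirna_matrix = if (length(feats_mir))
        mat[feats_mir, , drop = FALSE] else NULL,
      condition = condition, pair_id = pair_id)
    list(study = study,
         truth = list(planted_ffls = planted, node_effects = node_effects,
                      pair_targets = pair_targets))
  })
}

#' Generate a synthetic cancer DE list with a known pattern
#'
#' Samples up/down gene sets from the perturbation signature's universe with
#' rank-dependent weights: under \code{"consistent"}, up-genes concentrate at
#' the top (small ranks) and down-genes at the bottom; \code{"reverse"} swaps
#' the two; \code{"null"} samples uniformly. Weights are
#' \code{exp(-strength * u)} with \code{u} the normalised rank.
#'
#' @param signature data.frame from [rankSignature()].
#' @param pattern \code{"consistent"}, \code{"reverse"} or \code{"null"}.
#' @param n_up,n_down set sizes (their sum must fit in the universe).
#' @param enrichment_strength weight decay rate (default 6).
#' @param seed integer seed.
#' @return list: \code{table} (gene, log2FC, FDR, direction), \code{up},
#'   \code{down}, \code{pattern}.
#' @export
synthCancerDE <- function(signature, pattern = c("consistent", "reverse",
                                                 "null"),
                          n_up = 100L, n_down = 100L,
                          enrichment_strength = 6, seed = 1L) {
  pattern <- match.arg(pattern)
  N <- nrow(signature)
  if (n_up + n_down > N)
    stop("n_up + n_down exceeds the signature universe", call. = FALSE)
  u <- (signature$rank - 1) / max(N - 1, 1)
  w_top <- exp(-enrichment_strength * u)
  w_bottom <- exp(-enrichment_strength * (1 - u))
  w <- switch(pattern,
    consistent = list(up = w_top, down = w_bottom),
    reverse = list(up = w_bottom, down = w_top),
    null = list(up = rep(1, N), down = rep(1, N)))
  .withSeed(seed, {
    up <- if (n_up > 0L)
      sample(signature$feature, n_up, prob = w$up) else character()
    remaining <- !(signature$feature %in% up)
    down <- if (n_down > 0L)
      sample(signature$feature[remaining], n_down,
             prob = w$down[remaining]) else character()
    tab <- data.frame(
      gene = c(up, down),
      log2FC = c(runif(length(up), 1, 4), runif(length(down), -4, -1)),
      FDR = runif(length(up) + length(down), 0, 0.05),
      direction = rep(c("up", "down"), c(length(up), length(down))),
      stringsAsFactors = FALSE)
    list(table = tab, up = up, down = down, pattern = pattern)
  })
}

#' Generate drug-screening tables with a designed winner
#'
#' Emits a drug-to-miRNA effect table and per-drug gene signatures: one
#' designated winner drug downregulates every target miRNA and reverses the
#' perturbation direction of \code{n_reversed_genes} genes; decoy drugs hit
#' targets at random with probability \code{p_hit} and random directions.
#'
#' @param pert_de list with \code{up}/\code{down} perturbation gene sets.
#' @param target_mirnas miRNAs the screen should suppress.
#' @param n_drugs total drugs including the winner (default 20).
#' @param p_hit decoy hit probability per (drug, target) (default 0.1).
#' @param n_reversed_genes genes the winner reverses (default 6, so the
#'   winner separates from decoys whose reversals are binomial at rate
#'   \code{p_hit / 2}).
#' @param seed integer seed.
#' @return list: \code{mirna_table}, \code{signatures} (data.frames),
#'   \code{truth} (winner name).
#' @export
synthDrugTables <- function(pert_de, target_mirnas, n_drugs = 20L,
                            p_hit = 0.1, n_reversed_genes = 6L, seed = 1L) {
  stopifnot(n_drugs >= 1L, p_hit >= 0, p_hit < 1,
            length(target_mirnas) >= 1L)
  drugs <- sprintf("drug%02d", seq_len(n_drugs))
  winner <- drugs[1L]
  pert_genes <- c(pert_de$up, pert_de$down)
  if (!length(pert_genes))
    stop("perturbation DE sets are empty", call. = FALSE)
  n_reversed_genes <- min(n_reversed_genes, length(pert_genes))
  .withSeed(seed, {
    mir_rows <- list(data.frame(
      drug = winner, mirna = target_mirnas, effect = "down",
      source = "designed", stringsAsFactors = FALSE))
    sig_rows <- list()
    win_genes <- sample(pert_genes, n_reversed_genes)
    sig_rows[[1L]] <- data.frame(
      drug = winner, gene = win_genes,
      direction = ifelse(win_genes %in% pert_de$up, "down", "up"),
      stringsAsFactors = FALSE)
    for (d in drugs[-1L]) {
      hit <- runif(length(target_mirnas)) < p_hit
      if (any(hit))
        mir_rows[[length(mir_rows) + 1L]] <- data.frame(
          drug = d, mirna = target_mirnas[hit],
          effect = sample(c("up", "down"), sum(hit), replace = TRUE),
          source = "decoy", stringsAsFactors = FALSE)
      ghit <- runif(length(pert_genes)) < p_hit
      if (any(ghit))
        sig_rows[[length(sig_rows) + 1L]] <- data.frame(
          drug = d, gene = pert_genes[ghit],
          direction = sample(c("up", "down"), sum(ghit), replace = TRUE),
          stringsAsFactors = FALSE)
    }
    list(mirna_table = do.call(rbind, mir_rows),
         signatures = do.call(rbind, sig_rows),
         truth = list(winner = winner))
  })
}
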