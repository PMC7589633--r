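# Stage orchestration: fixture generation, configuration, one-shot run.

#' Pipeline configuration
#'
#' Validated bundle of every tunable the pipeline uses. Defaults follow the
#' published analysis where a value is printed there (gamma 0.5, 100,000
#' permutation draws, FFL alpha 0.05, pattern alpha 0.1, hub degree 10,
#' "general" sharing threshold 3, reversal threshold 3); DE thresholds
#' default to p <= 0.05 and |log2FC| >= 1.
#'
#' @param gamma node/edge weight in (0,1).
#' @param n_draws permutation draws.
#' @param seed master integer seed, expanded into per-stage seeds.
#' @param alpha_ffl dysregulation cutoff on the empirical p.
#' @param alpha_pattern rank-shift pattern cutoff.
#' @param de_p_max,de_lfc_min DE thresholds.
#' @param min_degree hub degree threshold.
#' @param general_min systems shared for a "general" FFL.
#' @param min_reversed genes a drug must reverse.
#' @param clamp_eps probability floor for the score transforms.
#' @return validated list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(gamma = 0.5, n_draws = 1e5, seed = 1L,
                           alpha_ffl = 0.05, alpha_pattern = 0.1,
                           de_p_max = 0.05, de_lfc_min = 1,
                           min_degree = 10L, general_min = 3L,
                           min_reversed = 3L, clamp_eps = 1e-15) {
  stopifnot(gamma > 0, gamma < 1, n_draws >= 1,
            alpha_ffl > 0, alpha_ffl < 1, alpha_pattern > 0,
            alpha_pattern < 1, de_p_max > 0, de_lfc_min > 0,
            min_degree >= 1, general_min >= 2, min_reversed >= 1,
            clamp_eps > 0, clamp_eps < 0.5)
  structure(list(gamma = gamma, n_draws = as.integer(n_draws),
                 seed = as.integer(seed), alpha_ffl = alpha_ffl,
                 alpha_pattern = alpha_pattern, de_p_max = de_p_max,
                 de_lfc_min = de_lfc_min, min_degree = as.integer(min_degree),
                 general_min = as.integer(general_min),
                 min_reversed = as.integer(min_reversed),
                 clamp_eps = clamp_eps),
            class = "pipelineConfig")
}

#' Write a complete synthetic demo dataset
#'
#' Generates every input the pipeline consumes — per-class regulation edge
#' lists, gene and miRNA expression matrices with a sample sheet, GMT
#' annotations with a body-system map, cancer DE lists of known pattern, and
#' drug tables with a designed winner — plus the ground-truth JSON, all
#' deterministic from one master seed.
#'
#' @param dir output directory (created if needed).
#' @param seed master integer seed.
#' @param n_tf,n_mirna,n_gene,edge_density,n_planted_ffls network size; see
#'   [synthNetwork()].
#' @param n_pairs,effect_lfc,coexpr_delta,noise_sd expression design; see
#'   [synthExpression()].
#' @return invisibly, the list of written file paths.
#' @export
makeFixtures <- function(dir, seed = 1L, n_tf = 50L, n_mirna = 80L,
                         n_gene = 300L, edge_density = 0.05,
                         n_planted_ffls = 10L, n_pairs = 5L,
                         effect_lfc = 2, coexpr_delta = 0.8,
                         noise_sd = 0.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- .stageSeeds(seed, 5L)
  net <- synthNetwork(n_tf, n_mirna, n_gene, edge_density, n_planted_ffls,
                      seed = seeds[1L])
  expr <- synthExpression(net, n_pairs, effect_lfc, coexpr_delta, noise_sd,
                          seed = seeds[2L])
  paths <- character()
  wp <- function(name) {
    p <- file.path(dir, name); paths[[length(paths) + 1L]] <<- p; p
  }
  # per-class regulation edge lists
  e <- networkEdges(net$network)
  for (cls in .EDGE_CLASSES) {
    sel <- e[e$edge_class == cls, c("source", "target")]
    .writeTsv(sel, wp(paste0(cls, ".tsv")), col.names = TRUE)
  }
  # expression matrices + sample sheet
  study <- expr$study
  mat <- SummarizedExperiment::assay(study, "exprs")
  fclass <- featureClass(study)
  for (cl in c("gene", "miRNA")) {
    m <- mat[fclass == cl, , drop = FALSE]
    df <- data.frame(feature = rownames(m), round(m, 6),
                     check.names = FALSE, stringsAsFactors = FALSE)
    .writeTsv(df, wp(paste0(ifelse(cl == "gene", "gene", "mirna"),
                            "_expr.tsv")))
  }
  .writeTsv(data.frame(sample = colnames(study),
                       condition = sampleCondition(study),
                       pairId = samplePair(study)), wp("samples.tsv"))
  # annotations: 5 body systems; planted FFL i serves system (i mod 5) + 1,
  # and the first two planted FFLs additionally serve systems 2 and 3 so
  # the sharing analysis has "general" FFLs to find
  planted <- net$truth$planted_ffls
  systems <- c("immune", "cardiovascular", "nervous", "skeletal",
               "endocrine")
  assign_sys <- lapply(seq_len(nrow(planted)), function(i) {
    s <- systems[(i - 1L) %% 5L + 1L]
    if (i <= 2L) unique(c(s, systems[2:3])) else s
  })
  sys_members <- setNames(vector("list", 5L), systems)
  for (i in seq_len(nrow(planted))) {
    trip <- unlist(planted[i, c("tf", "mirna", "gene")], use.names = FALSE)
    for (s in assign_sys[[i]])
      sys_members[[s]] <- union(sys_members[[s]], trip)
  }
  extra <- .withSeed(seeds[3L], lapply(systems, function(s)
    sample(nodeIds(net$network, "gene"), 12L)))
  gmt_lines <- vapply(seq_along(systems), function(k) {
    members <- union(sys_members[[systems[k]]], extra[[k]])
    paste(c(paste0("pathway_", systems[k]), "synthetic pathway",
            .lexSort(members)), collapse = "\t")
  }, character(1))
  writeLines(gmt_lines, wp("annotations.gmt"))
  .writeTsv(data.frame(system = systems,
                       pathway = paste0("pathway_", systems)),
            wp("system_map.tsv"), col.names = FALSE)
  # cancer DE lists need the perturbation signature: compute DE here
  de <- moderatedDE(study)
  sig <- rankSignature(de[de$class == "gene", ])
  cancer_specs <- list(SYNCA = "consistent", SYNCB = "reverse",
                       SYNCC = "null")
  cancer_truth <- list()
  n_side <- min(100L, nrow(sig) %/% 4L)
  for (k in seq_along(cancer_specs)) {
    cd <- synthCancerDE(sig, pattern = cancer_specs[[k]],
                        n_up = n_side, n_down = n_side,
                        seed = seeds[4L] %% 100000L + k)
    cancer_truth[[names(cancer_specs)[k]]] <- cd$pattern
    .writeTsv(cd$table, wp(paste0("cancer_", names(cancer_specs)[k],
                                  ".tsv")))
  }
  # drug tables against the planted perturbation
  pert <- deSets(de, p_max = 0.05, lfc_min = 1)
  mir_de <- deSets(de[de$class == "miRNA", ], p_max = 0.05, lfc_min = 1)
  targets <- mir_de$up
  if (!length(targets)) targets <- planted$mirna[1:2]
  drugs <- synthDrugTables(pert, targets, seed = seeds[5L])
  .writeTsv(drugs$mirna_table, wp("drug_mirna.tsv"))
  .writeTsv(drugs$signatures, wp("drug_signatures.tsv"))
  truth <- list(seed = seed,
                planted_ffls = planted,
                node_effects = expr$truth$node_effects,
                cancer_patterns = cancer_truth,
                drug_winner = drugs$truth$winner,
                target_mirnas = targets)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), wp("truth.json"))
  invisible(unlist(paths))
}

# Read the fixture directory back into the objects the stages need.
.readFixtures <- function(dir) {
  regs <- do.call(rbind, lapply(.EDGE_CLASSES, function(cls)
    readRegulations(file.path(dir, paste0(cls, ".tsv")), cls)))
  network <- buildNetwork(regs)
  samples <- .readTsv(file.path(dir, "samples.tsv"), header = TRUE)
  read_mat <- function(name) {
    df <- .readTsv(file.path(dir, name), header = TRUE, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df[[1L]]
    m[, samples$sample, drop = FALSE]
  }
  study <- ExpressionStudy(read_mat("gene_expr.tsv"),
                           read_mat("mirna_expr.tsv"),
                           condition = samples$condition,
                           pair_id = samples$pairId)
  annotations <- readGeneSets(file.path(dir, "annotations.gmt"))
  system_map <- readSystemMap(file.path(dir, "system_map.tsv"))
  cancer_files <- .lexSort(list.files(dir, pattern = "^cancer_.*\\.tsv$"))
  cancers <- lapply(cancer_files, function(f)
    readCancerDE(file.path(dir, f)))
  names(cancers) <- sub("^cancer_(.*)\\.tsv$", "\\1", cancer_files)
  list(network = network, study = study, annotations = annotations,
       system_map = system_map, cancers = cancers,
       drug_mirna = readDrugMirnaTable(file.path(dir, "drug_mirna.tsv")),
       drug_signatures = readDrugSignatures(file.path(dir,
                                                      "drug_signatures.tsv")),
       truth = jsonlite::fromJSON(file.path(dir, "truth.json")))
}

#' Run the full pipeline on a fixture directory
#'
#' One-shot orchestration of every stage: differential expression, FFL
#' enumeration, scoring, permutation null, dysregulation flagging, merged
#' network and hubs, body-system assignment and sharing, rank-shift pattern
#' tests for each cancer list, and both drug screens. All randomness derives
#' from the config's master seed, so reruns with the same inputs and config
#' are byte-identical. A deterministic plain-text summary is written to
#' \code{output_dir/summary.tsv} alongside the per-stage TSV outputs.
#'
#' @param input_dir fixture directory (see [makeFixtures()]).
#' @param output_dir where outputs are written (created if needed).
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with every stage's in-memory result.
#' @export
runPipeline <- function(input_dir, output_dir,
                        config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fx <- .readFixtures(input_dir)
  params <- scoreParams(gamma = config$gamma,
                        clamp_eps = config$clamp_eps)
  de <- moderatedDE(fx$study)
  .writeTsv(cbind(de[1:2], lapply(de[-(1:2)], .fmtNum)),
            file.path(output_dir, "de.tsv"))
  ffls <- enumerateFFLs(fx$network)
  scored <- scoreFFLs(ffls, fx$study, de, params)
  null <- permutationNull(fx$network, fx$study, de,
                          n_draws = config$n_draws,
                          seed = .stageSeeds(config$seed, 1L)[1L],
                          params = params)
  flagged <- flagDysregulated(scored, null, alpha = config$alpha_ffl)
  out_ffl <- cbind(flagged[1:4], lapply(flagged[5:12], .fmtNum),
                   flagged["dysregulated"])
  .writeTsv(out_ffl, file.path(output_dir, "ffls.tsv"))
  dys <- dysregulatedNetwork(flagged)
  writeNetwork(dys$network, file.path(output_dir, "dysregulated_network.tsv"))
  hubs <- hubFFLs(flagged, dys$network, min_degree = config$min_degree)
  assignment <- assignSystemFFLs(flagged[flagged$dysregulated, ,
                                         drop = FALSE],
                                 fx$annotations, fx$system_map)
  sharing <- sharingAnalysis(assignment, general_min = config$general_min)
  subnets <- mergeSystemSubnetworks(assignment)
  sig <- rankSignature(de[de$class == "gene", ])
  patterns <- lapply(fx$cancers, function(cd) {
    p <- patternTest(sig, cd)
    c(as.list(p), classifyPatterns(p, alpha = config$alpha_pattern))
  })
  pat_df <- do.call(rbind, lapply(names(patterns), function(nm) {
    pt <- patterns[[nm]]
    data.frame(cancer = nm, up_top = pt$up_top, up_bottom = pt$up_bottom,
               down_top = pt$down_top, down_bottom = pt$down_bottom,
               labels = paste(pt$labels, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  pat_df <- pat_df[.lexOrder(pat_df$cancer), , drop = FALSE]
  .writeTsv(cbind(pat_df["cancer"], lapply(pat_df[2:5], .fmtNum),
                  pat_df["labels"]),
            file.path(output_dir, "patterns.tsv"))
  mir_de <- deSets(de[de$class == "miRNA", ], p_max = config$de_p_max,
                   lfc_min = config$de_lfc_min)
  targets <- if (length(mir_de$up)) mir_de$up else
    unique(fx$drug_mirna$mirna)
  inhibitors <- screenMirnaInhibitors(fx$drug_mirna, targets)
  pert <- deSets(de, p_max = config$de_p_max, lfc_min = config$de_lfc_min)
  reversal <- signatureReversal(fx$drug_signatures, pert,
                                min_reversed = config$min_reversed)
  .writeTsv(inhibitors, file.path(output_dir, "drug_inhibitors.tsv"))
  .writeTsv(reversal$all, file.path(output_dir, "drug_reversal.tsv"))
  summary_df <- .pipelineSummary(fx, de, flagged, dys, hubs, assignment,
                                 sharing, subnets, pat_df, inhibitors,
                                 reversal, config)
  .writeTsv(summary_df, file.path(output_dir, "summary.tsv"))
  invisible(list(de = de, ffls = flagged, null = null, dysregulated = dys,
                 hubs = hubs, assignment = assignment, sharing = sharing,
                 subnetworks = subnets, patterns = pat_df,
                 inhibitors = inhibitors, reversal = reversal,
                 summary = summary_df))
}

.pipelineSummary <- function(fx, de, flagged, dys, hubs, assignment,
                             sharing, subnets, pat_df, inhibitors, reversal,
                             config) {
  row <- function(section, key, value)
    data.frame(section = section, key = key, value = as.character(value),
               stringsAsFactors = FALSE)
  nodes <- networkNodes(fx$network)
  ec <- edgeCounts(fx$network)
  rows <- list(
    row("config", "seed", config$seed),
    row("config", "n_draws", config$n_draws),
    row("config", "gamma", .fmtNum(config$gamma)),
    row("network", "n_tf", sum(nodes$node_class == "TF")),
    row("network", "n_mirna", sum(nodes$node_class == "miRNA")),
    row("network", "n_gene", sum(nodes$node_class == "gene")))
  for (cls in names(ec)) rows <- c(rows, list(row("network", cls, ec[cls])))
  type_counts <- table(factor(flagged$type, levels = .FFL_TYPES))
  rows <- c(rows, list(row("ffl", "n_total", nrow(flagged))))
  dysc <- dys$counts
  for (tp in .FFL_TYPES) {
    rows <- c(rows, list(row("ffl", paste0("n_", tp), type_counts[tp])))
    rows <- c(rows, list(row("dysregulated", paste0("n_", tp), dysc[tp])))
  }
  rows <- c(rows, list(
    row("dysregulated", "n_total", dysc["total"]),
    row("dysregulated", "sum_equals_total",
        sum(dysc[.FFL_TYPES]) == dysc["total"]),
    row("hub", "n_hub_ffls", nrow(hubs$hub_ffls))))
  for (s in assignment$systems)
    rows <- c(rows, list(row("systems", s, assignment$counts[s])))
  for (k in names(sharing$breakdown))
    rows <- c(rows, list(row("sharing", k, sharing$breakdown[k])))
  rows <- c(rows, list(
    row("sharing", "nodes_shared",
        paste0(subnets$node_overlap$shared, "/",
               subnets$node_overlap$total)),
    row("sharing", "edges_shared",
        paste0(subnets$edge_overlap$shared, "/",
               subnets$edge_overlap$total))))
  for (i in seq_len(nrow(pat_df)))
    rows <- c(rows, list(row("pattern", pat_df$cancer[i], paste(
      .fmtNum(unlist(pat_df[i, 2:5])), collapse = ";"))))
  for (i in seq_len(nrow(pat_df)))
    rows <- c(rows, list(row("pattern_label", pat_df$cancer[i],
                             pat_df$labels[i])))
  for (i in seq_len(nrow(inhibitors)))
    rows <- c(rows, list(row("drug_inhibitor", inhibitors$drug[i],
                             inhibitors$coverage[i])))
  passing <- reversal$passing
  for (i in seq_len(nrow(passing)))
    rows <- c(rows, list(row("drug_reversal", passing$drug[i],
                             passing$n_reversed[i])))
  do.call(rbind, rows)
}
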