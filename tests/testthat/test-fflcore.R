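test_that("enumerateFFLs finds and types the canonical motifs", {
  # minimal TF-FFL
  tf_ffl <- toyFFLNetwork(drop = "mirna_tf")
  expect_equal(enumerateFFLs(tf_ffl),
               data.frame(tf = "T1", mirna = "m1", gene = "G1",
                          type = "TF_FFL"))
  # adding the reverse regulator link merges into a single FB-FFL
  fb <- enumerateFFLs(toyFFLNetwork())
  expect_equal(nrow(fb), 1L)
  expect_equal(fb$type, "FB_FFL")
  # miRNA-FFL
  expect_equal(enumerateFFLs(toyFFLNetwork(drop = "tf_mirna"))$type,
               "MIRNA_FFL")
  # no regulator link -> no motif
  none <- toyFFLNetwork(drop = c("tf_mirna", "mirna_tf"))
  expect_equal(nrow(enumerateFFLs(none)), 0L)
})

test_that("enumerateFFLs equals the brute-force triple scan", {
  for (s in 1:6) {
    net <- synthNetwork(n_tf = 12, n_mirna = 12, n_gene = 25,
                        edge_density = 0.08, n_planted_ffls = 3,
                        seed = s)$network
    got <- enumerateFFLs(net)
    want <- bruteForceFFLs(net)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
    expect_false(any(duplicated(got[c("tf", "mirna", "gene")])))
  }
})

test_that("nodeScore implements the inverse-normal transform", {
  expect_equal(nodeScore(1.959964), 1.644854, tolerance = 1e-4)
  expect_equal(nodeScore(1.0), 0.4752, tolerance = 1e-3)
  # degenerate lower bound: Diff = 0 hits the clamp floor, finite
  expect_equal(nodeScore(0), qnorm(1e-15))
  expect_true(is.finite(nodeScore(0)))
  expect_true(is.finite(nodeScore(1e6)))
  # strictly increasing on the unclamped range
  d <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(nodeScore(d)) > 0))
  expect_error(nodeScore(-0.1), ">= 0")
})

test_that("fisherZ is the odd, increasing atanh transform", {
  expect_equal(fisherZ(0), 0)
  expect_equal(fisherZ(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisherZ(0.5), 0.5 * log(3), tolerance = 1e-12)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisherZ(-r), -fisherZ(r))
  expect_true(all(diff(fisherZ(r)) > 0))
  expect_error(fisherZ(1), "< 1")
})

test_that("edgeScore standardises the coexpression change", {
  cond <- rep(c("case", "control"), each = 5)
  # Spearman r = 0.9 in case (one adjacent swap), -0.9 in control
  src <- c(1:5, 1:5)
  tgt <- c(c(2, 1, 3, 4, 5), c(4, 5, 3, 2, 1))
  es <- edgeScore(src, tgt, cond)
  expect_equal(es$r_case, 0.9, tolerance = 1e-12)
  expect_equal(es$r_control, -0.9, tolerance = 1e-12)
  expect_equal(es$D, 2 * atanh(0.9) / sqrt(2 * 1.06 / 2), tolerance = 1e-12)
  expect_equal(es$D, 2.8599, tolerance = 1e-3)
  # swapping condition labels flips D's sign, not the score
  es2 <- edgeScore(src, tgt, rep(c("control", "case"), each = 5))
  expect_equal(es2$D, -es$D)
  expect_equal(es2$s_edge, es$s_edge)
  # identical correlation in both conditions -> D = 0 -> clamp floor
  es3 <- edgeScore(c(1:5, 1:5), c(1:5, 1:5), cond)
  expect_equal(es3$D, 0)
  expect_equal(es3$s_edge, qnorm(1e-15))
  # constant vector: r treated as 0 with a warning
  expect_warning(es4 <- edgeScore(c(rep(1, 5), 1:5), c(1:5, 5:1), cond),
                 "constant")
  expect_equal(es4$r_case, 0)
  expect_error(edgeScore(1:6, 6:1, rep(c("case", "control"), each = 3)),
               "> 3 samples")
})

test_that("fflScore is the gamma-weighted mean of means", {
  expect_identical(fflScore(c(1, 2, 3), c(0, 1, 2), gamma = 0.5), 1.5)
  # equal node and edge means are a fixed point at any gamma
  expect_equal(fflScore(c(2, 2, 2), c(1, 2, 3), gamma = 0.3), 2)
  # invariant to the storage order of the three edge scores
  expect_equal(fflScore(c(1, 2, 3), c(0, 1, 2)),
               fflScore(c(3, 1, 2), c(2, 0, 1)))
  expect_error(fflScore(c(1, 2), c(0, 1, 2)), "exactly 3")
  expect_error(fflScore(c(1, 2, 3), c(0, 1, 2), gamma = 1.5), "\\(0,1\\)")
})

test_that("scoreFFLs scores triples and a retyped triple identically", {
  net <- synthNetwork(n_tf = 10, n_mirna = 10, n_gene = 20,
                      edge_density = 0.1, n_planted_ffls = 2, seed = 5)
  expr <- synthExpression(net, seed = 6)
  de <- moderatedDE(expr$study)
  ffls <- enumerateFFLs(net$network)
  sc <- scoreFFLs(ffls, expr$study, de)
  expect_equal(nrow(sc), nrow(ffls))
  expect_true(all(is.finite(sc$score)))
  # the score recomputes from its parts (the ffl_score identity)
  expect_equal(sc$score,
               0.5 * rowMeans(sc[c("s_node_tf", "s_node_mirna",
                                   "s_node_gene")]) +
               0.5 * rowMeans(sc[c("s_edge_tm", "s_edge_tg", "s_edge_mg")]),
               tolerance = 1e-12)
  # FB vs TF typing of the same triple cannot change the score
  one <- sc[1, ]
  retyped <- ffls[1, ]; retyped$type <- setdiff(c("TF_FFL", "FB_FFL"),
                                                one$type)[1]
  sc2 <- scoreFFLs(retyped, expr$study, de)
  expect_equal(sc2$score, one$score)
  # missing nodes are skipped and counted
  extra <- rbind(ffls, data.frame(tf = "TFxx", mirna = "m1", gene = "G1",
                                  type = "TF_FFL"))
  expect_message(sc3 <- scoreFFLs(extra, expr$study, de), "skipped")
  expect_equal(attr(sc3, "n_skipped"), 1L)
  expect_equal(nrow(sc3), nrow(ffls))
})

test_that("a fully null FFL scores at the clamp floor", {
  mat <- matrix(rep(c(1, 2, 3, 4, 5), each = 3), 3, 5, byrow = FALSE)
  mat <- cbind(mat, mat)  # identical case/control -> lfc 0, same ranks
  rownames(mat) <- c("T1", "m1", "G1")
  colnames(mat) <- paste0("s", 1:10)
  study <- suppressWarnings(ExpressionStudy(
    mat[c("T1", "G1"), ], mat["m1", , drop = FALSE],
    condition = rep(c("case", "control"), each = 5),
    pair_id = rep(sprintf("D%d", 1:5), 2)))
  de <- data.frame(feature = c("T1", "G1", "m1"), diff_score = 0)
  ffl <- data.frame(tf = "T1", mirna = "m1", gene = "G1", type = "TF_FFL")
  sc <- scoreFFLs(ffl, study, de)
  expect_equal(sc$score, qnorm(1e-15))
})

test_that("permutationNull is seeded, sized, and validated", {
  net <- synthNetwork(n_tf = 10, n_mirna = 10, n_gene = 20,
                      edge_density = 0.1, n_planted_ffls = 0, seed = 2)
  expr <- synthExpression(net, seed = 3)
  de <- moderatedDE(expr$study)
  n1 <- permutationNull(net$network, expr$study, de, n_draws = 50, seed = 9)
  n2 <- permutationNull(net$network, expr$study, de, n_draws = 50, seed = 9)
  expect_identical(nullScores(n1), nullScores(n2))
  expect_length(nullScores(permutationNull(net$network, expr$study, de,
                                           n_draws = 1, seed = 1)), 1L)
  # empty eligible class -> error
  de_missing <- de[!de$feature %in% nodeIds(net$network, "miRNA"), ]
  expect_error(permutationNull(net$network, expr$study, de_missing,
                               n_draws = 10, seed = 1), "empty eligible")
})

test_that("empiricalPvalues counts strict exceedances", {
  null <- new("FFLNull", scores = c(6, 6, 1, 1), nDraws = 4L, seed = 1L)
  expect_equal(empiricalPvalues(5, null), 0.5)
  expect_equal(empiricalPvalues(7, null), 0)       # above every null score
  expect_equal(empiricalPvalues(6, null), 0)       # ties are not exceedances
  expect_equal(empiricalPvalues(0, null), 1)
  expect_equal(empiricalPvalues(c(5, 7), null), c(0.5, 0))
  # pseudocount variant
  expect_equal(empiricalPvalues(7, null, pseudocount = TRUE), 1 / 5)
})

test_that("dysregulatedNetwork merges FFLs with type-faithful edges", {
  ffls <- data.frame(
    tf = c("T1", "T2"), mirna = c("m1", "m2"), gene = c("G1", "G1"),
    type = c("TF_FFL", "FB_FFL"), dysregulated = TRUE)
  res <- dysregulatedNetwork(ffls)
  expect_equal(nrow(networkNodes(res$network)), 5L)  # shared gene G1
  expect_equal(unname(res$counts), c(1L, 0L, 1L, 2L))
  expect_equal(sum(res$counts[dysFFL:::.FFL_TYPES]),
               unname(res$counts["total"]))
  e <- networkEdges(res$network)
  expect_true(all(c("tf_mirna", "mirna_tf") %in%
                    e$edge_class[e$source %in% c("T2", "m2") |
                                 e$target %in% c("T2", "m2")]))
  # the TF-FFL contributes no mirna_tf edge
  expect_false(any(e$edge_class == "mirna_tf" & e$source == "m1"))
  expect_error(dysregulatedNetwork(ffls[0, ]), "no dysregulated")
})

test_that("hubFFLs applies the inclusive degree threshold", {
  # T1/m1 serve both FFLs (degree >= 2); G1 and G2 have degree 2 and 2;
  # T2/m2 appear once each
  ffls <- data.frame(
    tf = c("T1", "T1", "T2"), mirna = c("m1", "m1", "m2"),
    gene = c("G1", "G2", "G1"), type = "TF_FFL", dysregulated = TRUE)
  merged <- dysregulatedNetwork(ffls)$network
  # degrees: T1=3, m1=3, G1=4, G2=2, T2=2, m2=2
  res2 <- hubFFLs(ffls, merged, min_degree = 2)
  expect_equal(nrow(res2$hub_ffls), 3L)   # threshold is inclusive
  # strictness: G2 (degree 2) disqualifies its FFL at min_degree = 3
  res3 <- hubFFLs(ffls, merged, min_degree = 3)
  expect_equal(nrow(res3$hub_ffls), 1L)
  expect_equal(res3$hub_ffls$gene, "G1")
  # monotone non-increasing in min_degree
  sizes <- vapply(1:5, function(k)
    nrow(hubFFLs(ffls, merged, min_degree = k)$hub_ffls), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("cancerGeneEnrichment matches hand-rolled Fisher summation", {
  subset <- paste0("g", 1:5)
  background <- paste0("g", 1:20)
  known <- c(paste0("g", 1:4), "g6")  # 4 of 5 in subset, 1 of 15 outside
  res <- cancerGeneEnrichment(subset, background, known)
  expect_equal(unname(res$table[1, ]), c(4L, 1L))
  expect_equal(res$p_value, bruteFisher2x2(res$table), tolerance = 1e-9)
  # degenerate cases
  expect_equal(cancerGeneEnrichment(background, background, known)$p_value,
               1)
  expect_equal(cancerGeneEnrichment(subset, background,
                                    character())$p_value, 1)
  expect_error(cancerGeneEnrichment(c("zz", subset), background, known),
               "contained")
})

test_that("empirical p is uniform when scores come from the null itself", {
  net <- synthNetwork(n_tf = 120, n_mirna = 120, n_gene = 120,
                      edge_density = 0, n_planted_ffls = 120, seed = 21)
  expr <- synthExpression(net, effect_lfc = 0, coexpr_delta = 0, seed = 22)
  de <- moderatedDE(expr$study)
  null <- permutationNull(net$network, expr$study, de, n_draws = 4000,
                          seed = 23)
  sc <- scoreFFLs(enumerateFFLs(net$network), expr$study, de)
  p <- empiricalPvalues(sc$score, null)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})
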