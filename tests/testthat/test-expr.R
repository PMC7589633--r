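test_that("quantileNormalize maps columns onto the rank-mean reference", {
  m <- matrix(c(1, 5, 3, 7), nrow = 2)  # columns (1,5) and (3,7)
  expect_equal(quantileNormalize(m), matrix(c(2, 6, 2, 6), nrow = 2))
  # identical columns are a fixed point
  m2 <- matrix(rep(c(2, 4, 9), 3), ncol = 3)
  expect_equal(quantileNormalize(m2), m2)
  # post-condition: all column sorted vectors equal the reference, exactly
  set.seed(1)
  m3 <- matrix(rnorm(60), 12, 5)
  q <- quantileNormalize(m3)
  ref <- rowMeans(apply(m3, 2, sort))
  for (j in 1:5) expect_equal(sort(q[, j]), ref, ignore_attr = TRUE)
  # agreement with limma's implementation on tie-free data
  expect_equal(q, limma::normalizeQuantiles(m3), ignore_attr = TRUE)
  expect_error(quantileNormalize(matrix(c(1, NA), 1)), "missing")
  expect_error(quantileNormalize(matrix(1:3, 3, 1)), "2 columns")
})

test_that("quantileNormalize averages reference values across ties", {
  m <- matrix(c(1, 1, 4, 2, 3, 8), nrow = 3)
  q <- quantileNormalize(m)
  ref <- rowMeans(apply(m, 2, sort))  # (1.5, 2, 6)
  expect_equal(q[1:2, 1], rep(mean(ref[1:2]), 2))
  expect_equal(q[, 2], ref, ignore_attr = TRUE)
})

test_that("collapseProbes averages probe rows per feature", {
  m <- matrix(c(2, 6, 4, 8), nrow = 2,
              dimnames = list(c("p1", "p2"), c("s1", "s2")))
  out <- collapseProbes(m, c(p1 = "A", p2 = "A"))
  expect_equal(out, matrix(c(4, 6), 1, dimnames = list("A", c("s1", "s2"))))
  # single-probe feature passes through
  out2 <- collapseProbes(m, c(p1 = "A", p2 = "B"))
  expect_equal(out2["A", ], m["p1", ])
  expect_equal(out2["B", ], m["p2", ])
  # hand mean with three probes
  m3 <- matrix(c(0, 0, 9), 3, 1, dimnames = list(paste0("p", 1:3), "s1"))
  expect_equal(unname(collapseProbes(m3, setNames(rep("A", 3),
                                                  rownames(m3)))[1, 1]), 3)
  expect_error(collapseProbes(m, c(p1 = "A")), "not mapped")
  expect_equal(collapseProbes(m, c(p1 = "A"), unmapped = "drop"),
               m["p1", , drop = FALSE], ignore_attr = TRUE)
  expect_error(collapseProbes(m, data.frame(probe = c("p1", "p1", "p2"),
                                            feature = c("A", "B", "B"))),
               "two features")
})

test_that("moderatedDE recovers the ordinary paired t at prior_df = 0", {
  study <- toyStudy(n_feat = 20, effects = c(2, -1.5))
  de <- moderatedDE(study, prior_df = 0)
  mat <- SummarizedExperiment::assay(study)
  cond <- sampleCondition(study)
  d <- mat[, cond == "case"] - mat[, cond == "control"]
  for (i in c(1, 2, 7)) {
    tt <- t.test(d[i, ])
    row <- de[de$feature == rownames(mat)[i], ]
    expect_equal(row$log2FC, unname(tt$estimate), tolerance = 1e-12)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-12)
  }
})

test_that("moderatedDE limiting cases and diff_score follow the model", {
  # the worked 5-pair differences: oracle t-test on the differences
  diffs <- c(1.0, 1.2, 0.8, 1.1, 0.9)
  base <- matrix(rnorm(10 * 5, 8, 0.4), 10, 5)
  case <- base; case[1, ] <- base[1, ] + diffs
  rownames(base) <- rownames(case) <- sprintf("G%02d", 1:10)
  mat <- cbind(case, base)
  colnames(mat) <- paste0(rep(c("case", "control"), each = 5), "_", 1:5)
  study <- ExpressionStudy(mat, NULL,
                           condition = rep(c("case", "control"), each = 5),
                           pair_id = rep(sprintf("D%d", 1:5), 2))
  de0 <- moderatedDE(study, prior_df = 0)
  tt <- t.test(diffs)
  expect_equal(de0$p_value[1], tt$p.value, tolerance = 1e-10)
  expect_equal(de0$log2FC[1], mean(diffs), tolerance = 1e-10)
  # prior_df = Inf equals the z-test on the pooled variance
  deInf <- moderatedDE(study, prior_df = Inf)
  cond <- sampleCondition(study)
  d <- mat[, cond == "case"] - mat[, cond == "control"]
  pooled <- mean(apply(d, 1, var))
  z <- rowMeans(d) / sqrt(pooled / 5)
  expect_equal(deInf$p_value, unname(2 * pnorm(-abs(z))), tolerance = 1e-10)
  # diff_score definition
  expect_equal(de0$diff_score,
               (-log10(de0$p_value)) * abs(de0$log2FC), tolerance = 1e-12)
})

test_that("moderatedDE agrees with limma's eBayes pipeline", {
  study <- toyStudy(n_feat = 60, effects = c(3, 2, -2), seed = 9)
  de <- moderatedDE(study)
  mat <- SummarizedExperiment::assay(study)
  cond <- sampleCondition(study)
  pair <- samplePair(study)
  d <- mat[, cond == "case"] -
    mat[, cond == "control"][, match(pair[cond == "case"],
                                     pair[cond == "control"])]
  fit <- limma::eBayes(limma::lmFit(d, design = matrix(1, ncol(d), 1)))
  expect_equal(de$p_value, unname(fit$p.value[, 1]), tolerance = 1e-9)
  expect_equal(de$log2FC, unname(fit$coefficients[, 1]), tolerance = 1e-12)
})

test_that("moderatedDE handles degenerate features and validates design", {
  mat <- matrix(rnorm(40, 8), 4, 10)
  mat[1, ] <- 5  # constant feature
  rownames(mat) <- paste0("G", 1:4)
  colnames(mat) <- paste0("s", 1:10)
  study <- ExpressionStudy(mat, NULL,
                           condition = rep(c("case", "control"), each = 5),
                           pair_id = rep(sprintf("D%d", 1:5), 2))
  de <- moderatedDE(study)
  expect_equal(de$log2FC[1], 0)
  expect_equal(de$p_value[1], 1)
  expect_equal(de$diff_score[1], 0)
  # single pair: zero residual df
  m1 <- matrix(rnorm(8, 8), 4, 2,
               dimnames = list(paste0("G", 1:4), c("a", "b")))
  s1 <- ExpressionStudy(m1, NULL, condition = c("case", "control"),
                        pair_id = c("D1", "D1"))
  expect_error(moderatedDE(s1), ">= 2 pairs")
})

test_that("moderatedDE p-values are uniform under the null", {
  study <- toyStudy(n_feat = 2000, seed = 11)
  de <- moderatedDE(study)
  ks <- suppressWarnings(ks.test(de$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("moderatedDE computes FDR within feature class", {
  study <- toyStudy(n_feat = 30, n_mirna = 20, effects = c(3, 3), seed = 3)
  de <- moderatedDE(study)
  for (cl in c("gene", "miRNA")) {
    sel <- de$class == cl
    expect_equal(de$fdr[sel], p.adjust(de$p_value[sel], "BH"))
  }
})

test_that("deSets thresholds match reported example calls", {
  rec <- data.frame(
    feature = c("IFNG", "FOS", "BAX", "RELA"),
    log2FC = c(4.513, -3.765, 0.11, 0.957),
    p_value = c(0.012, 0.0005, 0.463, 0.033))
  sets <- deSets(rec, p_max = 0.05, lfc_min = 1)
  expect_true("IFNG" %in% sets$up)     # strong significant up
  expect_true("FOS" %in% sets$down)    # strong significant down
  expect_false("BAX" %in% c(sets$up, sets$down))   # null gene
  expect_false("RELA" %in% c(sets$up, sets$down))  # significant but |FC|<1
  expect_length(intersect(sets$up, sets$down), 0)
  # tightening thresholds shrinks both sets monotonically
  tight <- deSets(rec, p_max = 0.01, lfc_min = 2)
  expect_true(all(tight$up %in% sets$up))
  expect_true(all(tight$down %in% sets$down))
})
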