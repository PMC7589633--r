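test_that("readRegulations parses edge lists, headers and comments", {
  f <- writeTempTsv(c("# comment", "T1\tG1", "", "T1\tG2"))
  reg <- readRegulations(f, "tf_gene")
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$target, c("G1", "G2"))
  expect_true(all(reg$edge_class == "tf_gene"))

  # empty file -> zero rows, right columns
  empty <- readRegulations(writeTempTsv(character()), "mirna_gene")
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("source", "target", "edge_class", "provenance"))

  # header detected and dropped
  reg2 <- readRegulations(writeTempTsv(c("source\ttarget", "m1\tG1")),
                          "mirna_gene")
  expect_equal(nrow(reg2), 1L)

  # self-loop survives parsing (removed only at build)
  reg3 <- readRegulations(writeTempTsv("T1\tT1"), "tf_gene")
  expect_equal(nrow(reg3), 1L)

  expect_error(readRegulations(writeTempTsv(c("T1\tG1", "T2")), "tf_gene"),
               "line 2")
  expect_error(readRegulations(tempfile(), "tf_gene"), "not found")
})

test_that("buildNetwork unions, deduplicates, removes self-loops", {
  regs <- list(
    data.frame(source = c("T1", "T1", "T2", "T1"),
               target = c("G1", "G2", "G3", "T1"),
               edge_class = "tf_gene", provenance = "dbA"),
    data.frame(source = c("T1", "T1", "T2"),
               target = c("G1", "m1", "m2"),
               edge_class = c("tf_gene", "tf_mirna", "tf_mirna"),
               provenance = "dbB"),
    data.frame(source = c("m1", "m1", "m2", "m2"),
               target = c("G1", "G2", "G3", "G4"),
               edge_class = "mirna_gene", provenance = "dbA"))
  net <- buildNetwork(regs)
  # 3 tf_gene + 2 tf_mirna + 4 mirna_gene after dedup + self-loop removal
  expect_equal(unname(edgeCounts(net)[c("tf_gene", "tf_mirna",
                                        "mirna_gene")]),
               c(3L, 2L, 4L))
  expect_equal(net@removedSelfLoops, 1L)
  e <- networkEdges(net)
  expect_false(any(e$source == e$target))
  # duplicate edge from two databases: one edge, provenance concatenated
  dup <- e[e$source == "T1" & e$target == "G1", ]
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$provenance, "dbA;dbB")
  # idempotence: rebuilding from the built edges changes nothing
  again <- buildNetwork(networkEdges(net))
  expect_equal(networkEdges(again), networkEdges(net))
  expect_equal(networkNodes(again), networkNodes(net))
})

test_that("node classes are derived strictly, TF-TF regulation allowed", {
  # m1 appears as miRNA source and as mirna_gene target of m2 -> conflict
  bad <- data.frame(source = c("m1", "m2"), target = c("G1", "m1"),
                    edge_class = c("mirna_gene", "mirna_gene"),
                    provenance = "x")
  expect_error(buildNetwork(bad), "class conflict.*m1")
  # a TF as tf_gene target keeps class TF
  ok <- data.frame(source = c("T1", "T2", "T2"),
                   target = c("T2", "G1", "m1"),
                   edge_class = c("tf_gene", "tf_gene", "tf_mirna"),
                   provenance = "x")
  net <- buildNetwork(ok)
  nodes <- networkNodes(net)
  expect_equal(nodes$node_class[nodes$id == "T2"], "TF")
  expect_equal(sort(nodeIds(net, "gene")), "G1")
})

test_that("degreeDistribution matches hand counts and an independent fit", {
  star <- buildNetwork(data.frame(
    source = "T1", target = paste0("G", 1:5), edge_class = "tf_gene",
    provenance = ""))
  dd <- degreeDistribution(star)$degrees
  expect_equal(dd$degree[dd$id == "T1"], 5L)
  expect_true(all(dd$degree[dd$id != "T1"] == 1L))

  single <- buildNetwork(data.frame(source = "T1", target = "G1",
                                    edge_class = "tf_gene",
                                    provenance = ""))
  expect_warning(res <- degreeDistribution(single), "fit undefined")
  expect_true(all(res$degrees$degree == 1L))
  expect_null(res$fit)

  net <- synthNetwork(n_tf = 30, n_mirna = 30, n_gene = 120,
                      edge_density = 0.05, n_planted_ffls = 0, seed = 7)
  fit <- degreeDistribution(net$network)$fit
  expect_lt(fit$slope, 0)
  # refit with a second least-squares route
  deg <- degreeDistribution(net$network)$degrees$degree
  freq <- table(deg[deg > 0])
  x <- log10(as.numeric(names(freq))); y <- log10(as.numeric(freq))
  slope2 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(fit$slope, slope2, tolerance = 1e-12)
  r2 <- sum((x - mean(x)) * (y - mean(y)))^2 /
    (sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)
})

test_that("readGeneSets parses GMT, deduplicates, rejects name clashes", {
  gsc <- readGeneSets(writeTempTsv(c("S1\tdesc\tA\tB",
                                     "S2\tdesc\tA\tC\tC\tD")))
  expect_equal(length(geneSets(gsc)), 2L)
  expect_equal(geneSets(gsc)$S1, c("A", "B"))
  expect_equal(geneSets(gsc)$S2, c("A", "C", "D"))  # repeated member once
  expect_error(readGeneSets(writeTempTsv(c("S1\td\tA", "S1\td\tB"))),
               "duplicate")
  expect_error(GeneSetCollection(list(S1 = character())), "empty")
})

test_that("writeNetwork round-trips TSV, emits SIF and GraphML", {
  net <- toyFFLNetwork()
  f <- tempfile(fileext = ".tsv")
  writeNetwork(net, f, "tsv")
  back <- readNetworkTSV(f)
  expect_equal(networkEdges(back), networkEdges(net))
  expect_equal(networkNodes(back), networkNodes(net))

  sif <- tempfile(fileext = ".sif")
  writeNetwork(net, sif, "sif")
  lines <- readLines(sif)
  expect_true("T1\ttf_gene\tG1" %in% lines)
  expect_equal(length(lines), nrow(networkEdges(net)))

  gml <- tempfile(fileext = ".graphml")
  writeNetwork(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 3L)
  expect_equal(igraph::gsize(g), 4L)

  # empty network -> valid (empty) file
  emptyf <- tempfile(fileext = ".sif")
  writeNetwork(new("RegulatoryNetwork"), emptyf, "sif")
  expect_equal(length(readLines(emptyf)), 0L)
  expect_error(writeNetwork(net, f, "xml"), "arg")
})
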