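test_that("edges require coexpression, binding, and a TF endpoint", {
  inp <- make_edge_inputs()
  net <- assemble_grn(inp$genes, inp$cx, inp$bm, tf_list = "TF1")
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$tf, "TF1")
  expect_equal(net$edges$target, "G1")
  # G1-G2: strongest correlation of all, but neither gene is a TF with
  # binding evidence, so no edge exists
  expect_false(any(net$edges$target == "G2"))
  # TF1-G3 correlates at 0.95 but has no enriched motif hit: no edge
  expect_false(any(net$edges$target == "G3"))
  expect_true(all(net$nodes$gene %in% inp$genes))
})

test_that("PCC and FDR boundaries are inclusive in the edge rule", {
  inp <- make_edge_inputs()
  inp$cx$pcc["TF1", "G1"] <- inp$cx$pcc["G1", "TF1"] <- 0.9
  inp$cx$q["TF1", "G1"] <- inp$cx$q["G1", "TF1"] <- 0.05
  net <- assemble_grn(inp$genes, inp$cx, inp$bm, tf_list = "TF1")
  expect_equal(nrow(net$edges), 1)  # both boundaries sit exactly on threshold
  inp$cx$pcc["TF1", "G1"] <- inp$cx$pcc["G1", "TF1"] <- 0.8999
  expect_equal(nrow(assemble_grn(inp$genes, inp$cx, inp$bm, "TF1")$edges), 0)
})

test_that("negative-sign mode selects anti-correlated pairs only", {
  inp <- make_edge_inputs()
  inp$cx$pcc["TF1", "G1"] <- inp$cx$pcc["G1", "TF1"] <- -0.95
  pos <- assemble_grn(inp$genes, inp$cx, inp$bm, "TF1", sign = "positive")
  neg <- assemble_grn(inp$genes, inp$cx, inp$bm, "TF1", sign = "negative")
  expect_equal(nrow(pos$edges), 0)
  expect_equal(nrow(neg$edges), 1)
})

test_that("the Mutual Rank ceiling is an optional extra gate", {
  inp <- make_edge_inputs()
  base <- assemble_grn(inp$genes, inp$cx, inp$bm, "TF1")
  # G1 and G3 tie for TF1's best partner (rank 1.5); TF1 ranks second for
  # G1, so MR(TF1, G1) = sqrt(1.5 * 2)
  expect_equal(inp$cx$mr["TF1", "G1"], sqrt(3))
  withmr <- assemble_grn(inp$genes, inp$cx, inp$bm, "TF1", mr_max = 1.8)
  expect_equal(nrow(withmr$edges), nrow(base$edges))
  strict <- assemble_grn(inp$genes, inp$cx, inp$bm, "TF1", mr_max = 1.5)
  expect_equal(nrow(strict$edges), 0)
})

test_that("an empty DE gene set yields an empty network with a warning", {
  inp <- make_edge_inputs()
  expect_warning(net <- assemble_grn(character(0), inp$cx, inp$bm, "TF1"),
                 "empty")
  expect_equal(nrow(net$edges), 0)
  s <- summarize_network(net)
  expect_equal(s$n_nodes, 0)
  expect_equal(s$n_edges, 0)
})

test_that("pathway connection counts tally distinct TFs only", {
  e <- data.frame(tf = c("TF1", "TF2", "TF2"), target = c("W1", "W1", "W2"),
                  pcc = 0.95, pcc_q = 0.01, mr = 1, motif = "m",
                  best_score = 1, stringsAsFactors = FALSE)
  net <- structure(list(
    nodes = data.frame(gene = c("TF1", "TF2", "W1", "W2"),
                       is_tf = c(TRUE, TRUE, FALSE, FALSE)),
    edges = e,
    thresholds = list(pcc_min = 0.9, q_max = 0.05, sign = "positive",
                      mr_max = NULL)), class = "regulatory_network")
  s <- summarize_network(net, pathway_genes = c("W1", "W2", "W3"))
  expect_equal(unname(s$pathway_tf_connections), c(2, 1, 0))
  expect_equal(unname(s$tf_out_degree), c(1, 2))
  expect_true(sum(s$tf_out_degree) >= s$n_edges)
})

test_that("network export is deterministic and round-trips the edge list", {
  sm <- small_fixture()
  d1 <- file.path(tempdir(), "net1"); d2 <- file.path(tempdir(), "net2")
  run <- run_pipeline(sm$dir, d1, quiet = TRUE)
  export_network(run$network, d2)
  for (f in c("network_edges.tsv", "network_nodes.tsv", "network.graphml")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  edges <- read.delim(file.path(d1, "network_edges.tsv"))
  expect_equal(nrow(edges), summarize_network(run$network)$n_edges)
  expect_identical(edges$tf, run$network$edges$tf)
  g <- igraph::read_graph(file.path(d1, "network.graphml"), format = "graphml")
  expect_equal(igraph::ecount(g), nrow(run$network$edges))
  expect_equal(igraph::vcount(g), nrow(run$network$nodes))
})

test_that("recovery metrics follow the precision/recall definitions", {
  truth <- list(true_edges = data.frame(tf = rep("T", 10),
                                        target = paste0("g", 1:10)))
  net <- list(edges = data.frame(tf = rep("T", 10),
                                 target = paste0("g", c(1:9, 99))))
  m <- evaluate_recovery(net, truth)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$f1, 0.9)
  perfect <- evaluate_recovery(list(edges = truth$true_edges), truth)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  none <- evaluate_recovery(list(edges = data.frame(tf = character(),
                                                    target = character())),
                            truth)
  expect_equal(none$precision, 0)
  expect_true(none$empty_prediction)
})
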