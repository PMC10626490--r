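#' Assemble the gene regulatory network
#'
#' Builds directed TF-to-partner edges from the DE-selected gene set, the
#' coexpression result, and the promoter binding map. An edge (TF, partner)
#' is kept when both genes were DE-selected, the pair's Pearson correlation
#' reaches `pcc_min` (or `-pcc_min` for `sign = "negative"`), the
#' correlation-test FDR is at most `q_max` (inclusive), the TF's enriched
#' motif has a hit in the partner's promoter (a binding-map row), and,
#' optionally, the pair's Mutual Rank is at most `mr_max`. Every edge has at
#' least one TF endpoint by construction; mutual TF-TF binding yields two
#' directed edges.
#'
#' @param de_genes Character vector of selected genes ([select_de_genes()]).
#' @param coexpression A `coexpression_result` over (at least) those genes.
#' @param binding_map A [build_binding_map()] result.
#' @param tf_list Character vector of TF gene ids.
#' @param pcc_min Correlation threshold, boundary inclusive (default 0.9).
#' @param q_max Correlation-FDR threshold, boundary inclusive (default 0.05).
#' @param sign `"positive"` (default) or `"negative"` coexpression mode.
#' @param mr_max Optional Mutual Rank ceiling (default `NULL`, disabled).
#' @param de_table Optional `de_table` used to annotate nodes.
#' @return Object of class `regulatory_network`: list with `nodes` (gene,
#'   is_tf, plus DE annotations when available), `edges` (tf, target, pcc,
#'   pcc_q, mr, motif, best_score), and `thresholds`.
#' @export
assemble_grn <- function(de_genes, coexpression, binding_map, tf_list,
                         pcc_min = 0.9, q_max = 0.05,
                         sign = c("positive", "negative"), mr_max = NULL,
                         de_table = NULL) {
  sign <- match.arg(sign)
  stopifnot(is(coexpression, "coexpression_result"))
  if (!length(de_genes)) {
    warning("empty DE gene set; returning empty network")
    binding_map <- binding_map[0, , drop = FALSE]
  }
  unknown_tf <- setdiff(tf_list, coexpression$genes)
  if (length(unknown_tf))
    warning("TF(s) absent from coexpression result: ",
            paste(unknown_tf, collapse = ", "))
  pcc <- coexpression$pcc; q <- coexpression$q; mr <- coexpression$mr
  keep <- logical(nrow(binding_map))
  for (i in seq_len(nrow(binding_map))) {
    a <- binding_map$tf[i]; b <- binding_map$target[i]
    if (!(a %in% de_genes && b %in% de_genes)) next
    if (!(a %in% tf_list)) next
    if (!(a %in% rownames(pcc) && b %in% rownames(pcc))) next
    r <- pcc[a, b]
    if (is.na(r)) next
    ok_r <- if (sign == "positive") r >= pcc_min else r <= -pcc_min
    if (!ok_r) next
    if (is.na(q[a, b]) || q[a, b] > q_max) next
    if (!is.null(mr_max) && (is.na(mr[a, b]) || mr[a, b] > mr_max)) next
    keep[i] <- TRUE
  }
  bm <- binding_map[keep, , drop = FALSE]
  edges <- if (nrow(bm)) data.frame(
    tf = bm$tf, target = bm$target,
    pcc = pcc[cbind(bm$tf, bm$target)],
    pcc_q = q[cbind(bm$tf, bm$target)],
    mr = mr[cbind(bm$tf, bm$target)],
    motif = bm$motif, best_score = bm$best_score,
    stringsAsFactors = FALSE
  ) else data.frame(tf = character(), target = character(), pcc = numeric(),
                    pcc_q = numeric(), mr = numeric(), motif = character(),
                    best_score = numeric(), stringsAsFactors = FALSE)
  edges <- edges[order(edges$tf, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  node_ids <- sort(unique(c(edges$tf, edges$target)))
  nodes <- data.frame(gene = node_ids,
                      is_tf = node_ids %in% tf_list,
                      stringsAsFactors = FALSE)
  if (!is.null(de_table)) {
    m <- match(nodes$gene, de_table$gene)
    nodes$fold_change <- de_table$fold_change[m]
    nodes$fdr <- de_table$fdr[m]
    nodes$mean_epidermis <- de_table$mean_group1[m]
    nodes$mean_other <- de_table$mean_group2[m]
  }
  net <- structure(
    list(nodes = nodes, edges = edges,
         thresholds = list(pcc_min = pcc_min, q_max = q_max, sign = sign,
                           mr_max = mr_max)),
    class = "regulatory_network"
  )
  validate_network(net, tf_list)
  net
}

# re-validate the structural invariants of an assembled network
validate_network <- function(net, tf_list) {
  e <- net$edges
  if (nrow(e)) {
    if (!all(e$tf %in% tf_list))
      stop("network invariant violated: edge without a TF endpoint")
    thr <- net$thresholds
    ok <- if (thr$sign == "positive") all(e$pcc >= thr$pcc_min)
          else all(e$pcc <= -thr$pcc_min)
    if (!ok) stop("network invariant violated: edge below PCC threshold")
    if (any(e$pcc_q > thr$q_max))
      stop("network invariant violated: edge above FDR threshold")
  }
  invisible(net)
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (pcc >=", x$thresholds$pcc_min, ", q <=", x$thresholds$q_max,
      ",", x$thresholds$sign, ")\n")
  invisible(x)
}

#' Summarize a regulatory network
#'
#' Node and edge counts, per-TF out-degree, and — for an optional pathway
#' gene list — the number of distinct TFs connected to each pathway gene
#' (the "TF connections" annotation; genes absent from the network report
#' 0).
#'
#' @param network A `regulatory_network`.
#' @param pathway_genes Optional character vector of genes of interest.
#' @return Object of class `network_summary`: list with `n_nodes`,
#'   `n_edges`, `tf_out_degree` (named vector), `pathway_tf_connections`
#'   (named vector, when requested).
#' @export
summarize_network <- function(network, pathway_genes = NULL) {
  e <- network$edges
  tfs <- network$nodes$gene[network$nodes$is_tf]
  outdeg <- setNames(integer(length(tfs)), tfs)
  if (nrow(e)) {
    tab <- table(e$tf)
    outdeg[names(tab)] <- as.integer(tab)
  }
  res <- list(n_nodes = nrow(network$nodes), n_edges = nrow(e),
              tf_out_degree = outdeg)
  if (!is.null(pathway_genes)) {
    conn <- vapply(pathway_genes, function(g)
      length(unique(e$tf[e$target == g])), integer(1))
    res$pathway_tf_connections <- conn
  }
  structure(res, class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("network_summary:", x$n_nodes, "nodes,", x$n_edges, "edges\n")
  if (!is.null(x$pathway_tf_connections)) {
    cat("TF connections per pathway gene:\n")
    print(x$pathway_tf_connections)
  }
  invisible(x)
}

#' Export a regulatory network
#'
#' Writes the edge list and node table as TSV (rows ordered
#' lexicographically by TF then target, so repeated exports are
#' byte-identical) and the full attributed graph as Cytoscape-loadable
#' GraphML.
#'
#' @param network A `regulatory_network`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"network"`).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_network <- function(network, dir, prefix = "network") {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir)
  edge_path <- file.path(dir, paste0(prefix, "_edges.tsv"))
  node_path <- file.path(dir, paste0(prefix, "_nodes.tsv"))
  gml_path <- file.path(dir, paste0(prefix, ".graphml"))
  .write_tsv(network$edges, edge_path)
  .write_tsv(network$nodes, node_path)
  g <- igraph::graph_from_data_frame(
    if (nrow(network$edges)) network$edges else
      data.frame(tf = character(), target = character()),
    directed = TRUE, vertices = network$nodes)
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(edges = edge_path, nodes = node_path, graphml = gml_path))
}

#' Score a network against the planted truth
#'
#' Compares the network's directed TF-to-target edges with the generator's
#' planted edge set.
#'
#' @param network A `regulatory_network`.
#' @param truth A `planted_truth` (needs `true_edges`).
#' @return List with `precision`, `recall`, `f1`, `n_predicted`, `n_true`,
#'   `n_overlap`, and `empty_prediction` flag (precision defined as 0 when
#'   nothing is predicted).
#' @export
evaluate_recovery <- function(network, truth) {
  pred <- unique(paste(network$edges$tf, network$edges$target, sep = "->"))
  true <- unique(paste(truth$true_edges$tf, truth$true_edges$target, sep = "->"))
  overlap <- length(intersect(pred, true))
  empty <- length(pred) == 0
  precision <- if (empty) 0 else overlap / length(pred)
  recall <- if (length(true) == 0) NA_real_ else overlap / length(true)
  f1 <- if (empty || is.na(recall) || precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       n_predicted = length(pred), n_true = length(true),
       n_overlap = overlap, empty_prediction = empty)
}
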