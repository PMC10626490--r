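#' Pipeline configuration
#'
#' Collects every tunable threshold of the GRN pipeline in one validated
#' object. The defaults are the published selection rules: expression
#' TPM >= 5 in at least one cell-type mean, DE fold >= 5 with FDR < 0.05,
#' edge PCC >= 0.9 with correlation FDR <= 0.05, 1-kb promoters, and
#' motif-enrichment q < 0.05.
#'
#' @param tpm_min Cell-type mean TPM expression threshold (default 5).
#' @param fold_min Minimum linear DE fold change, inclusive (default 5).
#' @param de_fdr_max Strict DE FDR bound (default 0.05).
#' @param direction DE direction for network genes (default `"up"`).
#' @param pcc_min Edge correlation threshold, inclusive (default 0.9).
#' @param edge_q_max Edge correlation-FDR bound, inclusive (default 0.05).
#' @param sign Coexpression sign mode, `"positive"` or `"negative"`.
#' @param mr_max Optional Mutual Rank ceiling for edges (default disabled).
#' @param promoter_length Promoter length in bases (default 1000).
#' @param min_score_fraction Relative PWM score threshold (default 0.85).
#' @param enrichment_q CRE enrichment q threshold (default 0.05).
#' @param sample_mode Correlation sample mode (`"replicates"` or
#'   `"celltype_means"`).
#' @param transform Correlation expression transform (`"log2"` or
#'   `"linear"`).
#' @param pseudocount DE fold-change pseudocount (default 0.5).
#' @param epidermis_celltype Numerator cell type of the DE contrast.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(tpm_min = 5, fold_min = 5, de_fdr_max = 0.05,
                            direction = c("up", "down", "both"),
                            pcc_min = 0.9, edge_q_max = 0.05,
                            sign = c("positive", "negative"), mr_max = NULL,
                            promoter_length = 1000, min_score_fraction = 0.85,
                            enrichment_q = 0.05,
                            sample_mode = c("replicates", "celltype_means"),
                            transform = c("log2", "linear"),
                            pseudocount = 0.5,
                            epidermis_celltype = "epidermis") {
  direction <- match.arg(direction)
  sign <- match.arg(sign)
  sample_mode <- match.arg(sample_mode)
  transform <- match.arg(transform)
  cfg <- as.list(environment())
  num <- c("tpm_min", "fold_min", "de_fdr_max", "pcc_min", "edge_q_max",
           "promoter_length", "min_score_fraction", "enrichment_q",
           "pseudocount")
  for (f in num) if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 ||
                     !is.finite(cfg[[f]]) || cfg[[f]] < 0)
    stop("'", f, "' must be a single nonnegative number")
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config: TPM >=", x$tpm_min, "| fold >=", x$fold_min,
      ", FDR <", x$de_fdr_max, "| PCC >=", x$pcc_min, ", q <=", x$edge_q_max,
      "(", x$sign, ") | promoter", x$promoter_length, "bp, score frac",
      x$min_score_fraction, ", enrichment q <", x$enrichment_q, "\n")
  invisible(x)
}

#' Run the full GRN pipeline on a fixture directory
#'
#' Executes the stages expression (filter, TMM, differential expression,
#' gene selection), coexpression (Pearson + Mutual Rank), motifs (promoter
#' extraction, PWM scanning, CRE enrichment, binding map) and network
#' (assembly, summary, export) in order, writing every stage's table, the
#' network exports, a JSON summary with stage-wise gene/edge counts, and a
#' run log. When the fixture carries planted truth, recovery metrics are
#' computed and included.
#'
#' @param fixture_dir Directory written by [write_fixture()] (or laid out
#'   the same way).
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages (default FALSE).
#' @return Invisibly, a list with all intermediate objects (`de_table`,
#'   `de_genes`, `coexpression`, `hits`, `enrichment`, `binding_map`,
#'   `network`, `summary`, `recovery`) plus `paths`.
#' @export
run_pipeline <- function(fixture_dir, out_dir, config = pipeline_config(),
                         quiet = FALSE) {
  stopifnot(is(config, "pipeline_config"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory ", out_dir)
  log_lines <- character(0)
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  say("stemwax pipeline")
  say("thresholds: TPM>=", config$tpm_min, " fold>=", config$fold_min,
      " deFDR<", config$de_fdr_max, " PCC>=", config$pcc_min,
      " edgeQ<=", config$edge_q_max, " sign=", config$sign,
      " scoreFrac=", config$min_score_fraction,
      " enrichQ<", config$enrichment_q)

  fx <- stage("input", read_fixture(fixture_dir))
  ds <- fx$dataset
  say("input: ", nrow(ds$counts), " genes x ", ncol(ds$counts), " samples")

  # -- expression ----------------------------------------------------------
  expressed <- stage("expression", expression_filter(ds, config$tpm_min))
  say("expression filter: ", length(expressed), " genes with cell-type mean TPM >= ",
      config$tpm_min)
  de <- stage("expression", differential_expression(
    ds, group1 = config$epidermis_celltype, genes = expressed,
    pseudocount = config$pseudocount, threshold_tpm = config$tpm_min))
  de_genes <- select_de_genes(de, min_fold = config$fold_min,
                              max_fdr = config$de_fdr_max,
                              direction = config$direction)
  say("differential expression: ", length(de_genes), " genes with fold >= ",
      config$fold_min, ", FDR < ", config$de_fdr_max, " (", config$direction, ")")
  .write_tsv(as.data.frame(de), file.path(out_dir, "de_table.tsv"))

  # -- coexpression --------------------------------------------------------
  cx <- stage("coexpression", pearson_matrix(
    ds$tpm[de_genes, , drop = FALSE], samples = ds$samples,
    sample_mode = config$sample_mode, transform = config$transform))
  .write_tsv(coexpression_table(cx), file.path(out_dir, "coexpression.tsv"))
  say("coexpression: ", length(cx$genes), " genes, ",
      sum(cx$pcc[upper.tri(cx$pcc)] >= config$pcc_min, na.rm = TRUE),
      " pairs with PCC >= ", config$pcc_min)

  # -- motifs --------------------------------------------------------------
  promoters <- stage("motifs", extract_promoters(
    fx$genome, fx$tss, length = config$promoter_length))
  hits <- stage("motifs", scan_promoters_all(
    fx$pwms, promoters, min_score_fraction = config$min_score_fraction))
  say("motif scan: ", nrow(hits), " hits of ", length(fx$pwms),
      " motifs in ", length(promoters), " promoters")
  enr <- stage("motifs", cre_enrichment(
    hits, foreground = intersect(de_genes, names(promoters)),
    background = names(promoters), q_threshold = config$enrichment_q))
  say("CRE enrichment: ", sum(enr$enriched), " of ", nrow(enr),
      " motifs enriched at q < ", config$enrichment_q)
  bm <- stage("motifs", build_binding_map(
    hits, enr, fx$tf_motif_map, genes = de_genes))
  say("binding map: ", nrow(bm), " TF-target promoter-binding pairs")
  .write_tsv(hits, file.path(out_dir, "motif_hits.tsv"))
  .write_tsv(enr, file.path(out_dir, "cre_enrichment.tsv"))
  .write_tsv(as.data.frame(bm), file.path(out_dir, "binding_map.tsv"))

  # -- network -------------------------------------------------------------
  tf_list <- fx$truth$tf_ids
  net <- stage("network", assemble_grn(
    de_genes, cx, bm, tf_list, pcc_min = config$pcc_min,
    q_max = config$edge_q_max, sign = config$sign, mr_max = config$mr_max,
    de_table = de))
  say("network: ", nrow(net$nodes), " nodes, ", nrow(net$edges), " edges")
  paths <- export_network(net, out_dir)
  summ <- summarize_network(net)

  recovery <- NULL
  if (!is.null(fx$truth$true_edges) && nrow(fx$truth$true_edges)) {
    recovery <- evaluate_recovery(net, fx$truth)
    say(sprintf("recovery vs planted truth: precision %.3f recall %.3f F1 %.3f",
                recovery$precision, recovery$recall, recovery$f1))
  }

  summary_json <- list(
    thresholds = unclass(config),
    n_genes_input = nrow(ds$counts),
    n_samples = ncol(ds$counts),
    n_expressed = length(expressed),
    n_de_genes = length(de_genes),
    n_motif_hits = nrow(hits),
    n_enriched_motifs = sum(enr$enriched),
    n_binding_pairs = nrow(bm),
    n_nodes = summ$n_nodes,
    n_edges = summ$n_edges,
    tf_out_degree = as.list(summ$tf_out_degree),
    recovery = recovery
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(config = config, de_table = de, de_genes = de_genes,
                 coexpression = cx, promoters = promoters, hits = hits,
                 enrichment = enr, binding_map = bm, network = net,
                 summary = summ, recovery = recovery,
                 paths = c(paths, summary = file.path(out_dir, "summary.json")),
                 out_dir = out_dir))
}
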