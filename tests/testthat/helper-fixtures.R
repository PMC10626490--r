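# Shared fixtures, built once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

# small fixture for fast unit tests
small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    dir <- file.path(tempdir(), "stemwax_small_fixture")
    cfg <- sim_config(n_genes = 300, module_size = 40, n_tfs = 4,
                      targets_per_tf = 4, seed = 7)
    .fixture_cache$small <- list(sim = simulate_fixture(cfg, dir), dir = dir,
                                 config = cfg)
  }
  .fixture_cache$small
}

# the default study-scale fixture plus a full pipeline run over it
default_run <- function() {
  if (is.null(.fixture_cache$default)) {
    dir <- file.path(tempdir(), "stemwax_default_fixture")
    sim <- simulate_fixture(sim_config(seed = 1), dir)
    out <- file.path(tempdir(), "stemwax_default_out")
    res <- run_pipeline(dir, out, quiet = TRUE)
    .fixture_cache$default <- list(sim = sim, res = res, dir = dir, out = out)
  }
  .fixture_cache$default
}

# builds a valid expression_dataset from a matrix of desired TPM values by
# adding one filler gene per column so TPM columns sum to 1e6
make_dataset <- function(tpm_values, cell_types, replicates = 3,
                         counts = NULL) {
  samples <- data.frame(
    sample = paste(rep(cell_types, each = replicates),
                   rep(seq_len(replicates), length(cell_types)), sep = "_"),
    cell_type = rep(cell_types, each = replicates),
    replicate = rep(seq_len(replicates), length(cell_types)),
    stringsAsFactors = FALSE)
  stopifnot(ncol(tpm_values) == nrow(samples))
  colnames(tpm_values) <- samples$sample
  filler <- 1e6 - colSums(tpm_values)
  stopifnot(all(filler >= 0))
  tpm <- rbind(tpm_values, filler = filler)
  if (is.null(counts)) counts <- round(tpm / 10)
  else counts <- rbind(counts, filler = round(filler / 10))
  dimnames(counts) <- dimnames(tpm)
  expression_dataset(counts, tpm, samples)
}

# minimal hand-built coexpression result for edge-rule tests
fake_coexpression <- function(genes, pcc, q, mr = NULL) {
  if (is.null(mr)) mr <- mutual_rank(pcc)
  structure(list(genes = genes, pcc = pcc, p = q, q = q, mr = mr,
                 n_samples = 18, masked = character(0),
                 sample_mode = "replicates", transform = "log2"),
            class = "coexpression_result")
}

# four genes, one TF, one binding-supported pair, for edge-rule tests
make_edge_inputs <- function() {
  genes <- c("TF1", "G1", "G2", "G3")
  pcc <- matrix(0.5, 4, 4, dimnames = list(genes, genes))
  diag(pcc) <- 1
  pcc["TF1", "G1"] <- pcc["G1", "TF1"] <- 0.95
  pcc["G1", "G2"] <- pcc["G2", "G1"] <- 0.99
  pcc["TF1", "G3"] <- pcc["G3", "TF1"] <- 0.95
  q <- matrix(0.01, 4, 4, dimnames = list(genes, genes))
  q["G1", "G2"] <- q["G2", "G1"] <- 0.001
  diag(q) <- NA
  cx <- fake_coexpression(genes, pcc, q)
  bm <- data.frame(tf = "TF1", target = "G1", motif = "M_TF1",
                   best_score = 10, enrichment_q = 0.001, enriched = TRUE,
                   stringsAsFactors = FALSE)
  class(bm) <- c("binding_map", "data.frame")
  list(genes = genes, cx = cx, bm = bm)
}
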