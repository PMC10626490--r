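#' Simulation configuration for the synthetic cell-type study
#'
#' Defines the study design emulated by the generators: six stem cell types
#' with three biological replicates each, a 200-gene epidermis-upregulated
#' module containing TF regulons whose targets track their TF's expression
#' profile, negative-binomial counts, and 1-kb promoters carrying planted
#' motif instances for every true TF-target edge.
#'
#' @param n_genes Total number of genes (default 2000).
#' @param n_tfs Number of transcription factors with planted regulons
#'   (default 10).
#' @param targets_per_tf Targets per TF (default 5).
#' @param module_size Size of the epidermis-upregulated module, which must
#'   contain all TFs and their targets (default 200).
#' @param cell_types Cell-type labels; must include `"epidermis"`.
#' @param replicates Biological replicates per cell type (default 3).
#' @param epidermis_fold Expected ratio of the epidermis mean to the mean of
#'   the other cell types for module genes (default 8; must exceed 1).
#' @param nb_dispersion Negative-binomial dispersion phi (variance
#'   mu + phi mu^2); 0 gives the noise-free limit in which expected means are
#'   returned unsampled (default 0.05).
#' @param correlation_noise_sd SD (log2 scale) of the per-sample deviation of
#'   a target's expression profile from its TF's (default 0.2); 0 makes
#'   planted pairs perfectly correlated.
#' @param tf_profile_sd SD (log2 scale) of per-regulon cell-type expression
#'   offsets outside the epidermis; this is what separates regulons from one
#'   another (default 1.2).
#' @param promoter_length Promoter length in bases (default 1000).
#' @param motif_length Motif length in bases (default 12).
#' @param base_meanlog,base_sdlog Log-normal parameters of baseline mean
#'   counts for non-module genes.
#' @param module_meanlog,module_sdlog Same for module genes.
#' @param seed Integer seed; all outputs are pure functions of the
#'   configuration including this seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_tfs = 10, targets_per_tf = 5,
                       module_size = 200,
                       cell_types = c("epidermis", "pith_parenchyma", "phloem",
                                      "bundle_sheath", "xylem",
                                      "vascular_parenchyma"),
                       replicates = 3, epidermis_fold = 8,
                       nb_dispersion = 0.05, correlation_noise_sd = 0.2,
                       tf_profile_sd = 1.2, promoter_length = 1000,
                       motif_length = 12,
                       base_meanlog = log(100), base_sdlog = 1.2,
                       module_meanlog = log(150), module_sdlog = 0.5,
                       seed = 1) {
  cfg <- as.list(environment())
  if (n_tfs > 0 && targets_per_tf * n_tfs > n_genes - n_tfs)
    stop("config invariant violated: targets_per_tf * n_tfs <= n_genes - n_tfs")
  if (module_size < n_tfs * (1 + targets_per_tf))
    stop("config invariant violated: module_size must hold all TFs and targets")
  if (module_size > n_genes)
    stop("config invariant violated: module_size <= n_genes")
  if (epidermis_fold <= 1)
    stop("config invariant violated: epidermis_fold > 1")
  if (promoter_length < motif_length)
    stop("config invariant violated: promoter_length >= motif_length")
  if (!"epidermis" %in% cell_types)
    stop("config invariant violated: cell_types must include 'epidermis'")
  if (replicates < 1) stop("config invariant violated: replicates >= 1")
  if (nb_dispersion < 0) stop("config invariant violated: nb_dispersion >= 0")
  if (correlation_noise_sd < 0)
    stop("config invariant violated: correlation_noise_sd >= 0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes,", x$n_tfs, "TFs x", x$targets_per_tf,
      "targets,", length(x$cell_types), "cell types x", x$replicates,
      "replicates, fold", x$epidermis_fold, ", seed", x$seed, "\n")
  invisible(x)
}

.gene_ids <- function(n, prefix = "g") {
  sprintf("%s%0*d", prefix, max(4L, nchar(n)), seq_len(n))
}

#' Generate cell-type count and TPM matrices with planted truth
#'
#' Module genes receive an epidermis mean equal to `epidermis_fold` times the
#' average of their other-cell-type means; each regulon (one TF plus its
#' targets, or one independent module gene) carries its own log2 cell-type
#' profile outside the epidermis, and each target's per-sample log2 mean is
#' its TF's plus Gaussian noise, so TF-target correlation approaches 1 as
#' `correlation_noise_sd` and `nb_dispersion` go to 0. Counts are drawn
#' negative-binomially around the expected means (or returned as the exact
#' means when `nb_dispersion = 0`), gene lengths uniform in 500-5000 bp, and
#' TPM computed from counts and lengths.
#'
#' @param config A [sim_config()].
#' @return List with `dataset` (an [expression_dataset]) and `truth` (class
#'   `planted_truth`: `epidermis_module`, `tf_ids`, `true_edges`,
#'   `true_fold`, `profiles`, `motif_placements` (NULL until
#'   [simulate_promoters()]), `config`).
#' @export
simulate_celltype_counts <- function(config) {
  stopifnot(is(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  ids <- .gene_ids(n)
  ct <- config$cell_types
  nonepi <- setdiff(ct, "epidermis")
  samples <- data.frame(
    sample = paste(rep(ct, each = config$replicates),
                   rep(seq_len(config$replicates), length(ct)), sep = "_"),
    cell_type = rep(ct, each = config$replicates),
    replicate = rep(seq_len(config$replicates), length(ct)),
    stringsAsFactors = FALSE
  )
  ns <- nrow(samples)

  n_tf <- config$n_tfs
  n_tgt <- n_tf * config$targets_per_tf
  module <- ids[seq_len(config$module_size)]
  tf_ids <- if (n_tf > 0) ids[seq_len(n_tf)] else character(0)
  target_ids <- if (n_tgt > 0) ids[n_tf + seq_len(n_tgt)] else character(0)
  indep <- setdiff(module, c(tf_ids, target_ids))
  true_edges <- if (n_tgt > 0) data.frame(
    tf = rep(tf_ids, each = config$targets_per_tf),
    target = target_ids, stringsAsFactors = FALSE
  ) else data.frame(tf = character(0), target = character(0))

  # one profile per regulon, one per independent module gene
  profile_of <- setNames(rep(NA_integer_, n), ids)
  if (n_tf > 0) {
    profile_of[tf_ids] <- seq_len(n_tf)
    profile_of[true_edges$target] <- profile_of[true_edges$tf]
  }
  if (length(indep)) profile_of[indep] <- n_tf + seq_along(indep)
  n_prof <- n_tf + length(indep)
  off <- if (n_prof > 0) matrix(rnorm(n_prof * length(nonepi), 0, config$tf_profile_sd),
                                n_prof, length(nonepi),
                                dimnames = list(NULL, nonepi)) else
    matrix(0, 0, length(nonepi), dimnames = list(NULL, nonepi))

  base <- numeric(n)
  in_mod <- ids %in% module
  base[in_mod] <- rlnorm(sum(in_mod), config$module_meanlog, config$module_sdlog)
  base[!in_mod] <- rlnorm(sum(!in_mod), config$base_meanlog, config$base_sdlog)

  # expected linear mean per gene and cell type
  ctmean <- matrix(base, n, length(ct), dimnames = list(ids, ct))
  if (any(in_mod)) {
    for (g in which(in_mod)) {
      p <- profile_of[g]
      ctmean[g, nonepi] <- base[g] * 2^off[p, ]
      ctmean[g, "epidermis"] <- config$epidermis_fold * mean(ctmean[g, nonepi])
    }
  }
  mu <- ctmean[, samples$cell_type, drop = FALSE]
  colnames(mu) <- samples$sample
  if (length(target_ids) && config$correlation_noise_sd > 0) {
    delta <- matrix(rnorm(length(target_ids) * ns, 0, config$correlation_noise_sd),
                    length(target_ids), ns)
    mu[target_ids, ] <- mu[target_ids, , drop = FALSE] * 2^delta
  }

  counts <- if (config$nb_dispersion > 0) {
    matrix(rnbinom(n * ns, mu = mu, size = 1 / config$nb_dispersion),
           n, ns, dimnames = dimnames(mu))
  } else mu  # noise-free limit: expected means, possibly non-integer

  gene_lengths <- setNames(round(runif(n, 500, 5000)), ids)
  tpm <- tpm_from_counts(counts, gene_lengths)
  dataset <- expression_dataset(counts, tpm, samples, gene_lengths)

  true_fold <- setNames(ifelse(in_mod, config$epidermis_fold, 1), ids)
  truth <- structure(
    list(epidermis_module = module, tf_ids = tf_ids,
         true_edges = true_edges, true_fold = true_fold,
         profiles = profile_of, motif_placements = NULL, config = config),
    class = "planted_truth"
  )
  list(dataset = dataset, truth = truth)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("planted_truth:", length(x$epidermis_module), "module genes,",
      length(x$tf_ids), "TFs,", nrow(x$true_edges), "true edges,",
      if (is.null(x$motif_placements)) 0 else nrow(x$motif_placements),
      "motif placements\n")
  invisible(x)
}

# remove every exact occurrence of any consensus (either strand) from a
# background sequence by point mutation, rescanning until clean
.scrub_consensus <- function(seq, patterns) {
  for (iter in 1:20) {
    found <- FALSE
    for (p in patterns) {
      m <- gregexpr(p, seq, fixed = TRUE)[[1]]
      if (m[1] == -1) next
      found <- TRUE
      for (pos in as.integer(m)) {
        at <- pos + nchar(p) %/% 2
        cur <- substr(seq, at, at)
        substr(seq, at, at) <- sample(setdiff(DNA_BASES4, cur), 1)
      }
    }
    if (!found) return(seq)
  }
  seq
}

.revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Generate promoters, genome, TSS annotation and PWM library
#'
#' Gives every gene a uniform-random background promoter of
#' `promoter_length` bases; for every planted TF-target edge, the TF's motif
#' consensus (or its reverse complement) is written at a random offset of
#' the target's promoter and recorded as a motif placement. Background
#' promoters are guaranteed to contain no exact consensus occurrence of any
#' TF motif on either strand (near-matches may occur by chance). Each
#' promoter is embedded in its own contig with a 50-bp pad so that
#' strand-aware TSS-based extraction round-trips the emitted sequence.
#'
#' @param truth `planted_truth` from [simulate_celltype_counts()].
#' @param config The same [sim_config()].
#' @return List with `promoters` (named character), `genome`
#'   (`DNAStringSet`), `tss` (`GRanges`, BED-exportable), `pwms` (list of
#'   [pwm()]), `tf_motif_map` (data frame `tf`, `motif`), and `truth`
#'   augmented with `motif_placements` (`gene`, `motif`, `offset`,
#'   `strand`).
#' @export
simulate_promoters <- function(truth, config = truth$config) {
  stopifnot(is(truth, "planted_truth"), is(config, "sim_config"))
  set.seed((config$seed %% 1000000000L) + 1L)
  ids <- names(truth$true_fold)
  L <- config$motif_length
  plen <- config$promoter_length

  # distinct informative consensus per TF (no duplicate, none the reverse
  # complement of another)
  consensi <- character(0)
  while (length(consensi) < length(truth$tf_ids)) {
    cand <- paste(sample(DNA_BASES4, L, replace = TRUE), collapse = "")
    if (cand %in% consensi || .revcomp_chr(cand) %in% consensi) next
    consensi <- c(consensi, cand)
  }
  motif_ids <- paste0("M_", truth$tf_ids)
  pwms <- lapply(seq_along(motif_ids), function(i) {
    pfm <- matrix(3, 4, L, dimnames = list(DNA_BASES4, NULL))
    cons <- strsplit(consensi[i], "")[[1]]
    for (k in seq_len(L)) pfm[cons[k], k] <- 91
    pwm(pfm, id = motif_ids[i], name = truth$tf_ids[i])
  })
  names(pwms) <- motif_ids
  tf_motif_map <- data.frame(tf = truth$tf_ids, motif = motif_ids,
                             stringsAsFactors = FALSE)

  patterns <- unique(c(consensi, vapply(consensi, .revcomp_chr, "")))
  proms <- vapply(ids, function(g) {
    s <- paste(sample(DNA_BASES4, plen, replace = TRUE), collapse = "")
    if (length(patterns)) .scrub_consensus(s, patterns) else s
  }, "")

  placements <- NULL
  if (nrow(truth$true_edges)) {
    placements <- do.call(rbind, lapply(seq_len(nrow(truth$true_edges)), function(i) {
      tf <- truth$true_edges$tf[i]; tgt <- truth$true_edges$target[i]
      mi <- match(tf, truth$tf_ids)
      offset <- sample.int(plen - L + 1L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") consensi[mi] else .revcomp_chr(consensi[mi])
      if (offset + L > plen) stop("placement overruns promoter")
      substr(proms[tgt], offset + 1L, offset + L) <<- ins
      data.frame(gene = tgt, motif = motif_ids[mi], offset = offset,
                 strand = strand, stringsAsFactors = FALSE)
    }))
  }

  pad <- 50L
  gstrand <- sample(c("+", "-"), length(ids), replace = TRUE)
  contigs <- character(length(ids)); t0 <- integer(length(ids))
  for (i in seq_along(ids)) {
    down <- paste(sample(DNA_BASES4, pad, replace = TRUE), collapse = "")
    if (gstrand[i] == "+") {
      contigs[i] <- paste0(proms[ids[i]], down)   # TSS right after promoter
      t0[i] <- plen
    } else {
      contigs[i] <- paste0(down, .revcomp_chr(proms[ids[i]]))
      t0[i] <- pad - 1L                           # promoter genomic-downstream
    }
  }
  genome <- Biostrings::DNAStringSet(setNames(contigs, paste0("chr_", ids)))
  tss <- GenomicRanges::GRanges(
    seqnames = paste0("chr_", ids),
    ranges = IRanges::IRanges(start = t0 + 1L, width = 1L),
    strand = gstrand, name = ids, score = 0L
  )
  truth$motif_placements <- placements
  list(promoters = proms, genome = genome, tss = tss, pwms = pwms,
       tf_motif_map = tf_motif_map, truth = truth)
}

#' Generate a complete synthetic fixture
#'
#' Convenience wrapper running [simulate_celltype_counts()] and
#' [simulate_promoters()], optionally writing everything to a fixture
#' directory with [write_fixture()].
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory.
#' @return List with `dataset`, `truth`, `promoters`, `genome`, `tss`,
#'   `pwms`, `tf_motif_map` (and `dir` when written).
#' @export
simulate_fixture <- function(config = sim_config(), dir = NULL) {
  cc <- simulate_celltype_counts(config)
  pr <- simulate_promoters(cc$truth, config)
  sim <- list(dataset = cc$dataset, truth = pr$truth,
              promoters = pr$promoters, genome = pr$genome, tss = pr$tss,
              pwms = pr$pwms, tf_motif_map = pr$tf_motif_map)
  if (!is.null(dir)) {
    write_fixture(sim, dir)
    sim$dir <- dir
  }
  sim
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic fixture to a self-contained directory
#'
#' Emits counts and TPM TSVs (first column `gene`), the sample sheet, gene
#' lengths, genome FASTA, TSS BED6, JASPAR PFM library, TF list, TF-motif
#' map, planted truth (edge list and module membership) and the simulation
#' configuration as JSON — everything the pipeline needs end-to-end.
#'
#' @param sim Output of [simulate_fixture()] (or the same components).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create fixture directory ", dir)
  ds <- sim$dataset
  .write_tsv(data.frame(gene = rownames(ds$counts), ds$counts,
                        check.names = FALSE), file.path(dir, "counts.tsv"))
  .write_tsv(data.frame(gene = rownames(ds$tpm), ds$tpm,
                        check.names = FALSE), file.path(dir, "tpm.tsv"))
  .write_tsv(ds$samples, file.path(dir, "samples.tsv"))
  .write_tsv(data.frame(gene = names(ds$gene_lengths),
                        length_bp = as.integer(ds$gene_lengths)),
             file.path(dir, "gene_lengths.tsv"))
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  rtracklayer::export(sim$tss, file.path(dir, "tss.bed"), format = "BED")
  write_jaspar(sim$pwms, file.path(dir, "motifs.jaspar"))
  writeLines(sim$truth$tf_ids, file.path(dir, "tf_list.txt"))
  .write_tsv(sim$tf_motif_map, file.path(dir, "tf_motif_map.tsv"))
  .write_tsv(sim$truth$true_edges, file.path(dir, "truth_edges.tsv"))
  writeLines(sim$truth$epidermis_module, file.path(dir, "truth_module.txt"))
  if (!is.null(sim$truth$motif_placements))
    .write_tsv(sim$truth$motif_placements, file.path(dir, "truth_placements.tsv"))
  cfg <- sim$truth$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a fixture directory back into memory
#'
#' @param dir Fixture directory written by [write_fixture()].
#' @return List with `dataset`, `truth` (edge list, module, TF ids,
#'   placements when present), `tf_motif_map`, `pwms`, `genome`, `tss`, and
#'   the component file `paths`.
#' @export
read_fixture <- function(dir) {
  rd <- function(f) read.delim(file.path(dir, f), check.names = FALSE,
                               stringsAsFactors = FALSE)
  cts <- rd("counts.tsv"); tpm <- rd("tpm.tsv")
  counts <- as.matrix(cts[, -1]); rownames(counts) <- cts$gene
  tpmm <- as.matrix(tpm[, -1]); rownames(tpmm) <- tpm$gene
  samples <- rd("samples.tsv")
  gl <- rd("gene_lengths.tsv")
  dataset <- expression_dataset(counts, tpmm, samples,
                                setNames(gl$length_bp, gl$gene))
  truth <- list(
    epidermis_module = readLines(file.path(dir, "truth_module.txt")),
    tf_ids = readLines(file.path(dir, "tf_list.txt")),
    true_edges = rd("truth_edges.tsv"),
    motif_placements = if (file.exists(file.path(dir, "truth_placements.tsv")))
      rd("truth_placements.tsv") else NULL
  )
  class(truth) <- "planted_truth"
  paths <- list(genome = file.path(dir, "genome.fa"),
                tss = file.path(dir, "tss.bed"),
                pwms = file.path(dir, "motifs.jaspar"))
  list(dataset = dataset, truth = truth,
       tf_motif_map = rd("tf_motif_map.tsv"),
       pwms = read_jaspar(paths$pwms),
       genome = Biostrings::readDNAStringSet(paths$genome),
       tss = rtracklayer::import(paths$tss, format = "BED"),
       paths = paths)
}
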