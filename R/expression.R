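#' Construct an expression dataset
#'
#' Bundles a gene-level count matrix, the matching TPM matrix, and a sample
#' sheet describing the cell type and replicate of every column. This is the
#' common container consumed by the expression-filtering, normalization and
#' differential-expression steps.
#'
#' @param counts Numeric matrix, genes x samples, nonnegative. Row names are
#'   gene ids, column names sample ids.
#' @param tpm Numeric matrix with identical dimnames; each column sums to 1e6
#'   (within 1e-6 relative) unless the column is all zero.
#' @param samples Data frame with columns `sample`, `cell_type`, `replicate`;
#'   one row per count column, in column order or matchable by `sample`.
#' @param gene_lengths Optional named numeric vector of gene lengths in bp.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(counts, tpm, samples, gene_lengths = NULL) {
  counts <- as.matrix(counts)
  tpm <- as.matrix(tpm)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have gene row names and sample column names")
  if (!identical(dimnames(counts), dimnames(tpm)))
    stop("'counts' and 'tpm' must share identical gene and sample indices")
  if (any(counts < 0) || any(tpm < 0))
    stop("counts and TPM must be nonnegative")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  req <- c("sample", "cell_type", "replicate")
  if (!all(req %in% names(samples)))
    stop("'samples' needs columns: ", paste(req, collapse = ", "))
  if (!setequal(samples$sample, colnames(counts)))
    stop("sample sheet does not match count matrix columns")
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  cs <- colSums(tpm)
  bad <- cs > 0 & abs(cs - 1e6) > 1e-6 * 1e6
  if (any(bad))
    stop("TPM columns do not sum to 1e6: ", paste(colnames(tpm)[bad], collapse = ", "))
  if (!is.null(gene_lengths)) {
    if (is.null(names(gene_lengths)) || !all(rownames(counts) %in% names(gene_lengths)))
      stop("'gene_lengths' must be named and cover all genes")
    gene_lengths <- gene_lengths[rownames(counts)]
  }
  structure(
    list(counts = counts, tpm = tpm, samples = samples, gene_lengths = gene_lengths),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("cell types:", paste(unique(x$samples$cell_type), collapse = ", "), "\n")
  invisible(x)
}

#' Sum transcript-level abundances to gene level
#'
#' Collapses transcript-level count and TPM tables to gene level by summing
#' the rows of all transcripts belonging to the same gene, separately for
#' counts and TPM. Column sums are preserved, so gene-level TPM columns still
#' total 1e6.
#'
#' @param transcript_counts,transcript_tpm Matrices, transcripts x samples,
#'   with transcript ids as row names.
#' @param tx2gene Data frame with columns `transcript` and `gene`; every
#'   transcript row must be mapped exactly once.
#' @return List with gene-level `counts` and `tpm` matrices (genes in first-
#'   appearance order of `tx2gene`).
#' @export
aggregate_transcripts_to_genes <- function(transcript_counts, transcript_tpm, tx2gene) {
  transcript_counts <- as.matrix(transcript_counts)
  transcript_tpm <- as.matrix(transcript_tpm)
  if (!identical(dimnames(transcript_counts), dimnames(transcript_tpm)))
    stop("transcript counts and TPM must share dimnames")
  tx2gene <- as.data.frame(tx2gene, stringsAsFactors = FALSE)
  if (!all(c("transcript", "gene") %in% names(tx2gene)))
    stop("'tx2gene' needs columns 'transcript' and 'gene'")
  if (anyDuplicated(tx2gene$transcript))
    stop("duplicated transcripts in 'tx2gene'")
  txs <- rownames(transcript_counts)
  unmapped <- setdiff(txs, tx2gene$transcript)
  if (length(unmapped) > 0)
    stop("unmapped transcript id(s): ", paste(unmapped, collapse = ", "))
  gene_of <- setNames(tx2gene$gene, tx2gene$transcript)[txs]
  lev <- unique(tx2gene$gene[tx2gene$transcript %in% txs])
  agg <- function(m) {
    out <- rowsum(m, group = factor(gene_of, levels = lev), reorder = TRUE)
    out[lev, , drop = FALSE]
  }
  list(counts = agg(transcript_counts), tpm = agg(transcript_tpm))
}

#' Transcripts-per-million from counts and gene lengths
#'
#' Per column, counts are converted to length-normalized rates
#' (count / length in bp) and rescaled so the column sums to one million.
#'
#' @param counts Matrix, genes x samples, nonnegative.
#' @param gene_lengths_bp Numeric vector of positive gene lengths, one per
#'   gene (recycled by name if named).
#' @return TPM matrix with the dimnames of `counts`; all-zero columns stay
#'   all zero with a warning.
#' @export
tpm_from_counts <- function(counts, gene_lengths_bp) {
  counts <- as.matrix(counts)
  if (!is.null(names(gene_lengths_bp)) && !is.null(rownames(counts)))
    gene_lengths_bp <- gene_lengths_bp[rownames(counts)]
  if (length(gene_lengths_bp) != nrow(counts))
    stop("need one gene length per count row")
  if (any(!is.finite(gene_lengths_bp)) || any(gene_lengths_bp <= 0))
    stop("gene lengths must be positive")
  rate <- counts / gene_lengths_bp
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning("all-zero count column(s): ",
            paste(colnames(counts)[tot == 0], collapse = ", "),
            "; TPM left at zero")
    tot[tot == 0] <- 1
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Cell-type mean TPM expression filter
#'
#' A gene is retained when the mean TPM across replicates of at least one
#' cell type reaches `threshold_tpm`. One "sample" is thus the mean of a cell
#' type's biological replicates, not an individual library.
#'
#' @param dataset An [expression_dataset].
#' @param threshold_tpm Minimum cell-type mean TPM (default 5).
#' @return Character vector of retained gene ids (original order).
#' @export
expression_filter <- function(dataset, threshold_tpm = 5) {
  stopifnot(is(dataset, "expression_dataset"))
  ct <- factor(dataset$samples$cell_type)
  if (any(table(ct) == 0)) stop("cell type with zero replicates")
  means <- sapply(levels(ct), function(l)
    rowMeans(dataset$tpm[, ct == l, drop = FALSE]))
  rownames(dataset$tpm)[apply(means, 1, max) >= threshold_tpm]
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes per-sample TMM scaling factors for a count matrix: a reference
#' sample is picked as the one whose upper-quartile count fraction is closest
#' to the mean upper quartile; for every sample, gene-wise log2 abundance
#' ratios (M) and average log2 abundances (A) versus the reference are
#' computed over genes nonzero in both libraries, doubly trimmed (30% of M,
#' 5% of A, each side), and the factor is 2 to the precision-weighted mean of
#' the retained M values. Factors are rescaled to geometric mean one, so they
#' multiply library sizes into effective library sizes.
#'
#' @param counts Matrix, genes x samples (>= 2 samples).
#' @param trim_logratio Two-sided trim fraction on M (default 0.3).
#' @param trim_intensity Two-sided trim fraction on A (default 0.05).
#' @param ref Optional reference column (index or name); default automatic.
#' @return Named numeric vector of scaling factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_logratio = 0.3, trim_intensity = 0.05, ref = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero library size")
  if (is.null(ref)) {
    f75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
    ref <- if (median(f75) < 1e-20) which.max(colSums(sqrt(counts)))
           else which.min(abs(f75 - mean(f75)))
  } else if (is.character(ref)) ref <- match(ref, colnames(counts))
  refc <- counts[, ref]
  nR <- lib[ref]
  f <- vapply(seq_len(ncol(counts)), function(i) {
    obs <- counts[, i]
    nO <- lib[i]
    keep <- obs > 0 & refc > 0
    if (!any(keep)) stop("sample ", i, " shares no expressed genes with the reference")
    o <- obs[keep]; r <- refc[keep]
    M <- log2((o / nO) / (r / nR))
    A <- (log2(o / nO) + log2(r / nR)) / 2
    # asymptotic variance of M (delta method, binomial counts)
    w <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_logratio) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_intensity) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    fv <- sum(M[sel] / w[sel], na.rm = TRUE) / sum(1 / w[sel], na.rm = TRUE)
    if (!is.finite(fv)) fv <- 0
    2^fv
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment. Thin validating wrapper around
#' [stats::p.adjust()] so the FDR procedure used throughout the package is a
#' single, swappable choke point.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NAs propagated).
#' @return q-values, same length and names.
#' @export
bh_fdr <- function(p_values) {
  pv <- p_values[!is.na(p_values)]
  if (length(pv) && (any(pv < 0) || any(pv > 1)))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

# Method-of-moments common NB dispersion from normalized counts.
# Pooled within-group variance per gene; phi_g = (s2 - mu)/mu^2; the common
# value is the median over genes with enough signal for the moments to exist.
.common_dispersion <- function(norm_counts, group) {
  group <- as.factor(group)
  mu <- rowMeans(norm_counts)
  ss <- 0; df <- 0
  for (l in levels(group)) {
    m <- norm_counts[, group == l, drop = FALSE]
    if (ncol(m) < 2) stop("group '", l, "' has <2 samples; dispersion inestimable")
    ss <- ss + rowSums((m - rowMeans(m))^2)
    df <- df + ncol(m) - 1
  }
  s2 <- ss / df
  ok <- mu >= 1
  if (!any(ok)) return(0)
  phi <- (s2[ok] - mu[ok]) / mu[ok]^2
  max(0, median(phi))
}

# Conditional NB exact test: given pooled count t split between groups of
# n1 and n2 libraries (at common library size), p = sum of conditional
# outcome probabilities not exceeding that of the observed split
# (double-tail). phi = 0 reduces to the binomial split of a Poisson pair.
.nb_exact_pvalue <- function(y1, t, n1, n2, phi) {
  if (t == 0) return(1)
  mu <- t / (n1 + n2)
  m1 <- n1 * mu; m2 <- n2 * mu
  if (t <= 50000) {
    ys <- 0:t
  } else {
    sd1 <- sqrt(m1 + phi * m1^2 / n1)
    lo <- max(0, floor(min(m1 - 40 * sd1, y1 - 5)))
    hi <- min(t, ceiling(max(m1 + 40 * sd1, y1 + 5)))
    ys <- lo:hi
  }
  lp <- if (phi > 0) {
    dnbinom(ys, size = n1 / phi, mu = m1, log = TRUE) +
      dnbinom(t - ys, size = n2 / phi, mu = m2, log = TRUE)
  } else {
    dpois(ys, m1, log = TRUE) + dpois(t - ys, m2, log = TRUE)
  }
  lmax <- max(lp)
  pr <- exp(lp - lmax)
  obs <- pr[match(y1, ys)]
  min(1, sum(pr[pr <= obs * (1 + 1e-8)]) / sum(pr))
}

#' Epidermis-versus-rest differential expression
#'
#' Two-group negative-binomial differential expression in the style used for
#' cell-type contrasts: TMM-normalized effective library sizes, a common
#' dispersion estimated by the method of moments from within-group
#' variability, and a conditional exact test on group count sums scaled to a
#' common library size. Fold changes are ratios of normalized group means
#' with a pseudocount. q-values are Benjamini-Hochberg across all tested
#' genes.
#'
#' @param dataset An [expression_dataset].
#' @param group1 Cell type (or character vector of sample ids) forming the
#'   numerator group; default `"epidermis"`.
#' @param genes Optional gene subset to test (default all rows); typically
#'   the output of [expression_filter()].
#' @param pseudocount Added to both normalized group means before the ratio
#'   (default 0.5).
#' @param threshold_tpm Passed to [expression_filter()] to fill the
#'   `pass_expression_filter` column (default 5).
#' @return A `data.frame` of class `de_table` with columns `gene`,
#'   `mean_group1`, `mean_group2`, `fold_change`, `log2_fold_change`,
#'   `p_value`, `fdr`, `direction`, `pass_expression_filter`,
#'   `pass_de_filter`, plus attributes `tmm_factors` and `dispersion`.
#' @export
differential_expression <- function(dataset, group1 = "epidermis", genes = NULL,
                                    pseudocount = 0.5, threshold_tpm = 5) {
  stopifnot(is(dataset, "expression_dataset"))
  smp <- dataset$samples
  if (length(group1) == 1 && group1 %in% smp$cell_type) {
    g1 <- smp$sample[smp$cell_type == group1]
  } else {
    g1 <- intersect(group1, smp$sample)
  }
  g2 <- setdiff(smp$sample, g1)
  if (length(g1) < 2 || length(g2) < 2)
    stop("each group needs >= 2 samples (got ", length(g1), " and ", length(g2), ")")
  keep_genes <- if (is.null(genes)) rownames(dataset$counts) else {
    missing <- setdiff(genes, rownames(dataset$counts))
    if (length(missing)) stop("unknown gene(s): ", paste(missing, collapse = ", "))
    genes
  }
  counts <- dataset$counts[keep_genes, c(g1, g2), drop = FALSE]
  fac <- tmm_factors(counts)
  efflib <- colSums(counts) * fac
  L0 <- exp(mean(log(efflib)))
  norm <- sweep(counts, 2, efflib, "/") * L0
  grp <- rep(c("g1", "g2"), c(length(g1), length(g2)))
  phi <- .common_dispersion(norm, grp)

  m1 <- rowMeans(norm[, grp == "g1", drop = FALSE])
  m2 <- rowMeans(norm[, grp == "g2", drop = FALSE])
  fc <- (m1 + pseudocount) / (m2 + pseudocount)
  n1 <- length(g1); n2 <- length(g2)
  y1 <- round(rowSums(norm[, grp == "g1", drop = FALSE]))
  y2 <- round(rowSums(norm[, grp == "g2", drop = FALSE]))
  p <- vapply(seq_along(y1), function(i)
    .nb_exact_pvalue(y1[i], y1[i] + y2[i], n1, n2, phi), numeric(1))
  q <- bh_fdr(p)

  passed <- expression_filter(dataset, threshold_tpm = threshold_tpm)
  pass_expr <- keep_genes %in% passed
  direction <- ifelse(fc >= 1, "up", "down")
  tab <- data.frame(
    gene = keep_genes,
    mean_group1 = m1, mean_group2 = m2,
    fold_change = fc, log2_fold_change = log2(fc),
    p_value = p, fdr = q,
    direction = direction,
    pass_expression_filter = pass_expr,
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab$pass_de_filter <- (tab$fold_change >= 5 | tab$fold_change <= 1 / 5) &
    tab$fdr < 0.05 & tab$pass_expression_filter
  attr(tab, "tmm_factors") <- fac
  attr(tab, "dispersion") <- phi
  attr(tab, "groups") <- list(group1 = g1, group2 = g2)
  class(tab) <- c("de_table", "data.frame")
  tab
}

#' Select differentially expressed genes
#'
#' Applies the selection rule "fold change >= `min_fold` (or <= 1/`min_fold`
#' for down-regulation), FDR < `max_fdr`, and expressed above the TPM
#' threshold". The fold boundary is inclusive, the FDR boundary strict.
#'
#' @param table A `de_table` from [differential_expression()].
#' @param min_fold Minimum linear fold change (default 5).
#' @param max_fdr Strict FDR bound (default 0.05).
#' @param direction `"up"`, `"down"`, or `"both"`.
#' @return Character vector of selected gene ids.
#' @export
select_de_genes <- function(table, min_fold = 5, max_fdr = 0.05,
                            direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(table),
            all(c("gene", "fold_change", "fdr", "pass_expression_filter") %in% names(table)))
  up <- table$fold_change >= min_fold
  down <- table$fold_change <= 1 / min_fold
  dirok <- switch(direction, up = up, down = down, both = up | down)
  table$gene[dirok & table$fdr < max_fdr & table$pass_expression_filter]
}
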