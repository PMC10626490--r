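#' All-pairs Pearson correlation with significance
#'
#' Computes the symmetric Pearson correlation matrix across samples for a set
#' of genes, two-sided p-values from the t statistic
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom, and
#' Benjamini-Hochberg q-values over the upper triangle. Expression can be
#' taken at replicate resolution (default) or collapsed to cell-type means,
#' and is log2(x + 1) transformed by default, the usual variance
#' stabilization for TPM coexpression.
#'
#' @param expr Matrix, genes x samples (e.g. a TPM submatrix over selected
#'   genes).
#' @param samples Optional sample sheet (`sample`, `cell_type`, `replicate`);
#'   required for `sample_mode = "celltype_means"`.
#' @param sample_mode `"replicates"` (default) or `"celltype_means"`.
#' @param transform `"log2"` (default, log2(x+1)) or `"linear"`.
#' @return Object of class `coexpression_result`: list with `genes`, `pcc`,
#'   `p`, `q`, `mr` (filled by [mutual_rank()]), `n_samples`, and
#'   `masked` (ids of zero-variance genes, whose rows/columns are NA).
#' @export
pearson_matrix <- function(expr, samples = NULL,
                           sample_mode = c("replicates", "celltype_means"),
                           transform = c("log2", "linear")) {
  sample_mode <- match.arg(sample_mode)
  transform <- match.arg(transform)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stop("'expr' must have gene row names")
  if (sample_mode == "celltype_means") {
    if (is.null(samples)) stop("sample sheet required for cell-type means")
    ct <- factor(samples$cell_type[match(colnames(expr), samples$sample)])
    expr <- sapply(levels(ct), function(l) rowMeans(expr[, ct == l, drop = FALSE]))
  }
  n <- ncol(expr)
  if (n < 3) stop("need at least 3 samples/columns for correlation")
  x <- if (transform == "log2") log2(expr + 1) else expr
  sds <- apply(x, 1, sd)
  masked <- rownames(x)[sds == 0]
  if (length(masked))
    warning("constant gene(s) masked: ", paste(masked, collapse = ", "))
  r <- suppressWarnings(cor(t(x)))
  r[masked, ] <- NA; r[, masked] <- NA
  diag(r) <- ifelse(rownames(r) %in% masked, NA, 1)
  r <- pmin(pmax(r, -1), 1)

  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  diag(p) <- NA
  ut <- upper.tri(p)
  q <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(p))
  q[ut] <- bh_fdr(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  res <- structure(
    list(genes = rownames(r), pcc = r, p = p, q = q, mr = NULL,
         n_samples = n, masked = masked,
         sample_mode = sample_mode, transform = transform),
    class = "coexpression_result"
  )
  res$mr <- mutual_rank(r)
  res
}

#' @export
print.coexpression_result <- function(x, ...) {
  cat("coexpression_result:", length(x$genes), "genes,", x$n_samples,
      "samples (", x$sample_mode, ",", x$transform, ")\n")
  if (length(x$masked)) cat("masked constant genes:", length(x$masked), "\n")
  invisible(x)
}

#' Mutual Rank of a correlation matrix
#'
#' For every gene i, all partners j != i are ranked by decreasing
#' correlation (rank 1 = strongest partner, ties receive the average rank);
#' the Mutual Rank of a pair is the geometric mean of the two reciprocal
#' ranks, `sqrt(rank_i(j) * rank_j(i))`. Reciprocal best partners have
#' MR = 1. Masked (NA) genes are excluded from every ranking denominator.
#'
#' @param pcc Square symmetric correlation matrix (NA rows allowed).
#' @return Symmetric matrix of Mutual Ranks (>= 1), diagonal NA.
#' @export
mutual_rank <- function(pcc) {
  pcc <- as.matrix(pcc)
  if (nrow(pcc) != ncol(pcc)) stop("'pcc' must be square")
  n <- nrow(pcc)
  rk <- matrix(NA_real_, n, n, dimnames = dimnames(pcc))
  for (i in seq_len(n)) {
    v <- pcc[i, ]
    v[i] <- NA
    ok <- !is.na(v)
    if (!any(ok)) next
    rk[i, ok] <- rank(-v[ok], ties.method = "average")
  }
  mr <- sqrt(rk * t(rk))
  diag(mr) <- NA
  mr
}

#' Long-format coexpression table
#'
#' Flattens a [pearson_matrix()] result to one row per unordered gene pair
#' (upper triangle), with PCC, p, q and Mutual Rank.
#'
#' @param result A `coexpression_result`.
#' @return Data frame with columns `gene_a`, `gene_b`, `pcc`, `p`, `q`, `mr`.
#' @export
coexpression_table <- function(result) {
  stopifnot(is(result, "coexpression_result"))
  ut <- which(upper.tri(result$pcc), arr.ind = TRUE)
  data.frame(
    gene_a = result$genes[ut[, 1]],
    gene_b = result$genes[ut[, 2]],
    pcc = result$pcc[ut], p = result$p[ut],
    q = result$q[ut], mr = result$mr[ut],
    stringsAsFactors = FALSE
  )
}
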