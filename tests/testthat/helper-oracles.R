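# Independent brute-force oracles used to verify the package implementations.
# These deliberately share no code path with the package: explicit sorting,
# looped summation, and direct application of textbook definitions.

# Mutual Rank by explicit per-gene sorting; ties averaged over sorted runs.
oracle_mutual_rank <- function(pcc) {
  n <- nrow(pcc)
  pos <- matrix(NA_real_, n, n, dimnames = dimnames(pcc))
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    vals <- pcc[i, others]
    ord <- others[order(vals, decreasing = TRUE)]
    p <- seq_along(ord)
    # average positions over runs of equal correlation
    sorted_vals <- pcc[i, ord]
    for (v in unique(sorted_vals)) {
      run <- which(sorted_vals == v)
      p[run] <- mean(p[run])
    }
    pos[i, ord] <- p
  }
  mr <- matrix(NA_real_, n, n, dimnames = dimnames(pcc))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) mr[i, j] <- sqrt(pos[i, j] * pos[j, i])
  }
  mr
}

# random symmetric correlation-like matrix; rounding forces ties
random_pcc <- function(n, round_to = NULL) {
  m <- matrix(runif(n * n, -1, 1), n, n)
  m <- (m + t(m)) / 2
  if (!is.null(round_to)) m <- round(m, round_to)
  diag(m) <- 1
  dimnames(m) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  m
}

# TMM by literal textbook steps: sorted trimming instead of rank filtering.
oracle_tmm <- function(counts, trimM = 0.3, trimA = 0.05) {
  lib <- colSums(counts)
  f75 <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts)))
    f75[s] <- quantile(counts[, s], 0.75) / lib[s]
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- numeric(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    o <- counts[, s]; r <- counts[, ref]
    use <- o > 0 & r > 0
    o <- o[use]; r <- r[use]
    M <- log2((o / lib[s]) / (r / lib[ref]))
    A <- 0.5 * log2((o / lib[s]) * (r / lib[ref]))
    w <- (lib[s] - o) / (lib[s] * o) + (lib[ref] - r) / (lib[ref] * r)
    if (max(abs(M)) < 1e-6) { fac[s] <- 1; next }
    n <- length(M)
    keepM <- rep(FALSE, n); keepA <- rep(FALSE, n)
    keepM[order(M)[(floor(n * trimM) + 1):(n - floor(n * trimM))]] <- TRUE
    keepA[order(A)[(floor(n * trimA) + 1):(n - floor(n * trimA))]] <- TRUE
    keep <- keepM & keepA
    fac[s] <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  fac <- fac / exp(mean(log(fac)))
  setNames(fac, colnames(counts))
}

# Benjamini-Hochberg by the literal min-over-suffix definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# one-sided (over-representation) hypergeometric tail by direct summation of
# binomial coefficients; table rows are (fg_with, fg_without, bg_with,
# bg_without)
oracle_hypergeom_greater <- function(a, b, c_, d) {
  n <- a + b + c_ + d
  n_with <- a + c_
  n_fg <- a + b
  ks <- a:min(n_fg, n_with)
  sum(exp(lchoose(n_with, ks) + lchoose(n - n_with, n_fg - ks) -
            lchoose(n, n_fg)))
}

# naive two-pass Pearson correlation matrix
oracle_pearson <- function(x) {
  n <- nrow(x)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    xi <- x[i, ]; xj <- x[j, ]
    cov <- sum((xi - mean(xi)) * (xj - mean(xj))) / (length(xi) - 1)
    out[i, j] <- cov / (sd(xi) * sd(xj))
  }
  out
}

# brute-force PWM scanner: explicit per-character window scoring; minus
# strand scored by reverse-complementing the window text itself
oracle_scan <- function(w, seqs, min_score_fraction, both_strands = TRUE) {
  L <- ncol(w)
  smax <- sum(apply(w, 2, max)); smin <- sum(apply(w, 2, min))
  thr <- smin + min_score_fraction * (smax - smin)
  score_word <- function(word) {
    ch <- strsplit(word, "")[[1]]
    if (any(!ch %in% c("A", "C", "G", "T"))) return(NA_real_)
    s <- 0
    for (k in seq_len(L)) s <- s + w[ch[k], k]
    s
  }
  rc <- function(word) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", word), "")[[1]]), collapse = "")
  }
  rows <- list()
  for (g in names(seqs)) {
    sq <- seqs[[g]]
    if (nchar(sq) < L) next
    for (st in 0:(nchar(sq) - L)) {
      word <- substr(sq, st + 1, st + L)
      sc_f <- score_word(word)
      sc_r <- if (both_strands) score_word(rc(word)) else NA_real_
      cand <- c(`+` = unname(sc_f), `-` = unname(sc_r))
      cand <- cand[!is.na(cand) & cand >= thr]
      if (!length(cand)) next
      best <- which.max(cand)
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, start = st, strand = names(cand)[best],
        score = unname(cand[best]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(gene = character(), start = integer(),
                                       strand = character(), score = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$gene, out$start), ]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
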