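DNA_BASES4 <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param pfm 4 x L nonnegative matrix of per-position base observation
#'   counts, rows A, C, G, T.
#' @param id Motif identifier.
#' @param name Optional display name (defaults to `id`).
#' @param background Background base composition (A, C, G, T), summing to 1.
#' @param pseudocount Pseudocount used by [pwm_log_odds()] (default 0.25).
#' @return Object of class `pwm`.
#' @export
pwm <- function(pfm, id, name = id, background = rep(0.25, 4), pseudocount = 0.25) {
  pfm <- as.matrix(pfm)
  if (nrow(pfm) != 4) stop("PFM must have 4 rows (A, C, G, T)")
  if (ncol(pfm) < 1) stop("PFM must have at least one column")
  if (any(pfm < 0)) stop("PFM frequencies must be nonnegative")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  rownames(pfm) <- DNA_BASES4
  structure(list(id = id, name = name, pfm = pfm,
                 background = setNames(background, DNA_BASES4),
                 pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$id, "(", x$name, "), length", ncol(x$pfm),
      ", consensus", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence of a PWM (highest-count base per column)
#' @param x A `pwm`.
#' @return Character string of length L.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES4[apply(x$pfm, 2, which.max)], collapse = "")
}

#' Read a JASPAR-format PFM file
#'
#' Parses the standard JASPAR text layout: a `>` header line with motif id
#' and optional name, followed by four rows `A [ ... ]` ... `T [ ... ]`.
#'
#' @param path File path.
#' @param background,pseudocount Passed to every [pwm()] constructed.
#' @return Named list of `pwm` objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.25) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records in ", path)
  out <- lapply(starts, function(s) {
    hdr <- strsplit(sub("^>\\s*", "", lines[s]), "\\s+")[[1]]
    rows <- lines[(s + 1):(s + 4)]
    bases <- sub("^\\s*([ACGT]).*$", "\\1", rows)
    vals <- lapply(rows, function(r) {
      body <- sub("^\\s*[ACGT]", "", r)
      as.numeric(regmatches(body, gregexpr("[0-9]+\\.?[0-9]*(?:[eE][+-]?[0-9]+)?", body))[[1]])
    })
    if (length(unique(lengths(vals))) != 1)
      stop("ragged PFM rows in record ", hdr[1])
    mat <- do.call(rbind, vals)
    rownames(mat) <- bases
    mat <- mat[DNA_BASES4, , drop = FALSE]
    pwm(mat, id = hdr[1], name = if (length(hdr) > 1) hdr[2] else hdr[1],
        background = background, pseudocount = pseudocount)
  })
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Write PWMs to a JASPAR-format file
#'
#' @param pwms List of `pwm` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$id, " ", p$name), con)
    for (b in DNA_BASES4) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(format(p$pfm[b, ], trim = TRUE), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Log-odds scoring matrix of a PWM
#'
#' Per position k and base b:
#' `score[b, k] = log2( ((freq[b, k] + pc * bg[b]) / (colsum[k] + pc)) / bg[b] )`
#' in bits, where `pc` is the pseudocount and `bg` the background
#' composition.
#'
#' @param x A `pwm`, or a raw 4 x L PFM matrix.
#' @param background,pseudocount Overrides for the values stored in `x`.
#' @return 4 x L numeric matrix of log-odds scores (bits), rows A, C, G, T.
#' @export
pwm_log_odds <- function(x, background = NULL, pseudocount = NULL) {
  if (is(x, "pwm")) {
    pfm <- x$pfm
    if (is.null(background)) background <- x$background
    if (is.null(pseudocount)) pseudocount <- x$pseudocount
  } else {
    pfm <- as.matrix(x)
    if (is.null(background)) background <- rep(0.25, 4)
    if (is.null(pseudocount)) pseudocount <- 0.25
  }
  if (any(background <= 0)) stop("background probabilities must be positive")
  tot <- colSums(pfm)
  prob <- sweep(pfm + pseudocount * background, 2, tot + pseudocount, "/")
  lo <- log2(prob / background)
  rownames(lo) <- DNA_BASES4
  lo
}

# Encode A/C/G/T to 1..4, anything else (N etc.) to NA.
.encode_dna <- function(seqs) {
  lapply(seqs, function(s) {
    v <- match(strsplit(toupper(s), "")[[1]], DNA_BASES4)
    v
  })
}

# Reverse complement of a log-odds matrix: complement rows, reverse columns.
.revcomp_matrix <- function(w) {
  out <- w[4:1, rev(seq_len(ncol(w))), drop = FALSE]
  rownames(out) <- DNA_BASES4
  out
}

#' Scan promoter sequences with a PWM
#'
#' Slides the log-odds matrix over both strands of every sequence and
#' reports windows whose score reaches
#' `min_score + min_score_fraction * (max_score - min_score)`, where max/min
#' are the best and worst attainable window scores. Windows containing
#' non-ACGT characters are skipped. When both strands hit at the same start,
#' only the higher-scoring strand is kept. Positions are 0-based offsets of
#' the window start within the promoter.
#'
#' @param x A `pwm` or a 4 x L log-odds matrix.
#' @param seqs Named character vector of sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param min_score_fraction Relative score threshold in \[0, 1\]
#'   (default 0.85).
#' @param both_strands Scan the reverse strand too (default TRUE).
#' @return Data frame with columns `motif`, `gene`, `start`, `strand`,
#'   `score`. A motif longer than a sequence yields no rows for it.
#' @export
scan_promoters <- function(x, seqs, min_score_fraction = 0.85, both_strands = TRUE) {
  if (is(x, "pwm")) {
    w <- pwm_log_odds(x); id <- x$id
  } else {
    w <- as.matrix(x); id <- "motif"
    if (nrow(w) != 4) stop("scoring matrix must have 4 rows")
    rownames(w) <- DNA_BASES4
  }
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) stop("sequences must be named by gene")
  L <- ncol(w)
  smax <- sum(apply(w, 2, max)); smin <- sum(apply(w, 2, min))
  thr <- smin + min_score_fraction * (smax - smin)
  mats <- list(`+` = w)
  if (both_strands) mats$`-` <- .revcomp_matrix(w)
  codes <- .encode_dna(seqs)
  hits <- list()
  lens <- nchar(seqs)
  for (strand in names(mats)) {
    ws <- mats[[strand]]
    if (length(unique(lens)) == 1 && lens[1] >= L) {
      # equal-length fast path: one integer matrix, L shifted lookups
      cm <- do.call(rbind, codes)
      P <- lens[1] - L + 1
      S <- matrix(0, nrow(cm), P)
      for (k in seq_len(L)) {
        S <- S + matrix(ws[, k][cm[, k:(k + P - 1), drop = FALSE]], nrow(cm), P)
      }
      idx <- which(!is.na(S) & S >= thr, arr.ind = TRUE)
      if (nrow(idx)) {
        hits[[strand]] <- data.frame(
          motif = id, gene = names(seqs)[idx[, 1]], start = idx[, 2] - 1L,
          strand = strand, score = S[idx], stringsAsFactors = FALSE)
      }
    } else {
      per <- lapply(seq_along(codes), function(i) {
        v <- codes[[i]]
        if (length(v) < L) return(NULL)
        P <- length(v) - L + 1
        s <- rep(0, P)
        for (k in seq_len(L)) s <- s + ws[, k][v[k:(k + P - 1)]]
        at <- which(!is.na(s) & s >= thr)
        if (!length(at)) return(NULL)
        data.frame(motif = id, gene = names(seqs)[i], start = at - 1L,
                   strand = strand, score = s[at], stringsAsFactors = FALSE)
      })
      per <- per[!vapply(per, is.null, TRUE)]
      if (length(per)) hits[[strand]] <- do.call(rbind, per)
    }
  }
  if (!length(hits)) {
    return(data.frame(motif = character(), gene = character(),
                      start = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  # deduplicate same (gene, start) across strands: keep the higher score
  o <- order(out$gene, out$start, -out$score)
  out <- out[o, , drop = FALSE]
  out <- out[!duplicated(out[, c("gene", "start")]), , drop = FALSE]
  out <- out[order(out$gene, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan promoters with a library of PWMs
#'
#' @param pwms List of `pwm` objects.
#' @inheritParams scan_promoters
#' @return Row-bound hit table over all motifs (see [scan_promoters()]).
#' @export
scan_promoters_all <- function(pwms, seqs, min_score_fraction = 0.85,
                               both_strands = TRUE) {
  do.call(rbind, lapply(pwms, scan_promoters, seqs = seqs,
                        min_score_fraction = min_score_fraction,
                        both_strands = both_strands))
}

#' Extract promoter sequences upstream of transcription start sites
#'
#' For a plus-strand gene the promoter is the `length` bases ending
#' immediately before the TSS; for a minus-strand gene, the `length` bases
#' starting immediately after the TSS, reverse-complemented (so promoters
#' always read 5' to 3' towards the gene). Coordinates follow the BED
#' convention (0-based TSS positions). Promoters running off a contig edge
#' are truncated and flagged.
#'
#' @param genome FASTA path or `Biostrings::DNAStringSet`.
#' @param tss BED6 path or `GenomicRanges::GRanges` of single-base TSS
#'   features named by gene, with strand.
#' @param length Promoter length in bases (default 1000, i.e. 1 kb).
#' @return Named character vector of promoter sequences with attribute
#'   `truncated` (named logical).
#' @export
extract_promoters <- function(genome, tss, length = 1000) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(tss)) tss <- rtracklayer::import(tss, format = "BED")
  gene <- if (!is.null(tss$name)) tss$name else names(tss)
  if (is.null(gene)) stop("TSS annotation must carry gene names")
  chrom <- as.character(GenomicRanges::seqnames(tss))
  strand <- as.character(GenomicRanges::strand(tss))
  t0 <- GenomicRanges::start(tss) - 1L  # 0-based TSS position
  missing <- setdiff(chrom, names(genome))
  if (length(missing)) stop("contig(s) absent from FASTA: ",
                            paste(unique(missing), collapse = ", "))
  proms <- character(0); trunc <- logical(0)
  for (i in seq_along(tss)) {
    clen <- Biostrings::width(genome[chrom[i]])
    if (t0[i] < 0 || t0[i] >= clen) {
      warning("TSS of ", gene[i], " outside contig; skipped")
      next
    }
    if (strand[i] == "-") {
      from <- t0[i] + 2L; to <- min(t0[i] + 1L + length, clen)
      tr <- (to - from + 1L) < length
      s <- if (to < from) "" else as.character(
        Biostrings::reverseComplement(Biostrings::subseq(genome[[chrom[i]]], from, to)))
    } else {
      from <- max(1L, t0[i] - length + 1L); to <- t0[i]
      tr <- (to - from + 1L) < length
      s <- if (to < from) "" else
        as.character(Biostrings::subseq(genome[[chrom[i]]], from, to))
    }
    proms[gene[i]] <- s
    trunc[gene[i]] <- tr
  }
  if (any(trunc))
    warning(sum(trunc), " promoter(s) truncated at contig edges")
  attr(proms, "truncated") <- trunc
  proms
}

#' Cis-regulatory-element enrichment by Fisher's exact test
#'
#' Per motif, promoters are dichotomized into with/without at least one hit,
#' and over-representation in the foreground gene set versus the rest of the
#' background is tested one-sided with Fisher's exact test; q-values are
#' Benjamini-Hochberg across motifs.
#'
#' @param hits Hit table from [scan_promoters_all()].
#' @param foreground Character vector of foreground gene ids (e.g. the
#'   DE-selected genes); must be a subset of `background`.
#' @param background Character vector of all scanned gene ids.
#' @param q_threshold Enrichment flag threshold (default 0.05).
#' @return Data frame with columns `motif`, `fg_with`, `fg_total`,
#'   `bg_with`, `bg_total`, `odds_ratio`, `p`, `q`, `enriched`.
#' @export
cre_enrichment <- function(hits, foreground, background, q_threshold = 0.05) {
  if (!length(foreground)) stop("empty foreground gene set")
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  rest <- setdiff(background, foreground)
  motifs <- sort(unique(hits$motif))
  rows <- lapply(motifs, function(m) {
    with_hit <- unique(hits$gene[hits$motif == m])
    a <- sum(foreground %in% with_hit)          # fg with
    b <- length(foreground) - a                 # fg without
    c_ <- sum(rest %in% with_hit)               # bg-only with
    d <- length(rest) - c_                      # bg-only without
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                      alternative = "greater")
    data.frame(motif = m, fg_with = a, fg_total = length(foreground),
               bg_with = c_, bg_total = length(rest),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$enriched <- out$q < q_threshold
  rownames(out) <- NULL
  out
}

#' Build the TF-to-target promoter binding map
#'
#' Combines motif hits, CRE enrichment, and the TF-to-motif mapping into
#' rows (TF, target, motif): a row exists when the motif is enriched, the
#' target is in the supplied gene set, and the target's promoter carries at
#' least one hit of the motif. Self pairs (TF = target) are excluded.
#'
#' @param hits Hit table from [scan_promoters_all()].
#' @param enrichment Table from [cre_enrichment()].
#' @param tf_motif_map Data frame with columns `tf` and `motif`.
#' @param genes Gene universe for targets (e.g. DE-selected genes).
#' @param include_self Keep TF-self rows (default FALSE).
#' @return Data frame of class `binding_map` with columns `tf`, `target`,
#'   `motif`, `best_score`, `enrichment_q`, `enriched`.
#' @export
build_binding_map <- function(hits, enrichment, tf_motif_map, genes,
                              include_self = FALSE) {
  stopifnot(all(c("tf", "motif") %in% names(tf_motif_map)))
  unmapped <- setdiff(unique(hits$motif), tf_motif_map$motif)
  if (length(unmapped))
    warning("motif(s) without TF mapping dropped: ",
            paste(unmapped, collapse = ", "))
  enr <- enrichment[enrichment$enriched, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(tf_motif_map))) {
    tf <- tf_motif_map$tf[i]; m <- tf_motif_map$motif[i]
    e <- enr[enr$motif == m, , drop = FALSE]
    if (!nrow(e)) next
    h <- hits[hits$motif == m & hits$gene %in% genes, , drop = FALSE]
    if (!include_self) h <- h[h$gene != tf, , drop = FALSE]
    if (!nrow(h)) next
    best <- tapply(h$score, h$gene, max)
    rows[[length(rows) + 1L]] <- data.frame(
      tf = tf, target = names(best), motif = m,
      best_score = as.numeric(best), enrichment_q = e$q[1], enriched = TRUE,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tf = character(), target = character(), motif = character(),
               best_score = numeric(), enrichment_q = numeric(),
               enriched = logical(), stringsAsFactors = FALSE)
  out <- out[order(out$tf, out$target), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("binding_map", "data.frame")
  out
}
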