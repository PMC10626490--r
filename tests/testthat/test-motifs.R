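test_that("promoter extraction follows the BED strand conventions", {
  contig <- paste(c(strrep("A", 400), strrep("C", 600), strrep("G", 100)),
                  collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = contig, chr2 = contig))
  tss <- GenomicRanges::GRanges(
    c("chr1", "chr2"),
    IRanges::IRanges(start = c(1001, 50), width = 1),  # 0-based TSS 1000, 49
    strand = c("+", "-"), name = c("gplus", "gminus"), score = 0L)
  pr <- suppressWarnings(extract_promoters(genome, tss, length = 1000))
  # + strand: bases [0, 1000) of the contig
  expect_identical(pr[["gplus"]], substr(contig, 1, 1000))
  # - strand: reverse complement of bases [50, 1050)
  expect_identical(
    pr[["gminus"]],
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(contig, 51, 1050)))))
  # a TSS too close to the contig start truncates with a flag
  tss_short <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, width = 1),
                                      strand = "+", name = "gshort", score = 0L)
  expect_warning(pshort <- extract_promoters(genome, tss_short, 1000), "truncated")
  expect_identical(nchar(pshort[["gshort"]]), 100L)
  expect_true(attr(pshort, "truncated")[["gshort"]])
  expect_error(
    extract_promoters(genome, GenomicRanges::GRanges(
      "chrX", IRanges::IRanges(500, width = 1), strand = "+",
      name = "gx", score = 0L)),
    "absent")
})

test_that("log-odds scores behave at the uniform and degenerate limits", {
  uni <- pwm(matrix(25, 4, 6), id = "uni")
  expect_equal(pwm_log_odds(uni), matrix(0, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL)),
               tolerance = 1e-12)
  onA <- pwm(matrix(c(100, 0, 0, 0), 4, 1), id = "onA", pseudocount = 1e-9)
  expect_equal(unname(pwm_log_odds(onA)["A", 1]), 2, tolerance = 1e-6)  # log2(1/0.25)
  expect_error(pwm_log_odds(onA, background = c(0, 0.5, 0.25, 0.25)),
               "positive")
})

test_that("the maximum attainable k-mer score is the sum of column maxima", {
  set.seed(60)
  for (L in c(4, 6, 8)) {
    pfm <- matrix(rpois(4 * L, 20), 4, L)
    w <- pwm_log_odds(pwm(pfm, id = "r"))
    kmers <- do.call(expand.grid, rep(list(1:4), L))
    best <- max(apply(kmers, 1, function(k) sum(w[cbind(k, seq_len(L))])))
    expect_equal(best, sum(apply(w, 2, max)), tolerance = 1e-10)
  }
})

test_that("planted consensus sequences are recovered on the expected strand", {
  set.seed(61)
  p <- pwm(local({
    m <- matrix(3, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (k in 1:8) m[sample(4, 1), k] <- 91
    m
  }), id = "m1")
  cons <- pwm_consensus(p)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  seq_f <- paste0(strrep("A", 100), cons, strrep("A", 100))
  seq_r <- paste0(strrep("A", 40), rc, strrep("A", 40))
  hf <- scan_promoters(p, c(gf = seq_f))
  expect_true(any(hf$start == 100 & hf$strand == "+"))
  expect_equal(max(hf$score), sum(apply(pwm_log_odds(p), 2, max)))
  hr <- scan_promoters(p, c(gr = seq_r))
  expect_true(any(hr$start == 40 & hr$strand == "-"))
  # windows containing N are skipped, not scored
  hN <- scan_promoters(p, c(gn = paste0(strrep("N", 4), cons)))
  expect_true(all(hN$start >= 4))
  # motif longer than the sequence is empty, not an error
  expect_identical(nrow(scan_promoters(p, c(tiny = "ACGT"))), 0L)
})

test_that("scanning equals a brute-force window scanner on random sequences", {
  set.seed(62)
  pfm <- matrix(rpois(4 * 6, 10), 4, 6)
  p <- pwm(pfm, id = "m")
  seqs <- setNames(vapply(1:5, function(i) random_dna(300), ""),
                   paste0("g", 1:5))
  hits <- scan_promoters(p, seqs, min_score_fraction = 0.75)
  oracle <- oracle_scan(pwm_log_odds(p), seqs, 0.75)
  expect_equal(nrow(hits), nrow(oracle))
  expect_equal(hits$start, oracle$start)
  expect_equal(hits$strand, oracle$strand)
  expect_equal(hits$score, oracle$score, tolerance = 1e-10)
  # mixed-length input goes through the generic path with the same result
  seqs2 <- c(seqs, short = random_dna(40))
  hits2 <- scan_promoters(p, seqs2, min_score_fraction = 0.75)
  expect_equal(hits2[hits2$gene != "short", c("start", "strand")],
               hits[, c("start", "strand")], ignore_attr = TRUE)
})

test_that("reverse-complementing a sequence mirrors its hit set", {
  set.seed(63)
  pfm <- matrix(rpois(4 * 7, 15), 4, 7)
  p <- pwm(pfm, id = "m")
  s <- random_dna(400)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h1 <- scan_promoters(p, c(g = s), min_score_fraction = 0.7)
  h2 <- scan_promoters(p, c(g = rc), min_score_fraction = 0.7)
  expect_equal(nrow(h1), nrow(h2))
  mirrored <- data.frame(start = 400 - 7 - h2$start,
                         strand = ifelse(h2$strand == "+", "-", "+"),
                         score = h2$score)
  mirrored <- mirrored[order(mirrored$start), ]
  expect_equal(h1$start, mirrored$start)
  expect_equal(h1$strand, mirrored$strand)
  expect_equal(h1$score, mirrored$score, tolerance = 1e-10)
})

test_that("JASPAR files round-trip through the reader and writer", {
  sm <- small_fixture()
  path <- tempfile(fileext = ".jaspar")
  write_jaspar(sm$sim$pwms, path)
  back <- read_jaspar(path)
  expect_identical(names(back), names(sm$sim$pwms))
  for (id in names(back)) {
    expect_equal(back[[id]]$pfm, sm$sim$pwms[[id]]$pfm, ignore_attr = TRUE)
  }
})

test_that("CRE enrichment p-values are hypergeometric tails", {
  # 10 foreground promoters (8 with motif), 90 further background (10 with)
  hits <- data.frame(motif = "m1",
                     gene = c(paste0("f", 1:8), paste0("b", 1:10)),
                     start = 0L, strand = "+", score = 1)
  fg <- paste0("f", 1:10)
  bg <- c(fg, paste0("b", 1:90))
  enr <- cre_enrichment(hits, fg, bg)
  expect_equal(enr$p, oracle_hypergeom_greater(8, 2, 10, 80), tolerance = 1e-10)
  # motif in every promoter: no enrichment
  all_hits <- data.frame(motif = "m1", gene = bg, start = 0L, strand = "+", score = 1)
  expect_equal(cre_enrichment(all_hits, fg, bg)$p, 1)
  # foreground = background: no contrast
  expect_equal(cre_enrichment(hits, bg, bg)$p, 1)
  expect_error(cre_enrichment(hits, character(0), bg), "empty foreground")
  expect_error(cre_enrichment(hits, c(fg, "zzz"), bg), "subset")
})

test_that("the binding map contains planted pairs and respects its gates", {
  sm <- small_fixture()
  sim <- sm$sim
  hits <- scan_promoters_all(sim$pwms, sim$promoters)
  de_genes <- sim$truth$epidermis_module
  enr <- cre_enrichment(hits, de_genes, names(sim$promoters))
  bm <- build_binding_map(hits, enr, sim$tf_motif_map, de_genes)
  planted <- paste(sim$truth$true_edges$tf, sim$truth$true_edges$target)
  expect_true(all(planted %in% paste(bm$tf, bm$target)))
  # a non-enriched motif contributes no rows
  enr0 <- enr; enr0$enriched <- FALSE
  expect_identical(nrow(build_binding_map(hits, enr0, sim$tf_motif_map, de_genes)), 0L)
  # self pairs are excluded
  expect_true(all(bm$tf != bm$target))
  # a motif with no TF mapping is dropped with a warning
  expect_warning(
    build_binding_map(rbind(hits, data.frame(motif = "M_orphan", gene = de_genes[1],
                                             start = 0L, strand = "+", score = 1)),
                      enr, sim$tf_motif_map, de_genes),
    "M_orphan")
})
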