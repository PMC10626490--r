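test_that("transcript-to-gene aggregation sums rows and preserves order-independence", {
  tx_counts <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                      dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  tx_tpm <- matrix(c(3, 4, 993, 5, 6, 989) * 1e3, 3, 2,
                   dimnames = list(c("t1", "t2", "t3"), c("s1", "s2")))
  map <- data.frame(transcript = c("t1", "t2", "t3"),
                    gene = c("gA", "gA", "gB"))
  agg <- aggregate_transcripts_to_genes(tx_counts, tx_tpm, map)
  expect_equal(agg$tpm["gA", "s1"], 7e3)          # 3 + 4
  expect_equal(agg$counts["gA", ], c(s1 = 3, s2 = 9))
  expect_equal(agg$counts["gB", ], tx_counts["t3", ])  # single transcript
  perm <- c("t3", "t1", "t2")
  agg2 <- aggregate_transcripts_to_genes(tx_counts[perm, ], tx_tpm[perm, ], map)
  expect_equal(agg2$counts[rownames(agg$counts), ], agg$counts)
  expect_error(
    aggregate_transcripts_to_genes(tx_counts, tx_tpm,
                                   map[map$transcript != "t2", ]),
    "t2")
})

test_that("TPM conversion follows the length-normalized rate formula", {
  counts <- matrix(c(100, 100), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tpm <- tpm_from_counts(counts, c(a = 1000, b = 2000))
  expect_equal(tpm[, 1], c(a = 666666.67, b = 333333.33), tolerance = 0.01 / 666666)
  eq <- tpm_from_counts(matrix(c(7, 7), 2, 1, dimnames = list(c("a", "b"), "s")),
                        c(a = 800, b = 800))
  expect_equal(unname(eq[, 1]), c(5e5, 5e5))
  # scale invariance
  t1 <- tpm_from_counts(counts, c(a = 1000, b = 2000))
  t2 <- tpm_from_counts(counts * 10, c(a = 1000, b = 2000))
  expect_equal(t1, t2)
  expect_warning(z <- tpm_from_counts(matrix(0, 2, 1, dimnames = list(c("a", "b"), "s")),
                                      c(a = 100, b = 100)), "all-zero")
  expect_true(all(z == 0) && !anyNA(z))
})

test_that("the expression filter thresholds cell-type mean TPM at >= 5", {
  ct <- c("epidermis", "pith", "phloem", "bundle_sheath", "xylem", "vasc")
  tpm <- rbind(
    below = rep(4.9, 18),                                    # all means 4.9
    boundary = rep(c(0, 0, 0, 0, 0, 5), each = 3),           # one mean at 5.0
    burst = c(15, 0, 0, rep(0, 15))                          # mean 5 from one rep
  )
  ds <- make_dataset(tpm, ct)
  kept <- expression_filter(ds, threshold_tpm = 5)
  expect_false("below" %in% kept)
  expect_true("boundary" %in% kept)
  expect_true("burst" %in% kept)
  # idempotent over gene subsetting / order-independent
  expect_setequal(kept, expression_filter(ds, 5))
})

test_that("TMM factors are exact in the identity and pure-scaling cases", {
  set.seed(20)
  a <- rnbinom(400, mu = 100, size = 2) + 1
  same <- cbind(s1 = a, s2 = a)
  expect_equal(unname(tmm_factors(same)), c(1, 1))
  scaled <- cbind(s1 = a, s2 = 3 * a)
  expect_equal(unname(tmm_factors(scaled)), c(1, 1))
})

test_that("TMM matches a literal-steps oracle and edgeR on random matrices", {
  skip_if_not_installed("edgeR")
  set.seed(21)
  for (i in 1:3) {
    m <- matrix(rnbinom(500 * 2, mu = exp(rnorm(1000, 5, 1.5)), size = 3),
                500, 2, dimnames = list(paste0("g", 1:500), c("s1", "s2")))
    expect_equal(tmm_factors(m), oracle_tmm(m), tolerance = 1e-8)
    expect_equal(unname(tmm_factors(m)),
                 unname(edgeR::calcNormFactors(m, method = "TMM")),
                 tolerance = 1e-10)
  }
  # multi-sample case against edgeR
  m <- matrix(rnbinom(300 * 6, mu = 80, size = 1), 300, 6,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:6)))
  expect_equal(unname(tmm_factors(m)),
               unname(edgeR::calcNormFactors(m, method = "TMM")),
               tolerance = 1e-10)
  expect_equal(exp(mean(log(tmm_factors(m)))), 1)
})

test_that("sequencing depth is absorbed by the library size, not the factor", {
  set.seed(22)
  m <- matrix(rnbinom(400 * 3, mu = 120, size = 2), 400, 3,
              dimnames = list(paste0("g", 1:400), paste0("s", 1:3)))
  m2 <- m; m2[, 2] <- m2[, 2] * 7
  # M-values are depth-invariant; only the precision weights shift slightly
  expect_equal(tmm_factors(m), tmm_factors(m2), tolerance = 0.02)
})

test_that("a gene with identical group means is a clean null case", {
  ct <- c("epidermis", "pith", "phloem", "bundle_sheath", "xylem", "vasc")
  set.seed(30)
  n <- 200
  counts <- matrix(rnbinom(n * 18, mu = 100, size = 1 / 0.05), n, 18,
                   dimnames = list(sprintf("g%03d", 1:n), NULL))
  counts["g001", ] <- 100  # perfectly flat gene
  tpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  samples <- data.frame(sample = paste(rep(ct, each = 3), 1:3, sep = "_"),
                        cell_type = rep(ct, each = 3), replicate = 1:3)
  colnames(counts) <- colnames(tpm) <- samples$sample
  ds <- expression_dataset(counts, tpm, samples)
  de <- differential_expression(ds)
  flat <- de[de$gene == "g001", ]
  expect_equal(flat$fold_change, 1, tolerance = 0.02)
  expect_gt(flat$p_value, 0.5)
  expect_error(differential_expression(ds, group1 = "epidermis_1"), ">= 2 samples")
})

test_that("DE recovers the planted epidermis module on the small fixture", {
  sm <- small_fixture()
  ds <- sm$sim$dataset
  de <- differential_expression(ds, genes = expression_filter(ds))
  mod <- sm$sim$truth$epidermis_module
  expect_gt(mean(de$pass_de_filter[de$gene %in% mod]), 0.85)
  expect_lt(mean(de$pass_de_filter[!de$gene %in% mod]), 0.05)
  # q monotone nondecreasing in p order
  o <- order(de$p_value)
  expect_true(all(diff(de$fdr[o]) >= -1e-12))
})

test_that("DE gene selection applies inclusive fold and strict FDR boundaries", {
  tab <- data.frame(
    gene = c("a", "b", "c", "d"),
    fold_change = c(5.0, 6, 4.99, 0.1),
    fdr = c(0.01, 0.05, 0.001, 0.01),
    pass_expression_filter = c(TRUE, TRUE, TRUE, TRUE))
  expect_identical(select_de_genes(tab), "a")        # fold boundary inclusive
  expect_false("b" %in% select_de_genes(tab))        # FDR 0.05 exactly: strict
  expect_false("c" %in% select_de_genes(tab))        # below fold threshold
  expect_identical(select_de_genes(tab, direction = "down"), "d")
  expect_setequal(select_de_genes(tab, direction = "both"), c("a", "d"))
  # unexpressed genes never selected
  tab$pass_expression_filter[1] <- FALSE
  expect_length(select_de_genes(tab), 0)
})

test_that("BH q-values match hand computation and the min-over-suffix oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(40)
  for (i in 1:5) {
    p <- runif(50)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
  }
})
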