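toy_expr <- function(values) {
  n <- ncol(values)
  lines <- rep(c("A", "B"), each = n / 2)
  expression_table(values, tibble::tibble(
    sample_id = paste0(lines, "_", rep(1:(n / 2), 2)),
    cell_line = lines, replicate = rep(1:(n / 2), 2)))
}

test_that("expression TSVs round-trip with the sample naming convention", {
  set.seed(61)
  v <- matrix(rnorm(12, 8), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), NULL))
  e <- toy_expr(v)
  f <- withr::local_tempfile()
  write_expression(e, f)
  back <- read_expression(f)
  expect_equal(back$values, e$values, tolerance = 1e-9,
               ignore_attr = "dimnames")
  expect_equal(back$samples$cell_line, e$samples$cell_line)
  expect_equal(back$genes, e$genes)
})

test_that("identical groups give p near 1 and a planted shift is recovered", {
  set.seed(62)
  base <- matrix(rnorm(200 * 3, 8, 0.25), nrow = 200,
                 dimnames = list(sprintf("g%03d", 1:200), NULL))
  e <- toy_expr(cbind(base, base))
  de <- de_test(e, "A", "B")
  expect_true(all(de$p_value > 0.99))
  shifted <- base
  shifted[1:20, ] <- shifted[1:20, ] + 2
  e2 <- toy_expr(cbind(base, shifted))
  de2 <- de_test(e2, "B", "A")
  hits <- de2$gene_id[de2$p_value < 0.01]
  expect_gte(sum(sprintf("g%03d", 1:20) %in% hits), 18)
  expect_true(all(de2$direction[1:20] == "up"))
  expect_error(de_test(e2, "A", "missing"), "replicates")
})

test_that("a planted 4-fold shift is recovered at the oracle-computed rate", {
  # 100 of 2000 genes shifted by 2 log2 units, n = 3, sigma = 0.25;
  # expectations frozen from a 20-seed simulation of this exact design
  res <- sapply(1:20, function(s) {
    set.seed(s)
    v <- matrix(rnorm(2000 * 6, 8, 0.25), nrow = 2000,
                dimnames = list(sprintf("g%04d", 1:2000), NULL))
    v[1:100, 4:6] <- v[1:100, 4:6] + 2 * sample(c(-1, 1), 100, TRUE)
    e <- expression_table(v, tibble::tibble(
      sample_id = c(paste0("A_", 1:3), paste0("B_", 1:3)),
      cell_line = rep(c("A", "B"), each = 3), replicate = rep(1:3, 2)))
    de <- de_test(e, "A", "B")
    hits <- de$p_value < 0.01
    c(tp = sum(hits[1:100]), fpr = mean(hits[-(1:100)]))
  })
  expect_gte(median(res["tp", ]), 90)
  expect_lte(median(res["fpr", ]), 0.01)
})

test_that("the vectorised Welch t matches t.test gene by gene", {
  set.seed(63)
  v <- matrix(rnorm(30, 8), nrow = 5,
              dimnames = list(sprintf("g%d", 1:5), NULL))
  e <- toy_expr(v)
  de <- de_test(e, "A", "B")
  for (i in 1:5) {
    tt <- t.test(v[i, 1:3], v[i, 4:6])
    expect_equal(de$p_value[i], tt$p.value, tolerance = 1e-12)
    expect_equal(de$statistic[i], unname(tt$statistic), tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the hand-computed step-up example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # invariant under permutation after inverse mapping
  set.seed(64)
  p <- runif(50)
  perm <- sample.int(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("candidate genes are DE against both other lines but not between them", {
  mk <- function(p) tibble::tibble(gene_id = paste0("g", 1:4), adjusted_p = p,
                                   p_value = p)
  la <- mk(c(0.001, 0.001, 0.5, 0.001))
  lb <- mk(c(0.001, 0.001, 0.001, 0.5))
  ab <- mk(c(0.5, 0.001, 0.5, 0.5))
  expect_equal(candidate_de_genes(la, lb, ab), "g1")
  expect_error(candidate_de_genes(la, lb, mk(rep(0.5, 4))[-1, ]), "universe")
  # random fixtures equal the brute-force set filter
  set.seed(65)
  for (i in 1:5) {
    la <- mk(runif(4)); lb <- mk(runif(4)); ab <- mk(runif(4))
    idx <- which(la$p_value < 0.3 & lb$p_value < 0.3 & ab$p_value >= 0.3)
    want <- as.character(vapply(idx, function(j) paste0("g", j), character(1)))
    expect_equal(candidate_de_genes(la, lb, ab, alpha = 0.3), want)
  }
})

test_that("TSS windows capture peaks down to the 1-bp boundary", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
                          tss = 100000L, start = 100000L, end = 110000L,
                          exons = list(NULL))
  grab <- peak_tbl("chr1", 79900L, 80001L)  # reaches 1 bp into tss-20000
  miss <- peak_tbl("chr1", 79900L, 80000L)
  expect_equal(genes_near_peaks(grab, genes), "g1")
  expect_equal(genes_near_peaks(miss, genes), character(0))
  expect_equal(genes_near_peaks(grab[0, ], genes), character(0))
})

test_that("near-gene linking agrees with the all-pairs oracle", {
  set.seed(66)
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:30),
    chrom = sample(c("chr1", "chr2"), 30, TRUE),
    strand = "+", tss = sample.int(1e6, 30))
  genes$start <- genes$tss
  genes$end <- genes$tss + 1000L
  pk <- random_peaks(100, c(chr1 = 1e6, chr2 = 1e6))
  got <- genes_near_peaks(pk, genes, window = 20000)
  want <- genes$gene_id[vapply(seq_len(30), function(i) {
    any(pk$chrom == genes$chrom[i] & pk$start < genes$tss[i] + 20000 &
          pk$end > genes$tss[i] - 20000)
  }, logical(1))]
  expect_setequal(got, want)
})

test_that("Fisher enrichment matches exhaustive hypergeometric enumeration", {
  u <- paste0("g", 1:40)
  # balanced table: no association
  r <- fisher_enrichment(u[1:20], u[c(1:10, 21:30)], u)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)
  # (8,2,2,8)-style association vs enumeration oracle
  r2 <- fisher_enrichment(u[1:10], u[c(1:8, 11:12)], u[1:20])
  expect_equal(unlist(r2[, 1:4], use.names = FALSE), c(8L, 2L, 2L, 8L))
  expect_equal(r2$p_value, oracle_fisher_p(8, 2, 2, 8), tolerance = 1e-9)
  expect_equal(r2$odds_ratio, 16)
  # random tables against the oracle
  set.seed(67)
  for (i in 1:10) {
    de <- sample(u, sample(5:35, 1))
    near <- sample(u, sample(5:35, 1))
    r3 <- fisher_enrichment(de, near, u)
    expect_equal(r3$p_value,
                 oracle_fisher_p(r3$de_near, r3$de_far, r3$other_near,
                                 r3$other_far),
                 tolerance = 1e-9)
  }
  # degenerate margins
  r4 <- fisher_enrichment(u, u, u)
  expect_equal(r4$p_value, 1)
  expect_true(r4$continuity)
  expect_error(fisher_enrichment("g1", "g1", character(0)), "universe")
})

test_that("proximity fractions hit the trivial bounds and the oracle", {
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          strand = "+", tss = c(50000L, 500000L),
                          start = c(50000L, 500000L),
                          end = c(51000L, 501000L), exons = list(NULL, NULL))
  on_tss <- peak_tbl("chr1", c(49990L, 499990L), c(50010L, 500010L))
  expect_equal(peak_proximity_fraction(on_tss, c("g1", "g2"), genes), 100)
  expect_equal(peak_proximity_fraction(on_tss, character(0), genes), 0)
  set.seed(68)
  pk <- random_peaks(80, c(chr1 = 1e6))
  got <- peak_proximity_fraction(pk, "g1", genes)
  want <- 100 * mean(pk$start < 50000 + 20000 & pk$end > 50000 - 20000)
  expect_equal(got, want)
})

test_that("the two-proportion chi-squared equals the closed form and is symmetric", {
  same <- compare_proportions(30, 100, 15, 50)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  r <- compare_proportions(30, 100, 10, 100)
  expect_equal(r$statistic, 12.5)  # hand: E = (20,80); 2*(100/20 + 100/80)
  expect_equal(r$p_value, stats::pchisq(12.5, 1, lower.tail = FALSE))
  swapped <- compare_proportions(10, 100, 30, 100)
  expect_equal(swapped$p_value, r$p_value)
  # agreement with the standard uncorrected test
  ct <- suppressWarnings(stats::chisq.test(matrix(c(30, 70, 10, 90), 2,
                                                  byrow = TRUE),
                                           correct = FALSE))
  expect_equal(r$statistic, unname(ct$statistic))
  expect_error(compare_proportions(0, 10, 0, 10), "Fisher")
})
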