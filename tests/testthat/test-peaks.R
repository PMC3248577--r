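test_that("BED parsing follows the 0-based half-open convention", {
  f <- withr::local_tempfile(lines = c("chr1\t100\t200", "chr2\t0\t50"))
  pk <- read_peaks(f, format = "bed")
  expect_equal(pk$chrom, c("chr1", "chr2"))
  expect_equal(pk$start, c(100L, 0L))
  expect_equal(pk$end, c(200L, 50L))
  expect_true(all(is.na(pk$summit)))

  empty <- withr::local_tempfile(lines = character(0))
  expect_equal(nrow(read_peaks(empty, "bed")), 0L)

  bad <- withr::local_tempfile(lines = c("chr1\t100\t200", "chr1\t300\t250"))
  expect_error(read_peaks(bad, "bed"), "line 2")
})

test_that("MACS tabular input converts coordinates and summit offsets", {
  f <- withr::local_tempfile(lines = c(
    "chr\tstart\tend\tlength\tsummit\ttags\t-10*log10(pvalue)\tfold_enrichment\tFDR(%)",
    "chr1\t101\t200\t100\t50\t30\t150.2\t12.1\t0.5"))
  pk <- read_peaks(f, format = "macs_tab")
  expect_equal(pk$start, 100L)   # 1-based inclusive -> 0-based
  expect_equal(pk$end, 200L)
  expect_equal(pk$summit, 150L)  # relative offset 50 -> absolute
  expect_equal(pk$score, 150.2)
})

test_that("one base pair of shared sequence is an overlap; half-open ends are not", {
  p <- function(chrom, s, e) peak_tbl(chrom, s, e)
  expect_true(peaks_overlap(p("chr1", 100L, 200L), p("chr1", 199L, 300L)))
  expect_false(peaks_overlap(p("chr1", 100L, 200L), p("chr1", 200L, 300L)))
  expect_false(peaks_overlap(p("chr1", 100L, 200L), p("chr2", 100L, 200L)))
})

test_that("replicate consensus keeps anchor peaks present in both replicates", {
  r1 <- peak_tbl("chr1", c(100L, 1000L, 5000L), c(300L, 1200L, 5100L))
  r2 <- peak_tbl("chr1", c(250L, 7000L), c(400L, 7100L))
  cons <- consensus_replicates(r1, r2)
  expect_equal(cons$start, 100L)  # only the first r1 peak touches r2
  expect_equal(nrow(consensus_replicates(r1, r1)), nrow(r1))
  # idempotence
  expect_equal(consensus_replicates(cons, r2)$start, cons$start)
})

test_that("interval operations agree with the all-pairs oracle on random fixtures", {
  set.seed(42)
  for (i in 1:25) {
    a <- random_peaks(sample(1:200, 1), c(chr1 = 1e6, chr2 = 5e5))
    b <- random_peaks(sample(1:200, 1), c(chr1 = 1e6, chr2 = 5e5))
    cc <- random_peaks(sample(1:200, 1), c(chr1 = 1e6, chr2 = 5e5))
    expect_equal(nrow(consensus_replicates(a, b)), sum(oracle_overlap_any(a, b)))
    expect_equal(as.character(classify_cobinding(a, b, cc)$category),
                 oracle_cobind_category(a, b, cc))
    expect_equal(overlap_fraction(a, b),
                 100 * mean(oracle_overlap_any(a, b)))
  }
})

test_that("co-binding categories partition the anchor set", {
  set.seed(7)
  ctcf <- random_peaks(150)
  cb <- classify_cobinding(ctcf, random_peaks(100), random_peaks(100))
  expect_equal(sum(cobind_counts(cb)$n), nrow(ctcf))
  expect_false(any(is.na(cb$category)))
  # disjoint partners -> everything CTCF_only
  far <- peak_tbl("chrX", 0L, 10L)
  cb2 <- classify_cobinding(ctcf, far, far)
  expect_true(all(cb2$category == "CTCF_only"))
})

test_that("overlap_fraction handles identity, disjoint and empty sets", {
  set.seed(3)
  a <- random_peaks(50)
  expect_equal(overlap_fraction(a, a), 100)
  expect_equal(overlap_fraction(a, peak_tbl("chrZ", 0L, 10L)), 0)
  expect_equal(overlap_fraction(a[0, ], a), 0)
})

test_that("cell-line specific peaks appear in both own replicates and no other line", {
  # three lines on one chromosome; site at 1000 is MCF7-only, 5000 is common
  mk <- function(line, rep, starts) {
    tibble::tibble(chrom = "chr1", start = starts, end = starts + 100L,
                   cell_line = line, replicate = rep)
  }
  peaks <- dplyr::bind_rows(
    mk("MCF7", 1, c(1000L, 5000L)), mk("MCF7", 2, c(1010L, 5020L)),
    mk("ZR751", 1, 5000L), mk("ZR751", 2, 4990L),
    mk("MCF10A", 1, c(5000L, 9000L)), mk("MCF10A", 2, 5010L))
  out <- cell_line_specificity(peaks, reference = "MCF7")
  expect_equal(out$start[out$class == "MCF7_specific"], 1000L)
  expect_equal(out$start[out$class == "common"], 5000L)
  # 9000 is in only one MCF10A replicate: neither specific nor shared
  expect_false(9000L %in% out$start)
  # identical peaks everywhere -> no specific peaks, everything common
  same <- dplyr::bind_rows(lapply(c("A", "B"), function(L) {
    dplyr::bind_rows(mk(L, 1, c(100L, 900L)), mk(L, 2, c(100L, 900L)))
  }))
  out2 <- cell_line_specificity(same, reference = "A")
  expect_equal(sort(out2$start[out2$class == "common"]), c(100L, 900L))
  expect_false(any(grepl("specific", out2$class)))
  expect_error(
    cell_line_specificity(dplyr::bind_rows(mk("A", 1, 100L), mk("B", 1, 100L))),
    "2 replicates")
})

test_that("specificity classes are mutually consistent on random 3-line fixtures", {
  set.seed(11)
  for (i in 1:10) {
    peaks <- dplyr::bind_rows(lapply(c("L1", "L2", "L3"), function(L) {
      dplyr::bind_rows(lapply(1:2, function(r) {
        p <- random_peaks(60, c(chr1 = 2e5))
        tibble::tibble(chrom = p$chrom, start = p$start, end = p$end,
                       cell_line = L, replicate = r)
      }))
    }))
    out <- cell_line_specificity(peaks, reference = "L1")
    spec_classes <- grep("_specific$", unique(out$class), value = TRUE)
    # specific sets of distinct lines contain no mutually overlapping peaks
    for (c1 in spec_classes) {
      for (c2 in setdiff(spec_classes, c1)) {
        s1 <- out[out$class == c1, ]
        s2 <- out[out$class == c2, ]
        if (nrow(s1) && nrow(s2)) {
          expect_false(any(oracle_overlap_any(s1, s2)))
        }
      }
      # specific ∩ common = empty (no overlap either)
      com <- out[out$class == "common", ]
      s1 <- out[out$class == c1, ]
      if (nrow(s1) && nrow(com)) {
        expect_false(any(oracle_overlap_any(s1, com)))
      }
    }
    # oracle re-derivation of one line's specific set
    l1r <- lapply(1:2, function(r) {
      peaks[peaks$cell_line == "L1" & peaks$replicate == r, ]
    })
    cons <- oracle_consensus(l1r[[1]], l1r[[2]])
    others <- peaks[peaks$cell_line != "L1", ]
    expected <- cons[!oracle_overlap_any(cons, others), ]
    got <- out[out$class == "L1_specific", ]
    expect_equal(sort(got$start), sort(expected$start))
  }
})

test_that("BED6 output round-trips through the reader", {
  set.seed(5)
  pk <- random_peaks(100)
  f <- withr::local_tempfile()
  write_bed(pk, f)
  expect_equal(length(readLines(f)), 100L)
  back <- read_peaks(f, "bed")
  expect_equal(back[, c("chrom", "start", "end")],
               pk[, c("chrom", "start", "end")])
  # missing name/score become ./0
  one <- withr::local_tempfile()
  write_bed(peak_tbl("chr1", 100L, 200L), one)
  expect_equal(readLines(one), "chr1\t100\t200\t.\t0\t.")
})

test_that("invalid intervals and summits are rejected at construction", {
  expect_error(peak_tbl("chr1", 200L, 100L), "start < end")
  expect_error(peak_tbl("chr1", 100L, 200L, summit = 500L), "summit")
})
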