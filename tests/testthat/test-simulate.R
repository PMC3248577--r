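# small scenario for fast structural checks
small_cfg <- function(seed = 1, ...) {
  scenario_config(seed = seed, chroms = c(chr1 = 5e5, chr2 = 5e5),
                  sites_per_factor = 120L, min_spacing = 1000L,
                  reads_per_library = 20000L, n_genes = 300L, ...)
}

test_that("configuration validation rejects unknown keys and bad rates", {
  expect_error(scenario_config(not_a_key = 1), "not_a_key")
  expect_error(scenario_config(replicate_dropout = 1.5), "\\[0, 1\\]")
  expect_error(scenario_config(cobind_rates = c(CTCF_ER = 0.6, CTCF_FOXA1 = 0.5,
                                                CTCF_ER_FOXA1 = 0)), "exceed")
  expect_error(scenario_config(chroms = c(chr1 = 0)), "positive")
  cfg <- scenario_config(seed = 42)
  f <- withr::local_tempfile()
  yaml::write_yaml(list(seed = 42L, sites_per_factor = 10L,
                        lines = list("A", "B")), f)
  cfg2 <- read_scenario_config(f)
  expect_equal(cfg2$sites_per_factor, 10L)
  expect_equal(cfg2$lines, c("A", "B"))
})

test_that("the generator is fully deterministic: same seed, byte-identical files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_scenario(small_cfg(9), d1)
  s2 <- simulate_scenario(small_cfg(9), d2)
  files <- function(d) {
    f <- sort(list.files(d, recursive = TRUE, full.names = TRUE))
    setNames(unname(tools::md5sum(f)), basename(f))
  }
  expect_equal(files(d1), files(d2))
  s3 <- simulate_scenario(small_cfg(10), withr::local_tempdir())
  expect_false(identical(s1$truth, s3$truth))
})

test_that("the random genome is uniform with exact chromosome sizes", {
  cfg <- scenario_config(seed = 4, chroms = c(chr1 = 1e6))
  g <- make_genome(cfg)
  expect_equal(nchar(g[["chr1"]]), 1e6)
  gc <- sum(strsplit(g[["chr1"]], "")[[1]] %in% c("G", "C")) / 1e6
  expect_lt(abs(gc - 0.5), 0.005)
  expect_identical(make_genome(cfg), g)
  expect_error(make_genome(scenario_config(seed = 1, chroms = c(chr1 = 1e5,
                                                                chr2 = -1))),
               "positive")
})

test_that("binding truth honours co-binding rates and sharing classes", {
  cfg <- scenario_config(seed = 5)
  truth <- make_binding_truth(cfg)
  ctcf <- truth[truth$factor == "CTCF" & truth$cell_line == "MCF7", ]
  n <- nrow(ctcf)
  # 4.8% triple co-binding within binomial 3.5-sigma of the configured rate
  for (cat in c("both", "ER", "FOXA1")) {
    rate <- switch(cat, both = 0.048, ER = 0.048, FOXA1 = 0.196)
    expect_lt(abs(sum(ctcf$cobind == cat) / n - rate), 0.02)
  }
  # ER absent in the ER-negative line
  expect_equal(nrow(truth[truth$factor == "ER" & truth$cell_line == "MCF10A", ]), 0L)
  expect_equal(nrow(truth[truth$factor == "ER" & truth$cell_line == "MCF7", ]),
               cfg$sites_per_factor)
  # sharing classes: common sites identical across lines
  common <- truth[truth$factor == "CTCF" & truth$class == "common", ]
  pos_by_line <- split(common$pos, common$cell_line)
  expect_equal(sort(pos_by_line$MCF7), sort(pos_by_line$MCF10A))
  # zero rates -> disjoint factor sets
  t0 <- make_binding_truth(scenario_config(
    seed = 6, cobind_rates = c(CTCF_ER = 0, CTCF_FOXA1 = 0, CTCF_ER_FOXA1 = 0)))
  m7 <- t0[t0$cell_line == "MCF7", ]
  expect_false(any(m7$pos[m7$factor == "ER" & m7$class == "cobound"] %in%
                     m7$pos[m7$factor == "CTCF"]))
  expect_equal(sum(m7$class == "cobound"), 0L)
  # no line-specific sites when the fraction is zero
  t1 <- make_binding_truth(scenario_config(seed = 7, line_specific_fraction = 0))
  expect_false(any(grepl("_specific", t1$class[t1$factor == "CTCF"])))
})

test_that("replicate emission reflects dropout in the consensus count", {
  cfg <- scenario_config(seed = 8, replicate_dropout = 0.1, noise_peaks = 0L,
                         summit_jitter_sd = 0)
  truth <- make_binding_truth(cfg)
  pk <- emit_replicate_peaks(truth, cfg)
  m7 <- pk[pk$factor == "CTCF" & pk$cell_line == "MCF7", ]
  reps <- lapply(1:2, function(r) as_peak_tbl_for_test(m7[m7$replicate == r, ]))
  cons <- consensus_replicates(reps[[1]], reps[[2]])
  n_truth <- sum(truth$factor == "CTCF" & truth$cell_line == "MCF7")
  # both-replicate survival 0.9^2 = 0.81, within ~4 sigma
  expect_lt(abs(nrow(cons) / n_truth - 0.81), 0.05)
  # no dropout, no jitter, no noise -> replicates identical to truth
  cfg0 <- scenario_config(seed = 9, replicate_dropout = 0, noise_peaks = 0L,
                          summit_jitter_sd = 0)
  pk0 <- emit_replicate_peaks(make_binding_truth(cfg0), cfg0)
  m70 <- pk0[pk0$factor == "CTCF" & pk0$cell_line == "MCF7", ]
  expect_equal(sort(m70$summit[m70$replicate == 1]),
               sort(m70$summit[m70$replicate == 2]))
})

test_that("planted motifs are recovered by the scanner at the planting sites", {
  cfg <- small_cfg(11, motif_plant_rate = 1, motif_offset_max = 0L)
  truth <- make_binding_truth(cfg)
  genome <- plant_motifs(make_genome(cfg), truth, cfg)
  planted <- attr(genome, "planted")
  expect_gt(nrow(planted), 0)
  ctcf_planted <- planted[planted$factor == "CTCF", ]
  p <- builtin_motifs()$CTCF
  hit <- vapply(seq_len(nrow(ctcf_planted)), function(i) {
    s <- substr(genome[[ctcf_planted$chrom[i]]],
                ctcf_planted$start[i] + 1L,
                ctcf_planted$start[i] + p$length)
    nrow(similarity_scan(s, p, threshold = 0.85)) > 0
  }, logical(1))
  expect_gte(mean(hit), 0.97)  # rare overwrites by partner-motif planting
  fox_planted <- planted[planted$factor == "FOXA1", ]
  pf <- builtin_motifs()$FOXA1
  fox_hit <- vapply(seq_len(nrow(fox_planted)), function(i) {
    s <- substr(genome[[fox_planted$chrom[i]]],
                fox_planted$start[i] + 1L,
                fox_planted$start[i] + pf$length)
    nrow(similarity_scan(s, pf, threshold = 0.85)) > 0
  }, logical(1))
  expect_gte(mean(fox_hit), 0.99)  # planted last, nothing overwrites it
  # rate 0 leaves the genome untouched
  cfg0 <- small_cfg(11, motif_plant_rate = 0)
  g0 <- make_genome(cfg0)
  g0p <- plant_motifs(g0, make_binding_truth(cfg0), cfg0)
  expect_equal(unclass(g0p)[names(g0)], unclass(g0), ignore_attr = TRUE)
})

test_that("read libraries have exact sizes and signal concentrates near sites", {
  cfg <- small_cfg(12, signal_to_background = 1e6)
  truth <- make_binding_truth(cfg)
  reads <- simulate_reads(truth, cfg)
  expect_equal(unname(vapply(reads, nrow, integer(1))),
               rep(cfg$reads_per_library, length(reads)))
  m7 <- reads$CTCF_MCF7
  sites <- truth[truth$factor == "CTCF" & truth$cell_line == "MCF7", ]
  near <- peakcobind:::tss_near_sites(
    tibble::tibble(chrom = m7$chrom, tss = m7$pos), sites, 500)
  expect_gte(mean(near), 0.995)  # ~3 sigma of the 100-bp read spread
  # input is uniform across chromosomes (proportional to length)
  expect_lt(abs(mean(reads$input$chrom == "chr1") - 0.5), 0.02)
})

test_that("every generated file parses through its package reader", {
  d <- withr::local_tempdir()
  scen <- simulate_scenario(small_cfg(13), d)
  expect_no_warning({
    sizes <- read_chrom_sizes(scen$paths$chrom_sizes)
    genes <- read_gene_models(scen$paths$genes)
    expr <- read_expression(scen$paths$expression)
    pk <- read_peaks(scen$paths$peaks[["CTCF_MCF7_rep1"]], "bed")
    rd <- load_reads(scen$paths$reads[["CTCF_MCF7"]])
  })
  expect_equal(setNames(as.numeric(sizes$length), sizes$chrom),
               setNames(as.numeric(nchar(scen$genome)), names(scen$genome)))
  fa <- Biostrings::readDNAStringSet(scen$paths$fasta)
  expect_equal(unname(nchar(as.character(fa))), unname(nchar(scen$genome)))
  expect_equal(nrow(genes), nrow(scen$genes))
  expect_equal(dim(expr$values), dim(scen$expression$values))
  expect_equal(nrow(rd), small_cfg(13)$reads_per_library)
  expect_gt(nrow(pk), 0)
})

test_that("expression tables carry the configured dimensions and DE structure", {
  cfg <- small_cfg(14)
  truth <- make_binding_truth(cfg)
  ge <- simulate_genes_and_expression(truth, cfg)
  expect_equal(nrow(ge$expression$values), cfg$n_genes)
  expect_equal(ncol(ge$expression$values), cfg$n_reps * length(cfg$lines))
  expect_equal(dim(ge$de_truth), c(cfg$n_genes, length(cfg$lines)))
  # a planted DE gene really is shifted in its line
  li <- which(ge$de_truth[, "MCF7"])[1]
  if (!is.na(li)) {
    m7 <- ge$expression$values[li, ge$expression$samples$cell_line == "MCF7"]
    other <- ge$expression$values[li, ge$expression$samples$cell_line == "ZR751"]
    expect_gt(abs(mean(m7) - mean(other)), 1)
  }
})
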