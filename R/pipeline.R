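#' Run the full co-binding analysis pipeline
#'
#' Executes, in order: synthetic-data simulation, replicate consensus,
#' co-binding classification, GSC overlap significance, binned signal
#' matrices, windowed motif enrichment, genomic-distribution annotation, and
#' DE-gene proximity/enrichment, writing per-stage outputs (TSV/JSON) under
#' `out_dir/<stage>/` plus a run manifest. Every stochastic stage is driven
#' by `config$seed`, so a re-run with the same configuration reproduces the
#' stage outputs byte for byte. Files already present are rewritten only
#' when `overwrite = TRUE` is given or their stage has to run anyway.
#'
#' @param config a [scenario_config()] or path to a YAML/JSON config file.
#' @param out_dir output directory.
#' @param overwrite rewrite existing stage outputs (default `TRUE`).
#' @return A `run_manifest`: list with the configuration snapshot, seed,
#'   package version, per-stage output paths with MD5 digests, the headline
#'   `report` list, and a timestamp.
#' @export
run_pipeline <- function(config = scenario_config(), out_dir,
                         overwrite = TRUE) {
  cfg <- if (is.character(config)) read_scenario_config(config) else config
  stopifnot(inherits(cfg, "scenario_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = cfg$seed)
  stage_paths <- list()
  stage_dir <- function(stage) {
    d <- file.path(out_dir, stage)
    dir.create(d, showWarnings = FALSE)
    d
  }
  emit <- function(stage, name, writer) {
    d <- stage_dir(stage)
    p <- file.path(d, name)
    if (overwrite || !file.exists(p)) writer(p)
    stage_paths[[stage]] <<- c(stage_paths[[stage]], setNames(p, name))
    p
  }

  ## stage 1: simulate ------------------------------------------------------
  scen <- simulate_scenario(cfg, stage_dir("simulate"))
  stage_paths$simulate <- unlist(scen$paths, use.names = TRUE)
  ref <- cfg$lines[1L]
  genome_sizes <- setNames(as.numeric(nchar(scen$genome)), names(scen$genome))

  ## stage 2: replicate consensus ------------------------------------------
  peak_split <- split(
    scen$peaks,
    paste(scen$peaks$factor, scen$peaks$cell_line, scen$peaks$replicate,
          sep = "_"))
  get_reps <- function(factor, line) {
    lapply(1:2, function(r) {
      as_peak_tbl(peak_split[[paste(factor, line, r, sep = "_")]],
                  label = paste(factor, line, r, sep = "_"))
    })
  }
  combos <- dplyr::distinct(scen$peaks[, c("factor", "cell_line")])
  consensus <- list()
  for (i in seq_len(nrow(combos))) {
    f <- combos$factor[i]; L <- combos$cell_line[i]
    reps <- get_reps(f, L)
    consensus[[paste0(f, "_", L)]] <- consensus_replicates(reps[[1L]], reps[[2L]])
  }
  for (key in names(consensus)) {
    emit("consensus", paste0(key, ".bed"),
         function(p) write_bed(consensus[[key]], p))
  }
  report$consensus_counts <- lapply(consensus, nrow)

  ## stage 3: co-binding classification ------------------------------------
  cobind <- classify_cobinding(consensus[[paste0("CTCF_", ref)]],
                               consensus[[paste0("ER_", ref)]],
                               consensus[[paste0("FOXA1_", ref)]])
  counts <- cobind_counts(cobind)
  emit("cobind", "cobind_counts.tsv",
       function(p) readr::write_tsv(counts, p, progress = FALSE))
  emit("cobind", "cobind_peaks.tsv",
       function(p) readr::write_tsv(tibble::as_tibble(cobind), p, progress = FALSE))
  report$cobind <- setNames(as.list(counts$n), as.character(counts$category))
  report$cobind_percent <-
    100 * sum(counts$n[counts$category != "CTCF_only"]) / sum(counts$n)

  ## cell-line specificity of CTCF (used by stages 8 and reporting) --------
  ctcf_all <- scen$peaks[scen$peaks$factor == "CTCF", , drop = FALSE]
  spec <- cell_line_specificity(ctcf_all, reference = ref)
  emit("cobind", "ctcf_line_classes.tsv",
       function(p) readr::write_tsv(spec, p, progress = FALSE))
  report$ctcf_line_classes <- as.list(table(spec$class))

  ## stage 4: GSC overlap significance -------------------------------------
  gsc_ab <- gsc_overlap_test(consensus[[paste0("CTCF_", ref)]],
                             consensus[[paste0("ER_", ref)]],
                             genome_sizes, iterations = cfg$gsc_iterations,
                             block_length = cfg$gsc_block_length,
                             seed = cfg$seed + 10L)
  gsc_ba <- gsc_overlap_test(consensus[[paste0("ER_", ref)]],
                             consensus[[paste0("CTCF_", ref)]],
                             genome_sizes, iterations = cfg$gsc_iterations,
                             block_length = cfg$gsc_block_length,
                             seed = cfg$seed + 11L)
  gsc_tbl <- dplyr::bind_rows(
    dplyr::mutate(tidy(gsc_ab), comparison = "CTCF_in_ER", .before = 1),
    dplyr::mutate(tidy(gsc_ba), comparison = "ER_in_CTCF", .before = 1))
  emit("gsc", "gsc.tsv", function(p) readr::write_tsv(gsc_tbl, p, progress = FALSE))
  emit("gsc", "gsc.json", function(p) {
    jsonlite::write_json(gsc_tbl, p, auto_unbox = TRUE, digits = NA)
  })
  report$gsc_p_ctcf_in_er <- gsc_ab$p_value
  report$gsc_p_er_in_ctcf <- gsc_ba$p_value

  ## stage 5: signal matrices over triple co-bound regions ------------------
  triple <- as_peak_tbl(cobind[cobind$category == "CTCF_ER_FOXA1", , drop = FALSE])
  input_track <- read_track(scen$reads$input,
                            total_reads = nrow(scen$reads$input),
                            label = "input")
  report$total_intensity <- list()
  if (nrow(triple) > 0L) {
    for (f in c("CTCF", "ER", "FOXA1")) {
      tr <- read_track(scen$reads[[paste0(f, "_", ref)]],
                       total_reads = nrow(scen$reads[[paste0(f, "_", ref)]]),
                       label = paste0(f, "_", ref))
      m <- build_signal_matrix(triple, tr, input_track, genome = genome_sizes)
      emit("signal", paste0(f, "_triple_matrix.tsv"),
           function(p) write_signal_tsv(m, p))
      emit("signal", paste0(f, "_triple_profile.tsv"), function(p) {
        readr::write_tsv(tibble::tibble(bin = seq_along(column_profile(m)) - 1L,
                                        value = column_profile(m)),
                         p, progress = FALSE)
      })
      report$total_intensity[[f]] <- total_intensity(m)
    }
  }

  ## stage 6: motif enrichment around co-bound summits ----------------------
  motifs <- builtin_motifs()
  cats <- list(
    triple = triple,
    er_ctcf = as_peak_tbl(cobind[cobind$category == "CTCF_ER", , drop = FALSE]),
    foxa1_ctcf = as_peak_tbl(cobind[cobind$category == "CTCF_FOXA1", , drop = FALSE]))
  motif_tbl <- purrr::imap_dfr(cats, function(pk, cat) {
    if (nrow(pk) == 0L) return(NULL)
    seqs <- extract_summit_sequences(scen$genome, pk, span = 2000)
    res <- motif_enrichment(seqs, unname(motifs), n_perm = cfg$motif_n_perm,
                            threshold = cfg$motif_threshold,
                            seed = cfg$seed + 20L)
    dplyr::mutate(tibble::as_tibble(res), category = cat, .before = 1)
  })
  emit("motif", "motif_enrichment.tsv",
       function(p) readr::write_tsv(motif_tbl, p, progress = FALSE))
  min_p <- dplyr::summarise(
    dplyr::group_by(motif_tbl, .data$category, .data$pwm),
    min_p = min(.data$p_value), .groups = "drop")
  report$motif_min_p <- purrr::pmap(min_p, function(category, pwm, min_p) {
    list(category = category, pwm = pwm, min_p = min_p)
  })

  ## stage 7: genomic distribution -----------------------------------------
  dist_all <- genomic_distribution(consensus[[paste0("CTCF_", ref)]], scen$genes)
  emit("annotate", "ctcf_distribution.tsv",
       function(p) readr::write_tsv(tibble::as_tibble(dist_all), p, progress = FALSE))
  report$ctcf_promoter_percent <-
    dist_all$percent[dist_all$category == "promoter"]
  er_ctcf_peaks <- as_peak_tbl(cobind[cobind$category %in%
                                        c("CTCF_ER", "CTCF_ER_FOXA1"), ,
                                      drop = FALSE])
  if (nrow(er_ctcf_peaks) > 0L) {
    dist_ec <- genomic_distribution(er_ctcf_peaks, scen$genes)
    emit("annotate", "er_ctcf_distribution.tsv",
         function(p) readr::write_tsv(tibble::as_tibble(dist_ec), p, progress = FALSE))
    report$er_ctcf_promoter_upstream_percent <-
      attr(dist_ec, "promoter_upstream_percent")
  }

  ## stage 8: expression enrichment ----------------------------------------
  expr <- scen$expression
  lines <- cfg$lines
  de <- list()
  for (i in seq_along(lines)) {
    for (j in seq_along(lines)) {
      if (i < j) {
        de[[paste(lines[i], lines[j], sep = "_vs_")]] <-
          de_test(expr, lines[i], lines[j])
      }
    }
  }
  contrast <- function(a, b) {
    de[[paste(a, b, sep = "_vs_")]] %||% de[[paste(b, a, sep = "_vs_")]]
  }
  candidates <- lapply(setNames(lines, lines), function(L) {
    others <- setdiff(lines, L)
    candidate_de_genes(contrast(L, others[1L]), contrast(L, others[2L]),
                       contrast(others[1L], others[2L]))
  })
  near <- lapply(setNames(lines, lines), function(L) {
    cls <- spec[spec$class == paste0(L, "_specific"), , drop = FALSE]
    if (nrow(cls) == 0L) return(character(0))
    genes_near_peaks(as_peak_tbl(cls), scen$genes)
  })
  universe <- scen$genes$gene_id
  fisher_tbl <- purrr::map_dfr(lines, function(de_line) {
    purrr::map_dfr(lines, function(peak_line) {
      dplyr::mutate(
        fisher_enrichment(candidates[[de_line]], near[[peak_line]], universe,
                          alternative = "greater"),
        de_line = de_line, peak_line = peak_line, .before = 1)
    })
  })
  emit("express", "fisher_enrichment.tsv",
       function(p) readr::write_tsv(fisher_tbl, p, progress = FALSE))
  diag_row <- fisher_tbl[fisher_tbl$de_line == ref & fisher_tbl$peak_line == ref, ]
  report$fisher_diag_p <- setNames(
    as.list(fisher_tbl$p_value[fisher_tbl$de_line == fisher_tbl$peak_line]),
    fisher_tbl$de_line[fisher_tbl$de_line == fisher_tbl$peak_line])
  report$fisher_diag_or <- setNames(
    as.list(fisher_tbl$odds_ratio[fisher_tbl$de_line == fisher_tbl$peak_line]),
    fisher_tbl$de_line[fisher_tbl$de_line == fisher_tbl$peak_line])

  ## regulated-gene proximity (ER+CTCF vs ER+FOXA1-without-CTCF) ------------
  er_cons <- consensus[[paste0("ER_", ref)]]
  ctcf_cons <- consensus[[paste0("CTCF_", ref)]]
  fox_cons <- consensus[[paste0("FOXA1_", ref)]]
  er_and_ctcf <- as_peak_tbl(er_cons[overlap_any(er_cons, ctcf_cons), , drop = FALSE])
  er_fox_not_ctcf <- as_peak_tbl(
    er_cons[overlap_any(er_cons, fox_cons) & !overlap_any(er_cons, ctcf_cons), ,
            drop = FALSE])
  reg_genes <- scen$regulated$gene_id
  prox <- list()
  if (nrow(er_and_ctcf) > 0L && nrow(er_fox_not_ctcf) > 0L) {
    f1 <- peak_proximity_fraction(er_and_ctcf, reg_genes, scen$genes)
    f2 <- peak_proximity_fraction(er_fox_not_ctcf, reg_genes, scen$genes)
    k1 <- round(f1 / 100 * nrow(er_and_ctcf))
    k2 <- round(f2 / 100 * nrow(er_fox_not_ctcf))
    cmp <- compare_proportions(k1, nrow(er_and_ctcf), k2, nrow(er_fox_not_ctcf))
    prox <- list(er_ctcf_percent = f1, er_foxa1_no_ctcf_percent = f2,
                 chisq_statistic = cmp$statistic, chisq_p = cmp$p_value)
    prox_tbl <- tibble::tibble(
      class = c("ER_and_CTCF", "ER_FOXA1_without_CTCF"),
      n_peaks = c(nrow(er_and_ctcf), nrow(er_fox_not_ctcf)),
      percent_near_regulated = c(f1, f2))
    emit("express", "proximity.tsv",
         function(p) readr::write_tsv(prox_tbl, p, progress = FALSE))
  }
  report$proximity <- prox

  ## stage 9: report + manifest --------------------------------------------
  emit("report", "report.json", function(p) {
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA)
  })
  manifest <- list(
    package = "peakcobind",
    version = as.character(utils::packageVersion("peakcobind")),
    seed = cfg$seed,
    config = unclass(cfg),
    stages = lapply(stage_paths, function(ps) {
      lapply(setNames(as.list(unname(ps)), names(ps)), function(p) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      })
    }),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(c(manifest, list(report = report)),
                      class = "run_manifest"))
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("peakcobind run (seed %d): %d stages\n", x$seed,
              length(x$stages)))
  for (s in names(x$stages)) {
    cat(sprintf("  %-10s %d output(s)\n", s, length(x$stages[[s]])))
  }
  invisible(x)
}
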