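#' Scenario configuration for the synthetic-data generator
#'
#' Returns the full parameter set driving [simulate_scenario()], with
#' defaults emulating the statistical structure of a three-cell-line
#' (two ER-positive, one ER-negative) CTCF/ER/FOXA1 ChIP-seq + expression
#' study at desk scale: two 5-Mb chromosomes, ~1000 binding sites per
#' factor and line, co-binding rates matching the observed fractions
#' (ER and/or FOXA1 co-binding at CTCF sites: ~4.8% triple, ~4.8% ER-only,
#' ~19.6% FOXA1-only; half of the remaining ER sites carry FOXA1, the
#' pioneer-factor geometry), ~13% line-specific CTCF sites, duplicate replicates
#' with 5% dropout, read pileups of Normal(summit, 100 bp) over uniform
#' background, motifs planted near summits, and expression tables with DE
#' genes preferentially placed near line-specific sites (30% vs 5%
#' background).
#'
#' @param ... named overrides of any listed default; an unknown name is a
#'   validation error.
#' @return A named list of class `scenario_config`.
#' @export
scenario_config <- function(...) {
  cfg <- list(
    seed = 1L,
    chroms = c(chr1 = 5e6, chr2 = 5e6),
    lines = c("MCF7", "ZR751", "MCF10A"),
    er_lines = c("MCF7", "ZR751"),
    sites_per_factor = 1000L,
    cobind_rates = c(CTCF_ER = 0.048, CTCF_FOXA1 = 0.196,
                     CTCF_ER_FOXA1 = 0.048),
    er_foxa1_rate = 0.5,
    line_specific_fraction = 0.13,
    er_positive_shared_fraction = 0.10,
    cobind_offset_max = 500L,
    min_spacing = 2000L,
    replicate_dropout = 0.05,
    noise_peaks = 50L,
    summit_jitter_sd = 20,
    peak_width_mean = 400,
    peak_width_sd = 80,
    reads_per_library = 200000L,
    signal_to_background = 4,
    read_spread_sd = 100,
    motif_plant_rate = 0.7,
    motif_offset_max = 50L,
    n_genes = 2000L,
    n_reps = 3L,
    de_near_prob = 0.3,
    de_background_prob = 0.05,
    de_effect = 2,
    expression_noise_sd = 0.25,
    reg_near_prob = 0.3,
    reg_background_prob = 0.05,
    gsc_iterations = 2000L,
    gsc_block_length = 5e5,
    motif_n_perm = 500L,
    motif_threshold = 0.85
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over))) {
    over <- over[[1L]]
  }
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown configuration key(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  if ("lines" %in% names(over) && !("er_lines" %in% names(over))) {
    # by convention the last listed line is the ER-negative control
    cfg$er_lines <- head(cfg$lines, -1L)
  }
  validate_scenario_config(cfg)
  structure(cfg, class = "scenario_config")
}

validate_scenario_config <- function(cfg) {
  probs <- c(cfg$line_specific_fraction, cfg$er_positive_shared_fraction,
             cfg$replicate_dropout, cfg$motif_plant_rate, cfg$de_near_prob,
             cfg$de_background_prob, cfg$reg_near_prob,
             cfg$reg_background_prob, cfg$er_foxa1_rate, cfg$cobind_rates)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (sum(cfg$cobind_rates) > 1) abort("summed co-binding rates exceed 1")
  if (any(cfg$chroms <= 0)) abort("chromosome lengths must be positive")
  if (length(cfg$lines) < 2L) abort("need at least 2 cell lines")
  if (!all(cfg$er_lines %in% cfg$lines)) abort("er_lines must be a subset of lines")
  invisible(cfg)
}

#' Load a scenario configuration from YAML/JSON
#'
#' @param path config file; keys must match [scenario_config()] arguments.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (nm in c("chroms", "cobind_rates")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  for (nm in c("lines", "er_lines")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- as.character(unlist(raw[[nm]]))
  }
  do.call(scenario_config, raw)
}

# k positions in [0, len) with pairwise spacing >= s (classic gap trick)
spaced_positions <- function(k, len, s) {
  if (k <= 0L) return(integer(0))
  slack <- len - (k - 1) * s - 1
  if (slack <= 0) abort("site count infeasible for the requested spacing")
  sort(floor(runif(k) * slack)) + (seq_len(k) - 1L) * s
}

#' Generate a uniform random genome
#'
#' i.i.d. uniform A/C/G/T background; deterministic given the config seed.
#'
#' @param cfg a [scenario_config()].
#' @return Named character vector of chromosome sequences (use
#'   [write_genome()] for FASTA + chrom.sizes output).
#' @export
make_genome <- function(cfg) {
  if (any(cfg$chroms <= 0)) abort("zero-length chromosome")
  withr::with_seed(cfg$seed, {
    bases <- charToRaw("ACGT")
    vapply(cfg$chroms, function(len) {
      rawToChar(bases[sample.int(4L, len, replace = TRUE)])
    }, character(1))
  })
}

#' Write a genome as FASTA plus chrom.sizes
#'
#' @param genome named character vector of sequences.
#' @param fasta,sizes output paths.
#' @return `fasta`, invisibly.
#' @export
write_genome <- function(genome, fasta, sizes) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), fasta,
                              width = 70L)
  readr::write_lines(sprintf("%s\t%d", names(genome), nchar(genome)), sizes)
  invisible(fasta)
}

#' Simulate per-factor, per-line binding-site truth
#'
#' CTCF sites are drawn uniformly with minimum spacing and split into
#' line-sharing classes: common to all lines, shared by the ER-positive
#' lines only, and line-specific (at the configured fractions). Within each
#' line, configured fractions of CTCF sites are co-bound by ER and/or FOXA1;
#' the partner site centre is offset uniformly within
#' `±cobind_offset_max` bp of the CTCF centre (co-binding is not centred on
#' the CTCF summit). ER and FOXA1 exist only in the ER-positive lines, and
#' each is topped up with independent sites to `sites_per_factor`.
#'
#' @param cfg a [scenario_config()].
#' @return Tibble with `factor`, `cell_line`, `chrom`, `pos` (site centre),
#'   `class` (`common`, `er_positive`, `<line>_specific`, `independent`) and
#'   `cobind` (for CTCF sites: `none`, `ER`, `FOXA1`, `both`).
#' @export
make_binding_truth <- function(cfg) {
  withr::with_seed(cfg$seed + 1L, make_binding_truth_impl(cfg))
}

make_binding_truth_impl <- function(cfg) {
  S <- cfg$sites_per_factor
  n_spec <- round(cfg$line_specific_fraction * S)
  n_er_shared <- round(cfg$er_positive_shared_fraction * S)
  n_common <- S - n_spec - n_er_shared
  if (n_common < 0L) abort("specific + shared fractions exceed 1")
  n_total <- n_common + n_er_shared + n_spec * length(cfg$lines)

  # allocate site count per chromosome proportional to length, then draw
  lens <- cfg$chroms
  alloc <- floor(n_total * lens / sum(lens))
  alloc[1L] <- alloc[1L] + (n_total - sum(alloc))
  sites <- dplyr::bind_rows(purrr::imap(as.list(alloc), function(k, chr) {
    tibble::tibble(chrom = chr,
                   pos = spaced_positions(k, lens[[chr]], cfg$min_spacing))
  }))
  sites <- sites[sample.int(nrow(sites)), , drop = FALSE]
  classes <- c(rep("common", n_common), rep("er_positive", n_er_shared),
               rep(paste0(cfg$lines, "_specific"), each = n_spec))
  sites$class <- classes

  out <- list()
  for (L in cfg$lines) {
    keep <- sites$class == "common" |
      (sites$class == "er_positive" & L %in% cfg$er_lines) |
      sites$class == paste0(L, "_specific")
    ctcf <- sites[keep, , drop = FALSE]
    n <- nrow(ctcf)
    cobind <- rep("none", n)
    n_both <- round(cfg$cobind_rates[["CTCF_ER_FOXA1"]] * n)
    n_er <- round(cfg$cobind_rates[["CTCF_ER"]] * n)
    n_fox <- round(cfg$cobind_rates[["CTCF_FOXA1"]] * n)
    if (L %in% cfg$er_lines) {
      idx <- sample.int(n, n_both + n_er + n_fox)
      cobind[idx[seq_len(n_both)]] <- "both"
      cobind[idx[n_both + seq_len(n_er)]] <- "ER"
      cobind[idx[n_both + n_er + seq_len(n_fox)]] <- "FOXA1"
    }
    ctcf$cobind <- cobind
    ctcf$factor <- "CTCF"
    ctcf$cell_line <- L
    out[[length(out) + 1L]] <- ctcf

    if (L %in% cfg$er_lines) {
      jitter_onto <- function(base_chrom, base_pos) {
        off <- sample(-cfg$cobind_offset_max:cfg$cobind_offset_max,
                      length(base_pos), replace = TRUE)
        tibble::tibble(chrom = base_chrom,
                       pos = pmin(pmax(base_pos + off, 0),
                                  lens[base_chrom] - 1))
      }
      uniform_sites <- function(k) {
        dplyr::bind_rows(purrr::imap(as.list(lens), function(len, chr) {
          ki <- round(k * len / sum(lens))
          tibble::tibble(chrom = chr, pos = floor(runif(ki) * len))
        }))
      }
      # ER: co-bound at CTCF sites plus independent sites up to the target
      er_co <- jitter_onto(ctcf$chrom[ctcf$cobind %in% c("ER", "both")],
                           ctcf$pos[ctcf$cobind %in% c("ER", "both")])
      er_co$class <- "cobound"
      er_extra <- uniform_sites(max(0L, S - nrow(er_co)))
      er_extra$class <- "independent"
      er <- dplyr::bind_rows(er_co, er_extra)
      # FOXA1: co-bound at CTCF sites, at a fraction of the ER-only sites
      # (the pioneer-factor geometry: most ER sites carry FOXA1), and
      # independent sites up to the target
      fox_co <- jitter_onto(ctcf$chrom[ctcf$cobind %in% c("FOXA1", "both")],
                            ctcf$pos[ctcf$cobind %in% c("FOXA1", "both")])
      fox_co$class <- "cobound"
      n_on_er <- min(round(cfg$er_foxa1_rate * nrow(er_extra)),
                     max(0L, S - nrow(fox_co)))
      er_pick <- er_extra[sample.int(nrow(er_extra), n_on_er), , drop = FALSE]
      fox_er <- jitter_onto(er_pick$chrom, er_pick$pos)
      fox_er$class <- "cobound_er"
      fox_extra <- uniform_sites(max(0L, S - nrow(fox_co) - nrow(fox_er)))
      fox_extra$class <- "independent"
      fox <- dplyr::bind_rows(fox_co, fox_er, fox_extra)
      for (fac in c("ER", "FOXA1")) {
        tb <- if (fac == "ER") er else fox
        tb$cobind <- "none"
        tb$factor <- fac
        tb$cell_line <- L
        out[[length(out) + 1L]] <- tb
      }
    }
  }
  res <- dplyr::bind_rows(out)
  res$pos <- as.integer(res$pos)
  dplyr::arrange(res[, c("factor", "cell_line", "chrom", "pos", "class", "cobind")],
                 .data$factor, .data$cell_line, .data$chrom, .data$pos)
}

#' Emit replicate peak calls from binding truth
#'
#' Each truth site appears in each of the two replicates with probability
#' `1 - replicate_dropout`; the called summit is jittered
#' `Normal(0, summit_jitter_sd)` and the peak width drawn
#' `Normal(peak_width_mean, peak_width_sd)` (floor 100 bp). Each replicate
#' additionally carries `noise_peaks` replicate-private peaks at uniform
#' positions.
#'
#' @param truth tibble from [make_binding_truth()].
#' @param cfg a [scenario_config()].
#' @return Tibble of peaks with `factor`, `cell_line`, `replicate`, `chrom`,
#'   `start`, `end`, `summit`, `name`, `score`.
#' @export
emit_replicate_peaks <- function(truth, cfg) {
  withr::with_seed(cfg$seed + 2L, emit_replicate_peaks_impl(truth, cfg))
}

emit_replicate_peaks_impl <- function(truth, cfg) {
  lens <- cfg$chroms
  out <- list()
  groups <- dplyr::group_split(dplyr::group_by(truth, .data$factor, .data$cell_line))
  for (g in groups) {
    for (rep_i in 1:2) {
      keep <- runif(nrow(g)) >= cfg$replicate_dropout
      sub <- g[keep, , drop = FALSE]
      n_noise <- cfg$noise_peaks
      noise <- tibble::tibble(
        chrom = sample(names(lens), n_noise, replace = TRUE,
                       prob = lens / sum(lens)),
        pos = NA_integer_, class = "noise", cobind = "none",
        factor = g$factor[1L], cell_line = g$cell_line[1L])
      noise$pos <- floor(runif(n_noise) * lens[noise$chrom])
      sub <- dplyr::bind_rows(sub, noise)
      summit <- as.integer(round(sub$pos + rnorm(nrow(sub), 0, cfg$summit_jitter_sd)))
      width <- pmax(100L, as.integer(round(
        rnorm(nrow(sub), cfg$peak_width_mean, cfg$peak_width_sd))))
      start <- pmax(summit - width %/% 2L, 0L)
      end <- pmin(start + width, as.integer(lens[sub$chrom]))
      summit <- pmin(pmax(summit, start), end - 1L)
      out[[length(out) + 1L]] <- tibble::tibble(
        factor = sub$factor, cell_line = sub$cell_line, replicate = rep_i,
        chrom = sub$chrom, start = start, end = end, summit = summit,
        name = sprintf("%s_%s_rep%d_%d", sub$factor, sub$cell_line, rep_i,
                       seq_len(nrow(sub))),
        score = round(runif(nrow(sub), 50, 300), 1))
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$factor, .data$cell_line,
                 .data$replicate, .data$chrom, .data$start)
}

#' Built-in synthetic PWM collection
#'
#' A small constructed collection of position frequency matrices used by the
#' generator and examples: a CTCF-like GC-rich 14-mer, an ERE-like
#' palindrome with a 3-bp degenerate spacer, a forkhead-like 8-mer, plus two
#' short distractor motifs. These are synthetic stand-ins with the right
#' shapes (lengths, palindromy, information content), not curated database
#' matrices; the same collection ships as
#' `system.file("extdata", "motifs_synthetic.jaspar", package = "peakcobind")`.
#'
#' @return Named list of [pwm] objects.
#' @export
builtin_motifs <- function() {
  consensus_counts <- function(consensus, strong = 85, weak = 5) {
    b <- strsplit(consensus, "", fixed = TRUE)[[1L]]
    m <- matrix(weak, nrow = 4, ncol = length(b),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    uniform <- b == "N"
    m[, uniform] <- 25
    sel <- !uniform
    m[cbind(match(b[sel], rownames(m)), which(sel))] <- strong
    m
  }
  list(
    CTCF = pwm(consensus_counts("CCACCAGGGGGCGC"), "CTCF_like"),
    ER = pwm(consensus_counts("GGTCANNNTGACC"), "ERE_like"),
    FOXA1 = pwm(consensus_counts("TGTTTACA"), "FOXA1_like"),
    MYF = pwm(consensus_counts("CAGCTG"), "MYF_like"),
    AP1 = pwm(consensus_counts("TGACTCA"), "AP1_like")
  )
}

#' Plant motif instances near truth summits
#'
#' At rate `motif_plant_rate`, writes the consensus of the factor's motif
#' (CTCF-like at CTCF sites, ERE-like near ER sites, forkhead-like near
#' FOXA1 sites), on a random strand, centred within `±motif_offset_max` bp
#' of the site centre, overwriting the background bases. Sites shared across
#' lines are planted once. Instances that would extend past a chromosome end
#' are skipped and counted.
#'
#' @param genome named character vector from [make_genome()].
#' @param truth tibble from [make_binding_truth()].
#' @param cfg a [scenario_config()].
#' @param motifs named list of [pwm]s keyed by factor (default
#'   [builtin_motifs()]).
#' @return The modified genome; the planted instances are in
#'   `attr(, "planted")` (tibble: factor, chrom, start, strand) and the
#'   skipped count in `attr(, "skipped")`.
#' @export
plant_motifs <- function(genome, truth, cfg, motifs = builtin_motifs()) {
  withr::with_seed(cfg$seed + 3L, plant_motifs_impl(genome, truth, cfg, motifs))
}

plant_motifs_impl <- function(genome, truth, cfg, motifs) {
  raws <- lapply(genome, charToRaw)
  planted <- list()
  skipped <- 0L
  for (f in intersect(unique(truth$factor), names(motifs))) {
    sites <- dplyr::distinct(truth[truth$factor == f, c("chrom", "pos")])
    keep <- runif(nrow(sites)) < cfg$motif_plant_rate
    sites <- sites[keep, , drop = FALSE]
    if (nrow(sites) == 0L) next
    cons <- pwm_consensus(motifs[[f]])
    L <- nchar(cons)
    offs <- sample(-cfg$motif_offset_max:cfg$motif_offset_max, nrow(sites),
                   replace = TRUE)
    strands <- sample(c("+", "-"), nrow(sites), replace = TRUE)
    start <- sites$pos + offs - L %/% 2L
    lens <- nchar(genome)
    ok <- start >= 0L & start + L <= lens[sites$chrom]
    skipped <- skipped + sum(!ok)
    sites <- sites[ok, , drop = FALSE]
    start <- start[ok]
    strands <- strands[ok]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
    for (chr in unique(sites$chrom)) {
      sel <- sites$chrom == chr
      idx <- unlist(lapply(start[sel], function(s) s + seq_len(L)))
      seqs <- ifelse(strands[sel] == "+", cons, rc)
      val <- unlist(lapply(seqs, function(s) utf8ToInt(s)))
      raws[[chr]][idx] <- as.raw(val)
    }
    planted[[length(planted) + 1L]] <- tibble::tibble(
      factor = f, chrom = sites$chrom, start = as.integer(start),
      strand = strands)
  }
  out <- setNames(vapply(raws, rawToChar, character(1)), names(genome))
  attr(out, "planted") <- dplyr::bind_rows(planted)
  attr(out, "skipped") <- skipped
  out
}

#' Simulate ChIP and input read tracks
#'
#' Treatment reads mix `Normal(site centre, read_spread_sd)` pileups around
#' the factor/line's truth sites with uniform background at the configured
#' signal-to-background ratio; the shared input library is uniform only.
#' Every library has exactly `reads_per_library` reads.
#'
#' @param truth tibble from [make_binding_truth()].
#' @param cfg a [scenario_config()].
#' @return Named list of read tibbles (`chrom`, `pos`), one per
#'   `<factor>_<cell_line>` plus `"input"`.
#' @export
simulate_reads <- function(truth, cfg) {
  withr::with_seed(cfg$seed + 4L, simulate_reads_impl(truth, cfg))
}

simulate_reads_impl <- function(truth, cfg) {
  lens <- cfg$chroms
  n <- cfg$reads_per_library
  uniform_reads <- function(k) {
    chrom <- sample(names(lens), k, replace = TRUE, prob = lens / sum(lens))
    tibble::tibble(chrom = chrom, pos = as.integer(floor(runif(k) * lens[chrom])))
  }
  out <- list()
  groups <- dplyr::group_split(dplyr::group_by(truth, .data$factor, .data$cell_line))
  for (g in groups) {
    p_sig <- cfg$signal_to_background / (1 + cfg$signal_to_background)
    n_sig <- stats::rbinom(1L, n, p_sig)
    site <- g[sample.int(nrow(g), n_sig, replace = TRUE), , drop = FALSE]
    pos <- as.integer(round(site$pos + rnorm(n_sig, 0, cfg$read_spread_sd)))
    pos <- pmin(pmax(pos, 0L), as.integer(lens[site$chrom]) - 1L)
    reads <- dplyr::bind_rows(tibble::tibble(chrom = site$chrom, pos = pos),
                              uniform_reads(n - n_sig))
    out[[paste0(g$factor[1L], "_", g$cell_line[1L])]] <-
      dplyr::arrange(reads, .data$chrom, .data$pos)
  }
  out$input <- dplyr::arrange(uniform_reads(n), .data$chrom, .data$pos)
  out
}

#' Write a read tibble as a BED file of 5' starts
#'
#' @param reads tibble with `chrom`, `pos`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_bed <- function(reads, path) {
  readr::write_lines(sprintf("%s\t%d\t%d", reads$chrom, reads$pos,
                             reads$pos + 1L), path)
  invisible(path)
}

#' Simulate gene models, expression, and regulated-gene labels
#'
#' Places `n_genes` TSSs uniformly (random strand, 2-20 kb bodies with
#' simple exon structure). For each cell line, genes with a TSS within 20 kb
#' of that line's specific CTCF truth sites become DE in that line with
#' probability `de_near_prob` (others `de_background_prob`), with a
#' `±de_effect` log2 shift; replicate noise is
#' `Normal(0, expression_noise_sd)` around a `Normal(8, 1)` baseline.
#' "Estrogen up/down" labels are assigned preferentially (`reg_near_prob`
#' vs `reg_background_prob`) to genes near ER-and-CTCF co-bound truth sites
#' of the first ER-positive line.
#'
#' @param truth tibble from [make_binding_truth()].
#' @param cfg a [scenario_config()].
#' @return List with `genes` (gene-model tibble), `expression` (an
#'   [expression_table]), `de_truth` (gene x line logical matrix) and
#'   `regulated` (tibble `gene_id`, `regulation`).
#' @export
simulate_genes_and_expression <- function(truth, cfg) {
  withr::with_seed(cfg$seed + 5L, simulate_expression_impl(truth, cfg))
}

simulate_expression_impl <- function(truth, cfg) {
  lens <- cfg$chroms
  n <- cfg$n_genes
  chrom <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
  tss <- as.integer(floor(runif(n) * (lens[chrom] - 40000)) + 20000)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  body <- as.integer(round(runif(n, 2000, 20000)))
  start <- ifelse(strand == "+", tss, pmax(tss - body + 1L, 0L))
  end <- ifelse(strand == "+", tss + body, tss + 1L)
  exons <- lapply(seq_len(n), function(i) {
    k <- sample(2:4, 1L)
    gaps <- (end[i] - start[i]) %/% k
    es <- start[i] + (0:(k - 1L)) * gaps
    cbind(start = es, end = pmin(es + 150L, end[i]))
  })
  genes <- tibble::tibble(
    gene_id = sprintf("gene%04d", seq_len(n)), chrom = chrom,
    strand = strand, tss = tss, start = as.integer(start),
    end = as.integer(end), exons = exons)

  near_line_sites <- function(L) {
    sites <- truth[truth$factor == "CTCF" & truth$cell_line == L &
                     truth$class == paste0(L, "_specific"), , drop = FALSE]
    tss_near_sites(genes, sites, 20000)
  }
  de_truth <- sapply(cfg$lines, function(L) {
    near <- near_line_sites(L)
    runif(n) < ifelse(near, cfg$de_near_prob, cfg$de_background_prob)
  })
  shift_sign <- matrix(sample(c(-1, 1), n * length(cfg$lines), replace = TRUE),
                       nrow = n)
  baseline <- rnorm(n, 8, 1)
  samples <- tidyr::expand_grid(cell_line = cfg$lines,
                                replicate = seq_len(cfg$n_reps))
  samples$sample_id <- paste0(samples$cell_line, "_", samples$replicate)
  values <- matrix(0, nrow = n, ncol = nrow(samples),
                   dimnames = list(genes$gene_id, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    li <- match(samples$cell_line[j], cfg$lines)
    shift <- ifelse(de_truth[, li], shift_sign[, li] * cfg$de_effect, 0)
    values[, j] <- baseline + shift + rnorm(n, 0, cfg$expression_noise_sd)
  }
  expr <- expression_table(values, samples[, c("sample_id", "cell_line", "replicate")])

  er_line <- cfg$er_lines[1L]
  er_ctcf <- truth[truth$factor == "CTCF" & truth$cell_line == er_line &
                     truth$cobind %in% c("ER", "both"), , drop = FALSE]
  near_er <- tss_near_sites(genes, er_ctcf, 20000)
  is_reg <- runif(n) < ifelse(near_er, cfg$reg_near_prob, cfg$reg_background_prob)
  regulated <- tibble::tibble(
    gene_id = genes$gene_id[is_reg],
    regulation = sample(c("up", "down"), sum(is_reg), replace = TRUE))
  list(genes = genes, expression = expr, de_truth = de_truth,
       regulated = regulated)
}

# logical per gene: TSS within `window` bp of any site centre
tss_near_sites <- function(genes, sites, window) {
  if (nrow(sites) == 0L) return(rep(FALSE, nrow(genes)))
  out <- rep(FALSE, nrow(genes))
  for (chr in unique(genes$chrom)) {
    gi <- which(genes$chrom == chr)
    sp <- sort(sites$pos[sites$chrom == chr])
    if (length(sp) == 0L) next
    idx <- findInterval(genes$tss[gi], sp)
    d_lo <- ifelse(idx > 0L, genes$tss[gi] - sp[pmax(idx, 1L)], Inf)
    d_hi <- ifelse(idx < length(sp), sp[pmin(idx + 1L, length(sp))] - genes$tss[gi], Inf)
    out[gi] <- pmin(d_lo, d_hi) <= window
  }
  out
}

#' Run the full synthetic-data generator and write every input file
#'
#' Generates genome (with planted motifs), truth, replicate peak BEDs, read
#' BEDs, gene models, expression table and regulated-gene labels under
#' `dir`, all deterministically from `cfg$seed`.
#'
#' @param cfg a [scenario_config()].
#' @param dir output directory (created if needed).
#' @return List of class `scenario` with the in-memory objects (`genome`,
#'   `truth`, `peaks`, `reads`, `genes`, `expression`, `regulated`,
#'   `de_truth`) and a `paths` list of every file written.
#' @export
simulate_scenario <- function(cfg = scenario_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "reads"), showWarnings = FALSE)
  truth <- make_binding_truth(cfg)
  genome <- make_genome(cfg)
  genome <- plant_motifs(genome, truth, cfg)
  peaks <- emit_replicate_peaks(truth, cfg)
  reads <- simulate_reads(truth, cfg)
  ge <- simulate_genes_and_expression(truth, cfg)

  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    chrom_sizes = file.path(dir, "genome.chrom.sizes"),
    genes = file.path(dir, "genes.bed"),
    expression = file.path(dir, "expression.tsv"),
    regulated = file.path(dir, "regulated_genes.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_genome(genome, paths$fasta, paths$chrom_sizes)
  write_gene_models(ge$genes, paths$genes)
  write_expression(ge$expression, paths$expression)
  readr::write_tsv(ge$regulated, paths$regulated, progress = FALSE)
  readr::write_tsv(truth, paths$truth, progress = FALSE)

  paths$peaks <- list()
  for (g in dplyr::group_split(dplyr::group_by(peaks, .data$factor,
                                               .data$cell_line, .data$replicate))) {
    key <- sprintf("%s_%s_rep%d", g$factor[1L], g$cell_line[1L], g$replicate[1L])
    p <- file.path(dir, "peaks", paste0(key, ".bed"))
    write_bed(as_peak_tbl(g, label = key), p)
    paths$peaks[[key]] <- p
  }
  paths$reads <- list()
  for (key in names(reads)) {
    p <- file.path(dir, "reads", paste0(key, ".bed"))
    write_reads_bed(reads[[key]], p)
    paths$reads[[key]] <- p
  }
  structure(list(config = cfg, genome = genome, truth = truth, peaks = peaks,
                 reads = reads, genes = ge$genes, expression = ge$expression,
                 de_truth = ge$de_truth, regulated = ge$regulated,
                 paths = paths),
            class = "scenario")
}
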