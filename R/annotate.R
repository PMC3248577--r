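#' Read gene models from a BED-like TSV
#'
#' Expects at least 6 tab-separated columns (`chrom`, `start`, `end`,
#' `gene_id`, `score`, `strand`); when 12 BED-style columns are present,
#' columns 11 and 12 (comma-separated block sizes and starts) provide exon
#' structure. The TSS is `start` for `+` genes and `end - 1` for `-` genes
#' (0-based).
#'
#' @param path path to the gene model file (no header).
#' @return Tibble with `gene_id`, `chrom`, `strand`, `tss`, `start`, `end`
#'   and an `exons` list-column (each element a two-column matrix of
#'   0-based half-open exon intervals, or `NULL`).
#' @export
read_gene_models <- function(path) {
  # everything as character first: comma-separated block lists must not be
  # mistaken for grouped numbers
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                       progress = FALSE,
                       col_types = readr::cols(.default = "c"))
  if (ncol(x) < 6L) abort(sprintf("gene model file %s needs >= 6 columns", path))
  genes <- tibble::tibble(
    gene_id = as.character(x[[4L]]),
    chrom = as.character(x[[1L]]),
    strand = as.character(x[[6L]]),
    start = as.integer(x[[2L]]),
    end = as.integer(x[[3L]])
  )
  if (!all(genes$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$exons <- if (ncol(x) >= 12L) {
    purrr::pmap(list(x[[11L]], x[[12L]], genes$start), function(sz, st, g0) {
      if (is.na(sz) || sz == "." || sz == "") return(NULL)
      sizes <- as.integer(strsplit(sz, ",")[[1L]])
      starts <- as.integer(strsplit(st, ",")[[1L]])
      cbind(start = g0 + starts, end = g0 + starts + sizes)
    })
  } else {
    rep(list(NULL), nrow(genes))
  }
  genes[, c("gene_id", "chrom", "strand", "tss", "start", "end", "exons")]
}

#' Write gene models as BED12-style TSV
#'
#' Inverse of [read_gene_models()] (score fixed at 0; thickStart/thickEnd
#' mirror the span; itemRgb `"0"`).
#'
#' @param genes gene-model tibble.
#' @param path output path.
#' @return The input, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  has_exons <- !vapply(genes$exons %||% rep(list(NULL), nrow(genes)), is.null,
                       logical(1))
  fmt_exons <- function(e, g0) {
    if (is.null(e)) return(c("1", "", ""))
    c(as.character(nrow(e)),
      paste0(paste(e[, 2] - e[, 1], collapse = ","), ","),
      paste0(paste(e[, 1] - g0, collapse = ","), ","))
  }
  blocks <- mapply(fmt_exons, genes$exons, genes$start)
  n <- nrow(genes)
  if (any(has_exons)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%s\t%s\t%s",
                     genes$chrom, genes$start, genes$end, genes$gene_id,
                     genes$strand, genes$start, genes$end,
                     blocks[1, ], blocks[2, ], blocks[3, ])
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chrom, genes$start,
                     genes$end, genes$gene_id, genes$strand)
  }
  readr::write_lines(lines, path)
  invisible(genes)
}

#' Classify peaks as promoter / exonic / intronic / intergenic
#'
#' Each peak is represented by a single anchor point (its summit, or its
#' midpoint when no summit is recorded) so that the four categories form an
#' exact partition. Priority order: promoter (anchor within `promoter_bp` of
#' any TSS, either side), then exonic, then intronic (inside a gene span but
#' outside annotated exons; genes without exon annotation count their whole
#' body as intronic), else intergenic.
#'
#' @param peaks a peak table.
#' @param genes gene-model tibble from [read_gene_models()].
#' @param promoter_bp promoter radius around the TSS in bp (default 1000).
#' @return The peak table with added `location` factor column and a logical
#'   `promoter_upstream` column (anchor within `promoter_bp` upstream of a
#'   TSS, strand-aware) for the upstream-only statistic.
#' @export
classify_peak_location <- function(peaks, genes, promoter_bp = 1000) {
  anchor <- ifelse(is.na(peaks$summit), (peaks$start + peaks$end) %/% 2L,
                   peaks$summit)
  lv <- union(unique(peaks$chrom), unique(genes$chrom))
  anchor_gr <- GenomicRanges::GRanges(factor(peaks$chrom, levels = lv),
                                      IRanges::IRanges(anchor + 1L, width = 1L))
  if (nrow(genes) > 0L) {
    prom_gr <- GenomicRanges::GRanges(
      factor(genes$chrom, levels = lv),
      IRanges::IRanges(pmax(genes$tss - promoter_bp, 0L) + 1L,
                       genes$tss + promoter_bp + 1L))
    up_start <- ifelse(genes$strand == "+", genes$tss - promoter_bp, genes$tss)
    up_end <- ifelse(genes$strand == "+", genes$tss, genes$tss + promoter_bp)
    up_gr <- GenomicRanges::GRanges(
      factor(genes$chrom, levels = lv),
      IRanges::IRanges(pmax(up_start, 0L) + 1L, up_end + 1L))
    span_gr <- GenomicRanges::GRanges(
      factor(genes$chrom, levels = lv),
      IRanges::IRanges(genes$start + 1L, genes$end))
    exon_list <- purrr::compact(purrr::map2(genes$exons, genes$chrom, function(e, chr) {
      if (is.null(e)) return(NULL)
      GenomicRanges::GRanges(factor(rep(chr, nrow(e)), levels = lv),
                             IRanges::IRanges(e[, 1] + 1L, e[, 2]))
    }))
    exon_gr <- if (length(exon_list)) do.call(c, exon_list) else
      GenomicRanges::GRanges()
    in_prom <- IRanges::overlapsAny(anchor_gr, prom_gr)
    in_up <- IRanges::overlapsAny(anchor_gr, up_gr)
    in_gene <- IRanges::overlapsAny(anchor_gr, span_gr)
    in_exon <- if (length(exon_gr)) IRanges::overlapsAny(anchor_gr, exon_gr) else
      rep(FALSE, nrow(peaks))
  } else {
    in_prom <- in_up <- in_gene <- in_exon <- rep(FALSE, nrow(peaks))
  }
  location <- dplyr::case_when(
    in_prom ~ "promoter",
    in_gene & in_exon ~ "exonic",
    in_gene ~ "intronic",
    TRUE ~ "intergenic"
  )
  out <- peaks
  out$location <- factor(location,
                         levels = c("promoter", "exonic", "intronic", "intergenic"))
  out$promoter_upstream <- in_up
  out
}

#' Genomic distribution of a peak set
#'
#' Percentage of peaks per location category (an exact partition; the
#' percentages sum to 100). The strand-aware upstream-only promoter
#' percentage — peaks whose anchor lies within `promoter_bp` upstream of a
#' TSS — is reported alongside, since promoter proximity is quoted both ways
#' in the literature.
#'
#' @inheritParams classify_peak_location
#' @return Tibble of class `location_breakdown` with `category`, `n`,
#'   `percent`; the upstream-only percentage is in
#'   `attr(, "promoter_upstream_percent")`.
#' @export
genomic_distribution <- function(peaks, genes, promoter_bp = 1000) {
  if (nrow(peaks) == 0L) abort("empty peak set")
  cls <- classify_peak_location(peaks, genes, promoter_bp)
  out <- dplyr::count(tibble::as_tibble(cls), category = .data$location,
                      .drop = FALSE)
  out$percent <- 100 * out$n / sum(out$n)
  attr(out, "promoter_upstream_percent") <-
    100 * sum(cls$promoter_upstream) / nrow(peaks)
  class(out) <- c("location_breakdown", class(out))
  out
}

#' Bar plot of a genomic location breakdown
#'
#' @param object a `location_breakdown`.
#' @param ... unused.
#' @return A ggplot bar chart of category percentages.
#' @method autoplot location_breakdown
#' @export
autoplot.location_breakdown <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$category, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "% of peaks")
}
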