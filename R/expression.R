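#' Construct an expression table
#'
#' Holds a genes x samples matrix of log2 expression values together with the
#' sample-to-cell-line/replicate mapping.
#'
#' @param values numeric matrix (genes x samples) with gene ids as rownames.
#' @param samples tibble with `sample_id`, `cell_line`, `replicate` (one row
#'   per matrix column, in column order).
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(values, samples) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) abort("values must have gene ids as rownames")
  if (nrow(samples) != ncol(values)) {
    abort("samples must have one row per expression column")
  }
  if (anyNA(values)) abort("expression values must not contain NA")
  structure(list(values = values, samples = tibble::as_tibble(samples),
                 genes = rownames(values)),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$samples$cell_line), collapse = ", ")))
  invisible(x)
}

#' Read an expression TSV
#'
#' First column `gene_id`; remaining column names encode the sample as
#' `<cell_line>_<replicate>` (the last underscore splits the two).
#'
#' @param path path to the TSV (with header).
#' @return An [expression_table].
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(x[[1L]])
  mat <- as.matrix(x[, -1L, drop = FALSE])
  rownames(mat) <- ids
  nm <- colnames(mat)
  samples <- tibble::tibble(
    sample_id = nm,
    cell_line = sub("_[^_]*$", "", nm),
    replicate = sub("^.*_", "", nm)
  )
  expression_table(mat, samples)
}

#' Write an expression table as TSV
#'
#' @param expr an [expression_table].
#' @param path output path.
#' @return The input, invisibly.
#' @export
write_expression <- function(expr, path) {
  out <- tibble::as_tibble(expr$values, .name_repair = "minimal")
  names(out) <- expr$samples$sample_id
  out <- dplyr::bind_cols(tibble::tibble(gene_id = expr$genes), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(expr)
}

#' Per-gene two-sample differential expression (Welch t)
#'
#' Welch's unequal-variance t-test on log2 values per gene, two-sided, with
#' Benjamini-Hochberg adjustment across genes. Direction is the sign of
#' `mean(lineA) - mean(lineB)`. Genes with zero variance in both groups and
#' equal means get p = 1; zero pooled variance with unequal means gives
#' p = 0 (an infinite t).
#'
#' @param expr an [expression_table].
#' @param lineA,lineB cell-line names to contrast (>= 2 replicates each).
#' @return Tibble with `gene_id`, `estimate` (log2 A - B), `statistic`, `df`,
#'   `p_value`, `adjusted_p`, `direction`.
#' @export
de_test <- function(expr, lineA, lineB) {
  ia <- which(expr$samples$cell_line == lineA)
  ib <- which(expr$samples$cell_line == lineB)
  if (length(ia) < 2L || length(ib) < 2L) {
    abort("each contrasted line needs >= 2 replicates")
  }
  xa <- expr$values[, ia, drop = FALSE]
  xb <- expr$values[, ib, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  est <- ma - mb
  stat <- est / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(stat), df, lower.tail = FALSE)
  p[se2 == 0 & est == 0] <- 1
  p[se2 == 0 & est != 0] <- 0
  tibble::tibble(
    gene_id = expr$genes,
    estimate = unname(est),
    statistic = unname(stat),
    df = unname(df),
    p_value = unname(p),
    adjusted_p = bh_adjust(unname(p)),
    direction = ifelse(est >= 0, "up", "down")
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (input order preserved, capped at 1).
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Cell-line candidate DE genes
#'
#' Genes differentially expressed in line L against both other lines
#' (p < `alpha` in both L contrasts) but not between the other two lines
#' (p >= `alpha`). The default filters on raw p-values: without the
#' variance moderation of an empirical-Bayes caller, a BH-adjusted 0.01
#' cutoff at 3 replicates has very little power (the Welch t has ~4 degrees
#' of freedom), whereas the raw cutoff recovers planted effects at the
#' intended rate while the double-contrast requirement keeps false
#' candidates rare; set `use_adjusted = TRUE` for the FDR-controlled
#' variant.
#'
#' @param de_la,de_lb DE result tibbles for L vs A and L vs B ([de_test()]).
#' @param de_ab DE result tibble for A vs B.
#' @param alpha significance threshold (default 0.01).
#' @param use_adjusted filter on BH-adjusted instead of raw p.
#' @return Character vector of gene ids.
#' @export
candidate_de_genes <- function(de_la, de_lb, de_ab, alpha = 0.01,
                               use_adjusted = FALSE) {
  u <- de_la$gene_id
  if (!setequal(u, de_lb$gene_id) || !setequal(u, de_ab$gene_id)) {
    abort("the three contrasts must cover the same gene universe")
  }
  col <- if (use_adjusted) "adjusted_p" else "p_value"
  pick <- function(d) setNames(d[[col]], d$gene_id)[u]
  u[pick(de_la) < alpha & pick(de_lb) < alpha & pick(de_ab) >= alpha]
}

#' Genes with a binding event near their TSS
#'
#' A gene is reported when any peak interval intersects
#' `[tss - window, tss + window)` by at least one base pair.
#'
#' @param peaks a peak table.
#' @param genes gene-model tibble.
#' @param window half-width of the TSS window in bp (default 20000).
#' @return Character vector of gene ids (unique, in input gene order).
#' @export
genes_near_peaks <- function(peaks, genes, window = 20000) {
  if (nrow(peaks) == 0L || nrow(genes) == 0L) return(character(0))
  lv <- union(unique(genes$chrom), unique(peaks$chrom))
  win_gr <- GenomicRanges::GRanges(
    factor(genes$chrom, levels = lv),
    IRanges::IRanges(pmax(genes$tss - window, 0L) + 1L, genes$tss + window))
  hit <- IRanges::overlapsAny(win_gr, peaks_to_gr(peaks, lv), minoverlap = 1L)
  unique(genes$gene_id[hit])
}

#' Fisher's exact enrichment of DE genes near binding sites
#'
#' Builds the 2 x 2 table (DE / not-DE) x (near / not-near) over the gene
#' universe and tests over-representation with a two-sided Fisher's exact
#' test (minimum-likelihood summation, as in `fisher.test`). Use
#' `alternative = "greater"` when the question is over-representation only:
#' a candidate list built by excluding genes DE elsewhere is systematically
#' *depleted* near other lines' specific peaks, and a two-sided test flags
#' that depletion as significance. The reported odds ratio is the sample
#' odds ratio `(a d) / (b c)`; when any cell is zero, 0.5 is added to every
#' cell for the odds ratio only and the result is flagged.
#'
#' @param de_genes,near_genes character vectors, subsets of `universe`.
#' @param universe character vector of all genes considered.
#' @param alternative `"two.sided"` (default) or `"greater"` (enrichment
#'   only).
#' @return One-row tibble with the table cells (`de_near`, `de_far`,
#'   `other_near`, `other_far`), `odds_ratio`, `p_value` and `continuity`
#'   (whether 0.5 was added for the OR).
#' @export
fisher_enrichment <- function(de_genes, near_genes, universe,
                              alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (length(universe) == 0L) abort("empty gene universe")
  if (!all(de_genes %in% universe) || !all(near_genes %in% universe)) {
    abort("de_genes and near_genes must be subsets of the universe")
  }
  de <- universe %in% de_genes
  near <- universe %in% near_genes
  a <- sum(de & near); b <- sum(de & !near)
  cc <- sum(!de & near); d <- sum(!de & !near)
  tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE)
  p <- fisher.test(tab, alternative = alternative)$p.value
  continuity <- any(tab == 0)
  orr <- if (continuity) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  tibble::tibble(de_near = a, de_far = b, other_near = cc, other_far = d,
                 odds_ratio = orr, p_value = p, continuity = continuity)
}

#' Percentage of peaks near a gene set
#'
#' Fraction of peaks intersecting the `[tss - window, tss + window)` window
#' of at least one gene in `gene_set`, as a percentage.
#'
#' @param peaks non-empty peak table.
#' @param gene_set character vector of gene ids.
#' @param genes gene-model tibble.
#' @param window half-width in bp (default 20000).
#' @return Percentage in `[0, 100]`.
#' @export
peak_proximity_fraction <- function(peaks, gene_set, genes, window = 20000) {
  if (nrow(peaks) == 0L) abort("empty peak set")
  sel <- genes[genes$gene_id %in% gene_set, , drop = FALSE]
  if (nrow(sel) == 0L) return(0)
  lv <- union(unique(sel$chrom), unique(peaks$chrom))
  win_gr <- GenomicRanges::GRanges(
    factor(sel$chrom, levels = lv),
    IRanges::IRanges(pmax(sel$tss - window, 0L) + 1L, sel$tss + window))
  100 * sum(IRanges::overlapsAny(peaks_to_gr(peaks, lv), win_gr,
                                 minoverlap = 1L)) / nrow(peaks)
}

#' Chi-squared comparison of two proportions
#'
#' Pearson chi-squared on the 2 x 2 table of `k` successes out of `n` per
#' group, without continuity correction (1 df, two-sided).
#'
#' @param k1,n1,k2,n2 successes and totals of the two groups.
#' @return One-row tibble with `statistic`, `p_value`, `prop1`, `prop2`.
#' @export
compare_proportions <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  obs <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (any(expd == 0)) {
    abort("a zero expected cell: use Fisher's exact test instead")
  }
  stat <- sum((obs - expd)^2 / expd)
  tibble::tibble(statistic = stat,
                 p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 prop1 = k1 / n1, prop2 = k2 / n2)
}
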