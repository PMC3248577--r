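#' Construct a peak table
#'
#' A peak table is a tibble with one row per called binding event and columns
#' `chrom`, `start`, `end` (0-based half-open, BED convention), plus optional
#' `name`, `score` and `summit` (absolute 0-based position). All interval
#' functions in the package take and return peak tables sorted by
#' `(chrom, start, end)`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; `start < end` required.
#' @param name,score,summit optional per-peak annotation; `summit` is an
#'   absolute position with `start <= summit < end`.
#' @param label optional label for the whole set (factor/cell line/replicate),
#'   stored as the `"label"` attribute.
#' @return A sorted tibble of class `peak_tbl`.
#' @export
#' @examples
#' peak_tbl("chr1", c(100L, 500L), c(200L, 900L), summit = c(150L, NA))
peak_tbl <- function(chrom, start, end, name = NA_character_,
                     score = NA_real_, summit = NA_integer_, label = NULL) {
  x <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    name = as.character(name),
    score = as.double(score),
    summit = as.integer(summit)
  )
  validate_peaks(x)
  x <- dplyr::arrange(x, .data$chrom, .data$start, .data$end)
  class(x) <- c("peak_tbl", class(tibble::tibble()))
  attr(x, "label") <- label
  x
}

as_peak_tbl <- function(x, label = attr(x, "label")) {
  stopifnot(is.data.frame(x))
  for (col in c("name", "score", "summit")) {
    if (is.null(x[[col]])) {
      x[[col]] <- switch(col, name = NA_character_, score = NA_real_,
                         summit = NA_integer_)
    }
  }
  peak_tbl(x$chrom, x$start, x$end, x$name, x$score, x$summit, label = label)
}

validate_peaks <- function(x) {
  if (nrow(x) == 0L) return(invisible(x))
  bad <- which(!(x$start >= 0L & x$start < x$end))
  if (length(bad) > 0L) {
    abort(sprintf("invalid interval (need 0 <= start < end) in row(s): %s",
                  paste(head(bad, 5L), collapse = ", ")))
  }
  has_summit <- !is.na(x$summit)
  bad <- which(has_summit & !(x$summit >= x$start & x$summit < x$end))
  if (length(bad) > 0L) {
    abort(sprintf("summit outside [start, end) in row(s): %s",
                  paste(head(bad, 5L), collapse = ", ")))
  }
  invisible(x)
}

# 0-based half-open peak tibble -> GRanges (1-based closed); a shared
# seqlevel universe avoids spurious warnings when chromosome sets differ
peaks_to_gr <- function(x, levels = unique(x$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(x$chrom, levels = levels),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# logical per row of `a`: does it share >= 1 bp with any interval of `b`?
overlap_any <- function(a, b) {
  if (nrow(a) == 0L) return(logical(0))
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  lv <- union(unique(a$chrom), unique(b$chrom))
  IRanges::overlapsAny(peaks_to_gr(a, lv), peaks_to_gr(b, lv), minoverlap = 1L)
}

#' Read a peak file
#'
#' Reads BED (3+ columns, 0-based half-open) or MACS-style tabular peak files
#' (header `chr start end length summit tags -10*log10(pvalue)
#' fold_enrichment FDR(%)`, 1-based inclusive coordinates, summit given as an
#' offset relative to start). MACS coordinates are converted to the internal
#' 0-based half-open convention and the summit to an absolute position.
#'
#' @param path path to the peak file.
#' @param format `"bed"` or `"macs_tab"`.
#' @param label optional set label.
#' @return A [peak_tbl] sorted by `(chrom, start, end)`.
#' @export
read_peaks <- function(path, format = c("bed", "macs_tab"), label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("peak file not found: %s", path))
  if (format == "bed") {
    lines <- readr::read_lines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) return(peak_tbl(character(), integer(), integer(), label = label))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L)) {
      abort(sprintf("malformed BED line %d in %s: fewer than 3 columns",
                    which(nf < 3L)[1L], path))
    }
    chrom <- vapply(fields, `[[`, character(1), 1L)
    start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
    if (anyNA(start) || anyNA(end)) {
      abort(sprintf("malformed BED line %d in %s: non-integer coordinate",
                    which(is.na(start) | is.na(end))[1L], path))
    }
    name <- if (all(nf >= 4L)) vapply(fields, `[[`, character(1), 4L) else NA_character_
    score <- if (all(nf >= 5L)) {
      suppressWarnings(as.double(vapply(fields, `[[`, character(1), 5L)))
    } else NA_real_
    bad <- which(start >= end)
    if (length(bad) > 0L) {
      abort(sprintf("invalid interval (start >= end) at line %d of %s", bad[1L], path))
    }
    return(peak_tbl(chrom, start, end, name = name, score = score, label = label))
  }
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  names(x) <- tolower(names(x))
  need <- c("chr", "start", "end", "summit")
  if (!all(need %in% names(x))) {
    abort(sprintf("macs_tab file %s lacks required column(s): %s", path,
                  paste(setdiff(need, names(x)), collapse = ", ")))
  }
  start0 <- as.integer(x$start) - 1L
  bad <- which(start0 >= as.integer(x$end))
  if (length(bad) > 0L) {
    abort(sprintf("invalid interval (start >= end) at data line %d of %s",
                  bad[1L], path))
  }
  score <- if ("-10*log10(pvalue)" %in% names(x)) as.double(x[["-10*log10(pvalue)"]]) else NA_real_
  peak_tbl(x$chr, start0, as.integer(x$end),
           summit = start0 + as.integer(x$summit), score = score, label = label)
}

#' Do two peaks overlap by at least one base pair?
#'
#' Vectorised over rows (shorter input recycled). Two intervals overlap iff
#' they are on the same chromosome and share at least 1 bp under the
#' half-open convention.
#'
#' @param a,b peak tables (single rows or equal-length).
#' @return Logical vector.
#' @export
peaks_overlap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (n == 0L) return(logical(0))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ai] == b$chrom[bi] &
    pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi]) >= 1L
}

#' Replicate-consensus peaks
#'
#' A binding region is replicate-consistent when it occurs in both biological
#' replicates, overlapping by at least one base pair. The returned intervals
#' are those of `rep1` (the anchor replicate) by default; `keep = "union"`
#' instead merges each overlapping replicate pair into its union interval
#' (the count can then differ, which is why both are exposed).
#'
#' @param rep1,rep2 peak tables for the two replicates.
#' @param keep `"rep1"` (anchor intervals, default) or `"union"`.
#' @return A [peak_tbl] of consensus peaks.
#' @export
consensus_replicates <- function(rep1, rep2, keep = c("rep1", "union")) {
  keep <- match.arg(keep)
  hit <- overlap_any(rep1, rep2)
  anchored <- as_peak_tbl(rep1[hit, , drop = FALSE], label = attr(rep1, "label"))
  if (keep == "rep1") return(anchored)
  gr1 <- peaks_to_gr(anchored)
  gr2 <- peaks_to_gr(rep2)
  ov <- GenomicRanges::findOverlaps(gr1, gr2, minoverlap = 1L)
  pieces <- GenomicRanges::punion(gr1[S4Vectors_queryHits(ov)],
                                  gr2[S4Vectors_subjectHits(ov)], fill.gap = TRUE)
  merged <- GenomicRanges::reduce(pieces)
  peak_tbl(as.character(GenomicRanges::seqnames(merged)),
           GenomicRanges::start(merged) - 1L,
           GenomicRanges::end(merged),
           label = attr(rep1, "label"))
}

S4Vectors_queryHits <- function(x) methods::slot(x, "from")
S4Vectors_subjectHits <- function(x) methods::slot(x, "to")

#' Classify co-binding of an anchor factor with two partners
#'
#' Assigns every anchor (CTCF) consensus peak to exactly one of four
#' categories by presence/absence of a >= 1 bp overlap with the ER set and
#' with the FOXA1 set: `CTCF_ER_FOXA1`, `CTCF_ER`, `CTCF_FOXA1`, `CTCF_only`.
#' The categories partition the anchor set.
#'
#' @param ctcf anchor peak table (replicate consensus).
#' @param er,foxa1 partner peak tables (replicate consensus).
#' @return The anchor table with an added `category` factor column; category
#'   counts are available via [cobind_counts()] or `dplyr::count()`.
#' @export
classify_cobinding <- function(ctcf, er, foxa1) {
  in_er <- overlap_any(ctcf, er)
  in_fox <- overlap_any(ctcf, foxa1)
  category <- dplyr::case_when(
    in_er & in_fox ~ "CTCF_ER_FOXA1",
    in_er ~ "CTCF_ER",
    in_fox ~ "CTCF_FOXA1",
    TRUE ~ "CTCF_only"
  )
  out <- ctcf
  out$category <- factor(category, levels = cobind_levels())
  class(out) <- c("cobind_tbl", class(out))
  out
}

cobind_levels <- function() c("CTCF_ER_FOXA1", "CTCF_ER", "CTCF_FOXA1", "CTCF_only")

#' Category counts for a co-binding classification
#'
#' @param x result of [classify_cobinding()].
#' @return Tibble with `category`, `n` and `percent` (of all anchor peaks).
#' @export
cobind_counts <- function(x) {
  out <- dplyr::count(tibble::as_tibble(x), .data$category, .drop = FALSE)
  out$percent <- if (sum(out$n) > 0) 100 * out$n / sum(out$n) else 0
  out
}

#' Cell-line specific, shared and common peaks
#'
#' A cell-line specific binding event is a peak identified in both replicates
#' of that cell line and in neither replicate of any other cell line.
#' "Common" peaks are consensus peaks of the reference line overlapping at
#' least one peak of both replicates of every other line; peaks shared by a
#' proper subset of lines overlap both replicates of every other line in the
#' subset and no replicate outside it. Intervals are anchored on the first
#' line of each class (the reference line for `common`).
#'
#' @param peaks a tibble of peaks with `chrom`, `start`, `end` plus
#'   `cell_line` and `replicate` columns (exactly 2 replicates per line).
#' @param reference the anchor line for the `common` class (default: first).
#' @return Tibble of peaks with a `class` column (`<line>_specific`,
#'   `shared_<A>_<B>`, or `common`).
#' @export
cell_line_specificity <- function(peaks, reference = NULL) {
  stopifnot(all(c("chrom", "start", "end", "cell_line", "replicate") %in% names(peaks)))
  lines <- unique(peaks$cell_line)
  if (length(lines) < 2L) abort("need at least 2 cell lines")
  reps <- lapply(setNames(lines, lines), function(L) {
    sub <- peaks[peaks$cell_line == L, , drop = FALSE]
    rr <- sort(unique(sub$replicate))
    if (length(rr) != 2L) {
      abort(sprintf("cell line %s must have exactly 2 replicates, found %d",
                    L, length(rr)))
    }
    lapply(rr, function(r) as_peak_tbl(sub[sub$replicate == r, , drop = FALSE]))
  })
  cons <- lapply(reps, function(r) consensus_replicates(r[[1L]], r[[2L]]))
  if (is.null(reference)) reference <- lines[1L]
  stopifnot(reference %in% lines)

  in_both_reps <- function(anchor, L) {
    overlap_any(anchor, reps[[L]][[1L]]) & overlap_any(anchor, reps[[L]][[2L]])
  }
  in_any_rep <- function(anchor, L) {
    overlap_any(anchor, reps[[L]][[1L]]) | overlap_any(anchor, reps[[L]][[2L]])
  }

  res <- list()
  for (L in lines) {
    anchor <- cons[[L]]
    others <- setdiff(lines, L)
    if (nrow(anchor) == 0L) next
    hit_other <- Reduce(`|`, lapply(others, function(o) in_any_rep(anchor, o)))
    sel <- anchor[!hit_other, , drop = FALSE]
    if (nrow(sel) > 0L) {
      sel$class <- paste0(L, "_specific")
      res[[length(res) + 1L]] <- tibble::as_tibble(sel)
    }
  }
  subsets <- subset_combinations(lines, reference)
  for (S in subsets) {
    anchor_line <- S[1L]
    anchor <- cons[[anchor_line]]
    if (nrow(anchor) == 0L) next
    inside <- setdiff(S, anchor_line)
    outside <- setdiff(lines, S)
    ok <- rep(TRUE, nrow(anchor))
    for (o in inside) ok <- ok & in_both_reps(anchor, o)
    for (o in outside) ok <- ok & !in_any_rep(anchor, o)
    sel <- anchor[ok, , drop = FALSE]
    if (nrow(sel) > 0L) {
      sel$class <- if (length(S) == length(lines)) "common" else
        paste0("shared_", paste(S, collapse = "_"))
      res[[length(res) + 1L]] <- tibble::as_tibble(sel)
    }
  }
  out <- dplyr::bind_rows(res)
  attr(out, "reference") <- reference
  out
}

# all subsets of size >= 2; the full set is anchored on `reference`,
# proper subsets on their first line in `lines` order
subset_combinations <- function(lines, reference) {
  n <- length(lines)
  out <- list()
  for (k in 2:n) {
    cmb <- utils::combn(lines, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  lapply(out, function(S) {
    if (length(S) == n) c(reference, setdiff(lines, reference)) else S
  })
}

#' Percentage of peaks in one set overlapping another
#'
#' @param a,b peak tables.
#' @return `100 * #{a-peaks overlapping >= 1 b-peak} / |a|`; 0 when `a` is
#'   empty by convention.
#' @export
overlap_fraction <- function(a, b) {
  if (nrow(a) == 0L) return(0)
  100 * sum(overlap_any(a, b)) / nrow(a)
}

#' Write peaks as BED6
#'
#' Missing names/scores are written as `"."`/`0`; strand is always `"."`.
#' Round-trips through [read_peaks()] losslessly for `chrom`/`start`/`end`.
#'
#' @param peaks a peak table.
#' @param path output path.
#' @return The input, invisibly.
#' @export
write_bed <- function(peaks, path) {
  name <- ifelse(is.na(peaks$name), ".", peaks$name)
  score <- ifelse(is.na(peaks$score), 0, peaks$score)
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t.", peaks$chrom, peaks$start,
                   peaks$end, name, format(score, trim = TRUE, scientific = FALSE))
  readr::write_lines(lines, path)
  invisible(peaks)
}

#' Read a UCSC chrom.sizes file
#'
#' @param path two-column `chrom<TAB>length` file.
#' @return Tibble with `chrom` and `length`.
#' @export
read_chrom_sizes <- function(path) {
  x <- readr::read_tsv(path, col_names = c("chrom", "length"),
                       col_types = "ci", progress = FALSE)
  tibble::as_tibble(x)
}

# named integer vector of chromosome lengths from tibble or named vector
as_genome_sizes <- function(genome) {
  if (is.data.frame(genome)) return(setNames(as.numeric(genome$length), genome$chrom))
  if (!is.null(names(genome))) return(setNames(as.numeric(genome), names(genome)))
  abort("genome must be a chrom/length tibble or a named vector of lengths")
}
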