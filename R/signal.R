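#' Load a read-start track from BED
#'
#' Reads are represented by their 5' start position (the BED `start` field);
#' strand is ignored and no fragment extension is applied. Duplicate
#' positions are retained.
#'
#' @param path BED file of read positions (>= 3 columns).
#' @param total_override optional library size overriding the line count
#'   (used when a file is a subsample of a larger library).
#' @param label optional track label.
#' @return A `read_track`: tibble with `chrom` and `pos` (sorted), carrying
#'   `total_reads` and `label` attributes.
#' @export
load_reads <- function(path, total_override = NULL, label = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(read_track(tibble::tibble(chrom = character(), pos = integer()),
                      total_reads = total_override %||% 0L, label = label))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    abort(sprintf("malformed read BED line %d in %s", which(nf < 3L)[1L], path))
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  if (anyNA(pos)) {
    abort(sprintf("malformed read BED line %d in %s: non-integer start",
                  which(is.na(pos))[1L], path))
  }
  read_track(tibble::tibble(chrom = chrom, pos = pos),
             total_reads = total_override %||% length(pos), label = label)
}

read_track <- function(df, total_reads, label = NULL) {
  df <- dplyr::arrange(df, .data$chrom, .data$pos)
  class(df) <- c("read_track", class(tibble::tibble()))
  attr(df, "total_reads") <- as.double(total_reads)
  attr(df, "label") <- label
  df
}

#' Library size of a read track
#' @param track a `read_track`.
#' @return Total read count used for normalization.
#' @export
total_reads <- function(track) attr(track, "total_reads")

# bin counts of read 5' starts for all regions of one chromosome:
# edges is a (n_regions x (n_bins+1)) matrix of bin edges
bin_counts_chrom <- function(pos_sorted, edges) {
  cum <- matrix(findInterval(as.vector(edges) - 0.5, pos_sorted),
                nrow = nrow(edges))
  cum[, -1L, drop = FALSE] - cum[, -ncol(cum), drop = FALSE]
}

#' Input-subtracted, library-normalized binned signal matrix
#'
#' For each region, a window of `2 * half_width` bp centred on the region
#' midpoint is divided into bins of `bin_width` bp. Each bin gets
#' `1e7/treatment_total x treatment_count - 1e7/control_total x control_count`
#' where counts are reads whose 5' start falls in the (half-open) bin — i.e.
#' both libraries are normalised to 10 million reads and the input is
#' subtracted; values can be negative. Windows extending past a chromosome
#' edge are counted over the valid range only and flagged in the region
#' metadata.
#'
#' @param regions non-empty peak table; each window is centred on the region
#'   midpoint (`centre = "summit"` uses the summit where present).
#' @param treatment,control `read_track` objects (see [load_reads()]).
#' @param half_width half window size in bp (default 5000).
#' @param bin_width bin size in bp (default 100; 100 bins in total).
#' @param centre `"midpoint"` (default) or `"summit"`.
#' @param genome optional chrom/length table used to flag truncated windows.
#' @return A `signal_matrix`: list with `values` (n_regions x n_bins),
#'   `regions` (with a `truncated` flag), `bin_width`, `half_width` and the
#'   track labels.
#' @export
build_signal_matrix <- function(regions, treatment, control = NULL,
                                half_width = 5000, bin_width = 100,
                                centre = c("midpoint", "summit"),
                                genome = NULL) {
  centre <- match.arg(centre)
  if (nrow(regions) == 0L) abort("regions must be non-empty")
  if (2 * half_width %% bin_width != 0) {
    abort("2 * half_width must be a multiple of bin_width")
  }
  n_bins <- as.integer(2 * half_width / bin_width)
  ctr <- (regions$start + regions$end) %/% 2L
  if (centre == "summit") ctr <- ifelse(is.na(regions$summit), ctr, regions$summit)
  w_start <- ctr - half_width

  count_track <- function(track) {
    counts <- matrix(0L, nrow = nrow(regions), ncol = n_bins)
    for (chr in unique(regions$chrom)) {
      rsel <- which(regions$chrom == chr)
      pos <- track$pos[track$chrom == chr]
      edges <- outer(w_start[rsel], bin_width * (0:n_bins), `+`)
      counts[rsel, ] <- bin_counts_chrom(pos, edges)
    }
    counts
  }
  scale_of <- function(track) {
    tot <- total_reads(track)
    if (tot > 0) 1e7 / tot else 0   # empty track contributes nothing
  }
  t_counts <- count_track(treatment)
  values <- scale_of(treatment) * t_counts
  c_label <- NULL
  if (!is.null(control)) {
    values <- values - scale_of(control) * count_track(control)
    c_label <- attr(control, "label")
  }
  truncated <- w_start < 0L
  if (!is.null(genome)) {
    sizes <- as_genome_sizes(genome)
    truncated <- truncated | (ctr + half_width > sizes[regions$chrom])
  }
  meta <- tibble::as_tibble(regions)
  meta$truncated <- unname(truncated)
  structure(
    list(values = values, regions = meta, bin_width = bin_width,
         half_width = half_width, treatment_label = attr(treatment, "label"),
         control_label = c_label, treatment_counts = t_counts),
    class = "signal_matrix"
  )
}

#' Column profile of a signal matrix
#'
#' Per-bin sums over all regions — the data behind aggregate binding
#' intensity profiles around binding-site centres.
#'
#' @param m a `signal_matrix`.
#' @return Numeric vector of length `n_bins`.
#' @export
column_profile <- function(m) colSums(m$values)

#' Total normalised binding intensity
#'
#' The sum of all entries of a signal matrix — the summary used to compare
#' total binding strength of different factors over the same regions.
#'
#' @param m a `signal_matrix`.
#' @param clamp if `TRUE`, negative bins are clamped to zero before summing
#'   (both variants are of interest because input subtraction can leave
#'   negative bins).
#' @return A single number.
#' @export
total_intensity <- function(m, clamp = FALSE) {
  v <- m$values
  if (clamp) v[v < 0] <- 0
  sum(v)
}

#' Display order of signal-matrix rows
#'
#' Rows are grouped by category (in the order of the factor levels of
#' `groups`), then sorted by decreasing row sum within each category; the
#' sort is stable, so equal-intensity rows keep their input order.
#'
#' @param m a `signal_matrix`.
#' @param groups optional factor/character vector (one per region).
#' @return Integer permutation of row indices.
#' @export
order_rows <- function(m, groups = NULL) {
  rs <- rowSums(m$values)
  if (is.null(groups)) return(order(-rs, seq_along(rs), method = "radix"))
  g <- if (is.factor(groups)) groups else factor(groups, levels = unique(groups))
  order(as.integer(g), -rs, seq_along(rs), method = "radix")
}

#' Tidy a signal matrix into long format
#'
#' @param x a `signal_matrix`.
#' @param ... unused.
#' @return Tibble with `region` (row index), `bin` (0-based), `offset`
#'   (bp of bin start relative to the window centre) and `value`.
#' @method tidy signal_matrix
#' @export
tidy.signal_matrix <- function(x, ...) {
  n_bins <- ncol(x$values)
  tibble::tibble(
    region = rep(seq_len(nrow(x$values)), times = n_bins),
    bin = rep(0:(n_bins - 1L), each = nrow(x$values)),
    offset = rep(0:(n_bins - 1L) * x$bin_width - x$half_width,
                 each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' Heat-map plot of a signal matrix
#'
#' Negative (input-dominated) bins are clamped to zero for display only; the
#' underlying matrix keeps them.
#'
#' @param object a `signal_matrix`.
#' @param groups optional row categories passed to [order_rows()].
#' @param ... unused.
#' @return A ggplot heat map (rows ordered by [order_rows()]).
#' @method autoplot signal_matrix
#' @export
autoplot.signal_matrix <- function(object, groups = NULL, ...) {
  ord <- order_rows(object, groups)
  df <- tidy(object)
  df$row <- match(df$region, ord)
  df$value <- pmax(df$value, 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "distance from centre (bp)", y = "region",
                  fill = "signal")
}

#' Write a signal matrix as TSV
#'
#' One row per region (`chrom`, `start`, `end`, `truncated`, then one column
#' per bin named by the bp offset of the bin start from the window centre).
#'
#' @param m a `signal_matrix`.
#' @param path output path.
#' @return The input, invisibly.
#' @export
write_signal_tsv <- function(m, path) {
  n_bins <- ncol(m$values)
  off <- 0:(n_bins - 1L) * m$bin_width - m$half_width
  vals <- tibble::as_tibble(m$values, .name_repair = ~ paste0("bp_", off))
  out <- dplyr::bind_cols(m$regions[, c("chrom", "start", "end", "truncated")], vals)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
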