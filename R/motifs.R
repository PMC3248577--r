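#' Position weight matrix
#'
#' Builds a PWM from a 4 x L count (PFM) matrix, rows A, C, G, T. Frequencies
#' are derived with a pseudocount of 1 per cell: `(count + 1) /
#' (column_total + 4)`, so every frequency column sums to one and no
#' frequency is zero.
#'
#' @param counts 4 x L numeric matrix of non-negative counts.
#' @param name motif name.
#' @return An object of class `pwm` with `name`, `counts` and `frequencies`.
#' @export
pwm <- function(counts, name = "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) abort("PWM counts must have 4 rows (A, C, G, T)")
  if (any(counts < 0)) abort("PWM counts must be non-negative")
  rownames(counts) <- c("A", "C", "G", "T")
  freq <- sweep(counts + 1, 2, colSums(counts) + 4, `/`)
  structure(list(name = name, counts = counts, frequencies = freq,
                 length = ncol(counts)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%d positions), consensus %s\n",
              x$name, x$length, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (most frequent base per column)
#' @param p a `pwm`.
#' @return Character string of length `L`.
#' @export
pwm_consensus <- function(p) {
  paste(c("A", "C", "G", "T")[apply(p$frequencies, 2, which.max)], collapse = "")
}

#' Read a JASPAR PFM-format motif collection
#'
#' Accepts the JASPAR text format: a `>ID NAME` header followed by four count
#' rows, either bare numbers or in `A [ 1 2 3 ]` style.
#'
#' @param path path to the PFM file.
#' @return List of [pwm] objects in file order.
#' @export
read_jaspar <- function(path) {
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) abort(sprintf("no '>' motif headers in %s", path))
  ends <- c(starts[-1L] - 1L, length(lines))
  purrr::map2(starts, ends, function(s, e) {
    header <- sub("^>\\s*", "", lines[s])
    name <- gsub("\\s+", "_", header)
    rows <- lines[(s + 1L):e]
    if (length(rows) != 4L) {
      abort(sprintf("motif %s: expected 4 count rows, found %d", name, length(rows)))
    }
    parsed <- lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]\\s*\\[", "", r)
      r <- gsub("\\]\\s*$", "", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]])
    })
    if (length(unique(lengths(parsed))) != 1L) {
      abort(sprintf("motif %s: count rows have unequal lengths", name))
    }
    pwm(do.call(rbind, parsed), name = name)
  })
}

# A=0, C=1, G=2, T=3, anything else (incl. N) = 4
encode_seq <- function(seq) {
  v <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]],
             c("A", "C", "G", "T"))
  v[is.na(v)] <- 5L
  as.integer(v - 1L)
}

revcomp_code <- function(code) {
  rc <- rev(code)
  ifelse(rc > 3L, 4L, 3L - rc)
}

# min-max raw-score bounds of a frequency matrix (permutation-invariant)
pwm_score_range <- function(p) {
  c(min = sum(apply(p$frequencies, 2, min)),
    max = sum(apply(p$frequencies, 2, max)))
}

raw_threshold <- function(p, threshold) {
  r <- pwm_score_range(p)
  if (r["max"] - r["min"] <= 0) return(unname(r["min"]))
  unname(r["min"] + threshold * (r["max"] - r["min"]))
}

#' Scan a sequence for PWM matches above a similarity threshold
#'
#' At every offset on both strands the frequency-sum score is min-max
#' normalised: `similarity = (score - min) / (max - min)` with `min`/`max`
#' the sums of column-wise minimum/maximum frequencies, so the consensus
#' scores exactly 1 and the anti-consensus 0. Positions are forward-strand
#' match starts (0-based) for both strands; windows containing N never match.
#'
#' @param seq nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param p a [pwm].
#' @param threshold minimum similarity in `[0, 1]` (default 0.85).
#' @return Tibble with `position`, `strand` (`"+"`/`"-"`) and `similarity`,
#'   sorted by position.
#' @export
similarity_scan <- function(seq, p, threshold = 0.85) {
  code <- encode_seq(seq)
  L <- p$length
  empty <- tibble::tibble(position = integer(), strand = character(),
                          similarity = double())
  if (length(code) < L) return(empty)
  r <- pwm_score_range(p)
  thr <- raw_threshold(p, threshold)
  denom <- max(r["max"] - r["min"], .Machine$double.eps)
  fwd <- scan_hits_cpp(code, p$frequencies, thr)
  rev <- scan_hits_cpp(revcomp_code(code), p$frequencies, thr)
  out <- tibble::tibble(
    position = c(fwd$pos, length(code) - L - rev$pos),
    strand = c(rep("+", length(fwd$pos)), rep("-", length(rev$pos))),
    similarity = pmin((c(fwd$score, rev$score) - r["min"]) / denom, 1)
  )
  dplyr::arrange(out, .data$position, .data$strand)
}

#' Count motif hits in non-overlapping windows
#'
#' @param hits tibble from [similarity_scan()] (or integer vector of match
#'   start positions); strands are pooled.
#' @param span total sequence span in bp (default 2000).
#' @param window_width window size in bp (default 100; 20 windows).
#' @return Integer vector of per-window counts (window k covers
#'   `[k * window_width, (k+1) * window_width)` by match start).
#' @export
window_counts <- function(hits, span = 2000, window_width = 100) {
  pos <- if (is.data.frame(hits)) hits$position else as.integer(hits)
  if (length(pos) > 0L && (min(pos) < 0L || max(pos) >= span)) {
    abort("hit position outside [0, span)")
  }
  n_win <- span %/% window_width
  tabulate(pos %/% window_width + 1L, nbins = n_win)
}

#' Randomly permute the columns of a PWM
#'
#' Columns are reordered by a uniform random permutation (the identity is
#' allowed), preserving per-column base composition and total information
#' content while destroying the base order — the null used by the windowed
#' enrichment test.
#'
#' @param p a [pwm].
#' @param seed optional integer seed.
#' @return A [pwm] with permuted columns.
#' @export
permute_pwm <- function(p, seed = NULL) {
  draw <- function() sample.int(p$length)
  perm <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  pwm(p$counts[, perm, drop = FALSE], name = paste0(p$name, "_perm"))
}

#' Gaussian-tail empirical p-value
#'
#' Fits a Gaussian to the null counts (sd with denominator n - 1) and
#' returns the upper-tail area at the observed count:
#' `p = 1 - Phi((observed - mean) / sd)`. When the null is constant
#' (`sd = 0`), returns 1 if `observed <= mean` and the smallest positive
#' double otherwise (a documented sentinel for "beyond any null sample").
#'
#' @param observed observed count.
#' @param null_counts numeric vector of null counts (length >= 2).
#' @return p-value in `(0, 1]`.
#' @export
gaussian_p <- function(observed, null_counts) {
  if (length(null_counts) < 2L) abort("need >= 2 null counts")
  m <- mean(null_counts)
  s <- sd(null_counts)
  if (s == 0) {
    return(if (observed <= m) 1 else .Machine$double.xmin)
  }
  pnorm(observed, mean = m, sd = s, lower.tail = FALSE)
}

#' Windowed motif enrichment with a permuted-matrix null
#'
#' For each PWM, matches at similarity >= `threshold` are counted on both
#' strands in `span / window_width` non-overlapping windows, pooled over all
#' sequences. The null distribution per window comes from `n_perm` random
#' column permutations of the matrix scanned identically, and each window's
#' p-value is the Gaussian upper-tail area of the observed count under that
#' null ([gaussian_p()]). Because permutation preserves the column multiset,
#' the null keeps the matrix's information content and isolates positional
#' signal.
#'
#' @param sequences character vector of equal-length sequences (each exactly
#'   `span` bp; see [extract_summit_sequences()]).
#' @param pwms a [pwm] or list of them.
#' @param n_perm number of permuted matrices (default 1000).
#' @param threshold similarity threshold (default 0.85).
#' @param span,window_width window geometry (defaults 2000 / 100).
#' @param seed optional integer seed; results are deterministic given it.
#' @param adjust `"none"` (default) or `"bonferroni"` across all
#'   PWM-by-window tests (adds a `p_adjusted` column).
#' @return Tibble of class `motif_enrichment`: one row per PWM x window with
#'   `pwm`, `window`, `observed`, `null_mean`, `null_sd`, `p_value`.
#' @export
motif_enrichment <- function(sequences, pwms, n_perm = 1000, threshold = 0.85,
                             span = 2000, window_width = 100, seed = NULL,
                             adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (length(sequences) == 0L) abort("no sequences supplied")
  if (any(nchar(sequences) != span)) {
    abort("all sequences must be exactly `span` bp; pad or truncate first")
  }
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  codes <- lapply(sequences, encode_seq)
  rc_codes <- lapply(codes, revcomp_code)
  run <- function() {
    purrr::map_dfr(pwms, function(p) {
      L <- p$length
      thr <- raw_threshold(p, threshold)
      obs <- scan_window_counts_cpp(
        codes, rc_codes, p$frequencies,
        matrix(0:(L - 1L), nrow = 1L), thr, window_width, span)[1L, ]
      perms <- t(vapply(seq_len(n_perm), function(i) sample.int(L) - 1L,
                        integer(L)))
      null <- scan_window_counts_cpp(codes, rc_codes, p$frequencies, perms,
                                     thr, window_width, span)
      tibble::tibble(
        pwm = p$name,
        window = seq_along(obs) - 1L,
        observed = as.integer(obs),
        null_mean = colMeans(null),
        null_sd = apply(null, 2, sd),
        p_value = vapply(seq_along(obs), function(w) {
          gaussian_p(obs[w], null[, w])
        }, double(1))
      )
    })
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (adjust == "bonferroni") {
    out$p_adjusted <- pmin(out$p_value * nrow(out), 1)
  }
  class(out) <- c("motif_enrichment", class(out))
  out
}

#' Heat-map of windowed motif enrichment p-values
#'
#' @param object a `motif_enrichment` tibble.
#' @param ... unused.
#' @return A ggplot tile map of `-log10(p)` by PWM and window.
#' @method autoplot motif_enrichment
#' @export
autoplot.motif_enrichment <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window, y = .data$pwm,
                                       fill = -log10(.data$p_value))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = "100-bp window", y = NULL, fill = "-log10 p")
}

#' Extract fixed-width sequences around peak summits
#'
#' Retrieves `span` bp of genomic sequence centred on each peak's summit
#' (midpoint when the summit is absent), padding with `N` where the window
#' runs past a chromosome end, so every returned sequence is exactly `span`
#' bp.
#'
#' @param genome a named character vector of chromosome sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA path.
#' @param peaks a peak table.
#' @param span window width in bp (default 2000).
#' @return Character vector of sequences, one per peak.
#' @export
extract_summit_sequences <- function(genome, peaks, span = 2000) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  ctr <- ifelse(is.na(peaks$summit), (peaks$start + peaks$end) %/% 2L,
                peaks$summit)
  half <- span %/% 2L
  vapply(seq_len(nrow(peaks)), function(i) {
    chr_seq <- genome[[peaks$chrom[i]]]
    len <- nchar(chr_seq)
    from <- ctr[i] - half          # 0-based inclusive
    to <- from + span              # 0-based exclusive
    left_pad <- max(0L, -from)
    right_pad <- max(0L, to - len)
    core <- substr(chr_seq, from + 1L + left_pad, to - right_pad)
    paste0(strrep("N", left_pad), core, strrep("N", right_pad))
  }, character(1))
}
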