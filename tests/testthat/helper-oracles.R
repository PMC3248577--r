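# Brute-force oracles and random fixtures, independent of the package's
# interval index / compiled scanner code paths.

random_peaks <- function(n, chroms = c(chr1 = 1e6), width = c(50L, 400L),
                         with_summit = FALSE) {
  chrom <- sample(names(chroms), n, replace = TRUE)
  w <- sample(width[1]:width[2], n, replace = TRUE)
  start <- vapply(seq_len(n), function(i) {
    sample.int(chroms[[chrom[i]]] - w[i], 1L) - 1L
  }, integer(1))
  summit <- if (with_summit) start + w %/% 2L else NA_integer_
  peak_tbl(chrom, start, start + w, summit = summit)
}

# all-pairs overlap: does row i of a overlap any row of b?
oracle_overlap_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

oracle_consensus <- function(rep1, rep2) rep1[oracle_overlap_any(rep1, rep2), ]

oracle_cobind_category <- function(ctcf, er, foxa1) {
  in_er <- oracle_overlap_any(ctcf, er)
  in_fox <- oracle_overlap_any(ctcf, foxa1)
  ifelse(in_er & in_fox, "CTCF_ER_FOXA1",
         ifelse(in_er, "CTCF_ER", ifelse(in_fox, "CTCF_FOXA1", "CTCF_only")))
}

random_pwm <- function(L = sample(6:14, 1), name = "rand") {
  pwm(matrix(sample(0:50, 4 * L, replace = TRUE), nrow = 4), name = name)
}

random_seq <- function(len, n_prob = 0) {
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(rep((1 - n_prob) / 4, 4), n_prob)), collapse = "")
}

# exhaustive per-offset scanner: no pruning, no shared code with the C++ path
oracle_scan <- function(seq, p, threshold = 0.85) {
  F <- p$frequencies
  L <- p$length
  lo <- sum(apply(F, 2, min))
  hi <- sum(apply(F, 2, max))
  scan_strand <- function(s) {
    code <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    n <- length(code)
    if (n < L) return(integer(0))
    hits <- integer(0)
    for (i in 0:(n - L)) {
      win <- code[i + seq_len(L)]
      if (anyNA(win)) next
      sim <- (sum(F[cbind(win, seq_len(L))]) - lo) / (hi - lo)
      if (sim >= threshold - 1e-9) hits <- c(hits, i)
    }
    hits
  }
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }
  fwd <- scan_strand(seq)
  rev_hits <- scan_strand(rc(seq))
  tibble::tibble(
    position = c(fwd, nchar(seq) - L - rev_hits),
    strand = c(rep("+", length(fwd)), rep("-", length(rev_hits))))
}

# exact two-sided Fisher p by full enumeration over fixed-margin tables
oracle_fisher_p <- function(a, b, cc, d) {
  n <- a + b + cc + d
  r1 <- a + b
  c1 <- a + cc
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(x) {
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  }, double(1))
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# re-sort/re-validate a hand-edited peak tibble
as_peak_tbl_for_test <- function(x) peakcobind:::as_peak_tbl(x)

# exhaustive scanner oracle, vectorised by matrix column (still scores every
# offset; no pruning and no shared code with the compiled scanner)
oracle_scan_fast <- function(seq, p, threshold = 0.85) {
  F <- p$frequencies
  L <- p$length
  lo <- sum(apply(F, 2, min))
  hi <- sum(apply(F, 2, max))
  strand_hits <- function(s) {
    code <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    n <- length(code)
    if (n < L) return(integer(0))
    n_off <- n - L + 1L
    score <- rep(0, n_off)
    has_n <- rep(FALSE, n_off)
    for (k in seq_len(L)) {
      ck <- code[k:(n - L + k)]
      has_n <- has_n | is.na(ck)
      contrib <- F[cbind(ifelse(is.na(ck), 1L, ck), k)]
      score <- score + contrib
    }
    sim <- (score - lo) / (hi - lo)
    which(!has_n & sim >= threshold - 1e-9) - 1L
  }
  rc <- function(s) paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
                          collapse = "")
  fwd <- strand_hits(seq)
  rev_hits <- strand_hits(rc(seq))
  tibble::tibble(
    position = c(fwd, nchar(seq) - L - rev_hits),
    strand = c(rep("+", length(fwd)), rep("-", length(rev_hits))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
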