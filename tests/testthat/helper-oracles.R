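# Brute-force oracles used to cross-check the interval algebra and the
# motif scanner. They operate per base / per window and are deliberately
# independent of the package's IRanges-backed implementation.

# coverage of an interval set over [0, size) on one chromosome
bf_coverage <- function(x, chrom, size) {
  cov <- logical(size)
  sel <- x$chrom == chrom
  for (i in which(sel)) {
    lo <- max(x$start[i], 0) + 1
    hi <- min(x$end[i], size)
    if (hi >= lo) cov[lo:hi] <- TRUE
  }
  cov
}

# membership vector -> interval data frame
bf_to_intervals <- function(cov, chrom) {
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  keep <- r$values
  if (!any(keep))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep])
}

bf_setop <- function(a, b, op, chrom, size) {
  ca <- bf_coverage(a, chrom, size)
  cb <- bf_coverage(b, chrom, size)
  cv <- switch(op, intersect = ca & cb, subtract = ca & !cb, union = ca | cb)
  bf_to_intervals(cv, chrom)
}

# random interval set on one chromosome of the given size
random_ivs <- function(n, chrom = "c", size = 10000) {
  s <- sample.int(size - 2, n, replace = TRUE) - 1L
  w <- sample.int(200, n, replace = TRUE)
  interval_set(rep(chrom, n), s, pmin(s + w, size))
}

# per-window exact motif count on both strands, overlapping matches
bf_motif_count <- function(seq, motif) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  count_one <- function(seq, m) {
    k <- nchar(m)
    n <- nchar(seq)
    if (n < k) return(0L)
    sum(vapply(seq_len(n - k + 1), function(i)
      substr(seq, i, i + k - 1) == m, logical(1)))
  }
  rc <- revcomp(motif)
  cnt <- count_one(seq, motif)
  if (rc != motif) cnt <- cnt + count_one(seq, rc)
  cnt
}

# simple stepwise track builder
make_track <- function(chrom, start, end, value, genome = NULL) {
  signal_track(data.frame(chrom = chrom, start = start, end = end,
                          value = value), genome)
}
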