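#' Stepwise signal tracks
#'
#' A `signal_track` stores per-chromosome coverage (e.g. RPM from pooled
#' reads) as run-length-encoded vectors. Positions not covered by any step
#' have value 0. Tracks are queried for per-bp windows, means and maxima
#' over intervals.
#'
#' @param steps data frame with columns `chrom`, `start`, `end`, `value`
#'   (0-based half-open steps, non-overlapping within a chromosome,
#'   values >= 0).
#' @param genome optional named numeric vector of chromosome lengths;
#'   intervals beyond these bounds are clipped with a warning when queried.
#' @return An object of class `signal_track`.
#' @export
signal_track <- function(steps, genome = NULL) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(steps)))
  if (any(steps$value < 0)) stop("signal values must be >= 0")
  if (any(steps$end <= steps$start)) stop("step end must exceed start")
  rles <- list()
  for (ch in unique(as.character(steps$chrom))) {
    s <- steps[steps$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping steps on chromosome ", ch)
    len <- if (!is.null(genome) && ch %in% names(genome))
      as.integer(genome[[ch]]) else max(s$end)
    v <- S4Vectors::Rle(0, len)
    keep <- s$value != 0 & s$start < len
    if (any(keep)) {
      ir <- IRanges::IRanges(s$start[keep] + 1L, pmin(s$end[keep], len))
      v[ir] <- rep(s$value[keep], IRanges::width(ir))
    }
    rles[[ch]] <- v
  }
  if (!is.null(genome)) {
    for (ch in setdiff(names(genome), names(rles)))
      rles[[ch]] <- S4Vectors::Rle(0, as.integer(genome[[ch]]))
  }
  structure(list(rle = rles, genome = genome), class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosome(s); total mass %.2f\n",
              length(x$rle),
              sum(vapply(x$rle, function(r) sum(as.numeric(r)), numeric(1)))))
  invisible(x)
}

# Per-bp numeric window [start, end) of a track, zero-padded outside the
# stored extent. Returns plain numeric vector.
track_window <- function(track, chrom, start, end) {
  if (!chrom %in% names(track$rle))
    stop("chromosome not present in signal track: ", chrom)
  r <- track$rle[[chrom]]
  n <- end - start
  lo <- max(start, 0L); hi <- min(end, length(r))
  out <- numeric(n)
  if (hi > lo)
    out[(lo - start + 1):(hi - start)] <-
      as.numeric(S4Vectors::window(r, lo + 1L, hi))
  out
}

#' Summarise a track over intervals
#'
#' The mean is bp-weighted with uncovered positions counting as 0; the max
#' is taken over covered and uncovered positions alike. Intervals extending
#' past a declared chromosome bound are clipped with a warning (the clipped
#' part contributes zeros).
#'
#' @param track a `signal_track`.
#' @param x an `interval_set` (or one-row data frame).
#' @param stat `"mean"` or `"max"`.
#' @return numeric vector, one value per interval.
#' @export
signal_stat <- function(track, x, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  n <- nrow(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ch <- x$chrom[i]
    if (!ch %in% names(track$rle))
      stop("chromosome not present in signal track: ", ch)
    bound <- if (!is.null(track$genome) && ch %in% names(track$genome))
      track$genome[[ch]] else NA
    if (!is.na(bound) && (x$end[i] > bound || x$start[i] < 0))
      warning("interval ", ch, ":", x$start[i], "-", x$end[i],
              " clipped to chromosome bounds")
    w <- track_window(track, ch, x$start[i], x$end[i])
    out[i] <- if (stat == "mean") mean(w) else max(w)
  }
  out
}

#' @return `track_max_diff`: per interval, the largest per-bp value of
#'   `a - b` (signed), used for tissue-contrast ranking.
#' @rdname signal_stat
#' @param a,b `signal_track`s on the same genome.
#' @export
track_max_diff <- function(a, b, x) {
  n <- nrow(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    wa <- track_window(a, x$chrom[i], x$start[i], x$end[i])
    wb <- track_window(b, x$chrom[i], x$start[i], x$end[i])
    out[i] <- max(wa - wb)
  }
  out
}

#' Read and write signal tracks
#'
#' `read_bedgraph` parses bedGraph (4 columns, 0-based half-open; `track`
#' and comment lines skipped). `read_wig` reads fixed-step (and variable
#' step) WIG via rtracklayer and converts to the same representation.
#' `write_bedgraph` emits sorted non-zero steps.
#'
#' @param path file path.
#' @param genome optional named chromosome lengths.
#' @param track a `signal_track`.
#' @return a `signal_track`; `write_bedgraph` returns `path` invisibly.
#' @export
read_bedgraph <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0)
    return(signal_track(data.frame(chrom = character(), start = integer(),
                                   end = integer(), value = numeric()),
                        genome))
  fields <- strsplit(lines[idx], "[\t ]+")
  ncol <- vapply(fields, length, integer(1))
  if (any(ncol < 4))
    stop("malformed bedGraph line ", idx[which(ncol < 4)[1]], " in ", path)
  steps <- data.frame(
    chrom = vapply(fields, `[[`, character(1), 1L),
    start = as.integer(vapply(fields, `[[`, character(1), 2L)),
    end = as.integer(vapply(fields, `[[`, character(1), 3L)),
    value = as.numeric(vapply(fields, `[[`, character(1), 4L)),
    stringsAsFactors = FALSE)
  if (anyNA(steps$start) || anyNA(steps$end) || anyNA(steps$value))
    stop("malformed bedGraph fields in ", path)
  signal_track(steps, genome)
}

#' @rdname read_bedgraph
#' @export
read_wig <- function(path, genome = NULL) {
  gr <- as.data.frame(rtracklayer::import(path, format = "wig"))
  steps <- data.frame(chrom = as.character(gr$seqnames),
                      start = gr$start - 1L, end = gr$end,
                      value = gr$score, stringsAsFactors = FALSE)
  signal_track(steps, genome)
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(track, path) {
  out <- character()
  for (ch in names(track$rle)) {
    r <- track$rle[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, ends[-length(ends)])
    vals <- S4Vectors::runValue(r)
    nz <- vals != 0
    if (any(nz))
      out <- c(out, sprintf("%s\t%d\t%d\t%g", ch, starts[nz], ends[nz],
                            vals[nz]))
  }
  writeLines(out, path)
  invisible(path)
}
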