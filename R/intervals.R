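#' Genomic interval sets
#'
#' An `interval_set` is a data frame of genomic intervals in BED convention:
#' 0-based starts, exclusive ends, sorted by chromosome then start. It is the
#' substrate for all overlap logic in the package (peaks, LUMRs, genes, TEs,
#' masks, conserved non-coding sequences). Strand, when present, is metadata
#' only: interval algebra is strand-blind.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end`.
#' @param name optional character labels.
#' @param strand optional strand, one of `"+"`, `"-"`, `"*"`.
#' @param merged logical; assert that the set is pairwise disjoint.
#' @return A data frame of class `interval_set` with columns `chrom`,
#'   `start`, `end` and optionally `name`, `strand`.
#' @examples
#' interval_set("chr1", c(0, 500), c(100, 900))
#' @export
interval_set <- function(chrom = character(), start = integer(),
                         end = integer(), name = NULL, strand = NULL,
                         merged = FALSE) {
  chrom <- as.character(chrom)
  start <- as.integer(round(start))
  end <- as.integer(round(end))
  n <- max(length(chrom), length(start), length(end))
  if (length(chrom) == 1L) chrom <- rep(chrom, n)
  if (!is.null(name) && length(name) == 1L) name <- rep(name, n)
  if (!is.null(strand) && length(strand) == 1L) strand <- rep(strand, n)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop("chrom, start and end must have equal length")
  if (n > 0) {
    if (any(is.na(chrom)) || any(!nzchar(chrom)))
      stop("chromosome names must be non-empty")
    if (any(is.na(start)) || any(is.na(end)))
      stop("interval coordinates must not be NA")
    if (any(start < 0)) stop("interval start must be >= 0")
    if (any(end <= start)) stop("interval end must be greater than start")
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(strand)) {
    strand <- as.character(strand)
    strand[!strand %in% c("+", "-")] <- "*"
    df$strand <- strand
  }
  ord <- order(df$chrom, df$start, df$end)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("interval_set", "data.frame")
  if (merged) {
    if (n > 1) {
      same <- df$chrom[-1] == df$chrom[-n]
      if (any(same & df$start[-1] < df$end[-n]))
        stop("set flagged merged but contains overlapping intervals")
    }
    attr(df, "merged") <- TRUE
  }
  df
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set: %d interval(s) on %d chromosome(s), %d bp\n",
              nrow(x), length(unique(x$chrom)), iv_total_bp(x)))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

as_interval_set <- function(df, merged = FALSE) {
  interval_set(df$chrom, df$start, df$end,
               name = df[["name"]], strand = df[["strand"]], merged = merged)
}

#' Total base pairs covered by the intervals of a set
#'
#' Overlapping intervals are counted once (the set is merged first).
#' @param x an `interval_set`.
#' @return integer number of covered base pairs.
#' @export
iv_total_bp <- function(x) {
  if (nrow(x) == 0) return(0L)
  m <- iv_merge(x)
  sum(m$end - m$start)
}

# interval_set -> named list of IRanges (1-based closed, the IRanges
# convention); the +1 shift is confined to these two helpers.
.iv_to_ir <- function(x) {
  if (nrow(x) == 0) return(list())
  sp <- split(seq_len(nrow(x)), x$chrom)
  lapply(sp, function(i) IRanges::IRanges(start = x$start[i] + 1L,
                                          end = x$end[i]))
}

.iv_from_ir <- function(lst, merged = FALSE) {
  if (length(lst) == 0)
    return(interval_set(merged = merged))
  parts <- lapply(names(lst), function(ch) {
    ir <- lst[[ch]]
    if (length(ir) == 0) return(NULL)
    data.frame(chrom = ch, start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  if (is.null(df)) return(interval_set(merged = merged))
  interval_set(df$chrom, df$start, df$end, merged = merged)
}

.iv_binop <- function(a, b, fun, merged = TRUE) {
  ira <- .iv_to_ir(a)
  irb <- .iv_to_ir(b)
  chroms <- union(names(ira), names(irb))
  out <- lapply(chroms, function(ch) {
    ra <- if (ch %in% names(ira)) ira[[ch]] else IRanges::IRanges()
    rb <- if (ch %in% names(irb)) irb[[ch]] else IRanges::IRanges()
    fun(ra, rb)
  })
  names(out) <- chroms
  .iv_from_ir(out, merged = merged)
}

#' Interval set algebra
#'
#' `iv_intersect` returns the maximal regions covered by both sets;
#' `iv_subtract` removes from `a` every base covered by `b`; `iv_merge`
#' unions overlapping and book-ended intervals (optionally bridging gaps up
#' to `gap` bp). All three return merged, pairwise-disjoint sets.
#'
#' @param a,b,x `interval_set` objects.
#' @param gap non-negative integer; intervals separated by at most `gap`
#'   uncovered bp are merged into one.
#' @return An `interval_set` flagged as merged.
#' @examples
#' a <- interval_set("chr1", 0, 1000)
#' b <- interval_set("chr1", 500, 1500)
#' iv_intersect(a, b)   # [500, 1000)
#' iv_subtract(a, b)    # [0, 500)
#' iv_merge(interval_set("chr1", c(0, 100), c(100, 200)))  # [0, 200)
#' @export
iv_intersect <- function(a, b) {
  .iv_binop(a, b, function(ra, rb)
    IRanges::intersect(IRanges::reduce(ra), IRanges::reduce(rb)))
}

#' @rdname iv_intersect
#' @export
iv_subtract <- function(a, b) {
  .iv_binop(a, b, function(ra, rb)
    IRanges::setdiff(IRanges::reduce(ra), IRanges::reduce(rb)))
}

#' @rdname iv_intersect
#' @export
iv_merge <- function(x, gap = 0) {
  stopifnot(gap >= 0)
  ir <- .iv_to_ir(x)
  out <- lapply(ir, IRanges::reduce, min.gapwidth = gap + 1L)
  .iv_from_ir(out, merged = TRUE)
}

#' Pairwise overlap statistics for two intervals
#'
#' @param a,b single intervals: either one-row `interval_set`s or lists with
#'   elements `chrom`, `start`, `end`.
#' @return A list with `overlap_bp`, `frac_of_a`, `frac_of_b`. Intervals on
#'   different chromosomes overlap by zero.
#' @examples
#' overlap_stats(list(chrom = "c", start = 100, end = 200),
#'               list(chrom = "c", start = 150, end = 250))
#' @export
overlap_stats <- function(a, b) {
  a <- as.list(a[c("chrom", "start", "end")])
  b <- as.list(b[c("chrom", "start", "end")])
  if (a$chrom != b$chrom)
    return(list(overlap_bp = 0L, frac_of_a = 0, frac_of_b = 0))
  ov <- max(0L, min(a$end, b$end) - max(a$start, b$start))
  list(overlap_bp = as.integer(ov),
       frac_of_a = ov / (a$end - a$start),
       frac_of_b = ov / (b$end - b$start))
}

# Per-row overlap of `x` against the merged coverage of `y`.
# Returns integer bp vector aligned with rows of x.
iv_overlap_bp <- function(x, y) {
  if (nrow(x) == 0) return(integer())
  ym <- iv_merge(y)
  iry <- .iv_to_ir(ym)
  out <- integer(nrow(x))
  for (ch in unique(x$chrom)) {
    sel <- which(x$chrom == ch)
    if (!ch %in% names(iry)) next
    irx <- IRanges::IRanges(x$start[sel] + 1L, x$end[sel])
    hits <- IRanges::findOverlaps(irx, iry[[ch]])
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- pmin(IRanges::end(irx)[qi], IRanges::end(iry[[ch]])[si]) -
      pmax(IRanges::start(irx)[qi], IRanges::start(iry[[ch]])[si]) + 1L
    agg <- tapply(ov, qi, sum)
    out[sel[as.integer(names(agg))]] <- as.integer(agg)
  }
  out
}

# Logical per row of x: >= 1 bp overlap with any interval of y.
iv_overlaps_any <- function(x, y) iv_overlap_bp(x, y) > 0L

#' Read and write BED files
#'
#' `read_bed` parses BED3/BED6 (tab- or space-delimited) into an
#' `interval_set`; `track`, `browser` and `#` comment lines are skipped.
#' Coordinates are kept in the BED 0-based half-open convention.
#' `write_bed` emits deterministic, sorted BED (3 columns, or 6 when names
#' or strands are present); writing then reading restores the same set.
#'
#' @param path file path.
#' @param x an `interval_set`.
#' @return `read_bed` returns an `interval_set`; `write_bed` returns `path`
#'   invisibly.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) return(interval_set())
  fields <- strsplit(lines[idx], "[\t ]+")
  ncol <- vapply(fields, length, integer(1))
  if (any(ncol < 3))
    stop("malformed BED line ", idx[which(ncol < 3)[1]], " in ", path,
         ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0)
    stop("malformed BED line ", idx[bad[1]], " in ", path,
         ": coordinates do not parse as integers")
  bad <- which(end <= start | start < 0)
  if (length(bad) > 0)
    stop("invalid interval at BED line ", idx[bad[1]], " in ", path,
         ": requires 0 <= start < end")
  name <- if (all(ncol >= 4)) vapply(fields, `[[`, character(1), 4L) else NULL
  strand <- if (all(ncol >= 6)) vapply(fields, `[[`, character(1), 6L) else NULL
  interval_set(chrom, start, end, name = name, strand = strand)
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  if (nrow(x) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  has_meta <- !is.null(x[["name"]]) || !is.null(x[["strand"]])
  if (has_meta) {
    nm <- if (!is.null(x[["name"]])) x$name else rep(".", nrow(x))
    st <- if (!is.null(x[["strand"]])) x$strand else rep("*", nrow(x))
    st[st == "*"] <- "."
    out <- sprintf("%s\t%d\t%d\t%s\t0\t%s", x$chrom, x$start, x$end, nm, st)
  } else {
    out <- sprintf("%s\t%d\t%d", x$chrom, x$start, x$end)
  }
  writeLines(out, path)
  invisible(path)
}

#' Closest flanking genes for each query interval
#'
#' For each interval the nearest gene fully upstream (gene end at or before
#' the interval start) and fully downstream (gene start at or after the
#' interval end) are located by genomic coordinate, irrespective of gene
#' strand. Distances are gap widths in bp (0 when abutting). Genes
#' overlapping the query are not flanking genes.
#'
#' @param x an `interval_set` of query regions.
#' @param genes an `interval_set` of genes, ideally with a `name` column.
#' @return A data frame with one row per query: `upstream`, `downstream`
#'   (gene names or `NA`), `upstream_dist`, `downstream_dist` (bp or `NA`).
#' @export
nearest_flanking <- function(x, genes) {
  n <- nrow(x)
  out <- data.frame(upstream = rep(NA_character_, n),
                    downstream = rep(NA_character_, n),
                    upstream_dist = rep(NA_integer_, n),
                    downstream_dist = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  if (n == 0 || nrow(genes) == 0) return(out)
  gname <- if (!is.null(genes[["name"]])) genes$name else
    sprintf("gene_%d", seq_len(nrow(genes)))
  for (ch in unique(x$chrom)) {
    qi <- which(x$chrom == ch)
    gi <- which(genes$chrom == ch)
    if (length(gi) == 0) next
    ge <- genes$end[gi]; gs <- genes$start[gi]
    # upstream: gene with maximal end among ends <= query start
    ord_e <- order(ge)
    pos <- findInterval(x$start[qi], ge[ord_e])
    has_up <- pos >= 1
    up_idx <- gi[ord_e[pmax(pos, 1L)]]
    out$upstream[qi[has_up]] <- gname[up_idx[has_up]]
    out$upstream_dist[qi[has_up]] <-
      x$start[qi[has_up]] - genes$end[up_idx[has_up]]
    # downstream: gene with minimal start among starts >= query end
    ord_s <- order(gs)
    ss <- gs[ord_s]
    pos2 <- findInterval(x$end[qi] - 1L, ss)  # starts strictly < query end
    has_dn <- pos2 + 1L <= length(ss)
    dn_idx <- gi[ord_s[pmin(pos2 + 1L, length(ss))]]
    out$downstream[qi[has_dn]] <- gname[dn_idx[has_dn]]
    out$downstream_dist[qi[has_dn]] <-
      genes$start[dn_idx[has_dn]] - x$end[qi[has_dn]]
  }
  out
}
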