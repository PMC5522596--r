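#' Per-cytosine methylation tables
#'
#' Reads tab-delimited per-cytosine methylation calls with columns
#' `chrom`, `pos` (0-based bp), `context` (CG, CHG or CHH), `frequency`
#' (methylated fraction in [0, 1]) and `coverage` (reads). Frequencies are
#' only meaningful at covered sites; zero-coverage sites are kept in the
#' table but skipped by every downstream computation.
#'
#' @param path file path (tab-delimited, with or without header).
#' @return data frame of class `methylation_sites`.
#' @export
read_methylation <- function(path) {
  if (!file.exists(path)) stop("methylation file not found: ", path)
  first <- readLines(path, n = 1)
  header <- grepl("chrom", first)
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE)
  if (!header) names(df) <- c("chrom", "pos", "context", "frequency",
                              "coverage")[seq_len(ncol(df))]
  need <- c("chrom", "pos", "context", "frequency", "coverage")
  if (!all(need %in% names(df)))
    stop("methylation table needs columns: ", paste(need, collapse = ", "))
  if (!all(df$context %in% c("CG", "CHG", "CHH")))
    stop("methylation context must be CG, CHG or CHH")
  cov <- df$coverage > 0
  if (any(df$frequency[cov] < 0 | df$frequency[cov] > 1))
    stop("methylation frequencies must be in [0, 1]")
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("methylation_sites", "data.frame")
  df
}

#' Segment regions of low methylation in one context
#'
#' Finds maximal runs of at least `min_sites` consecutive covered sites of
#' the requested context whose methylation frequency is strictly below
#' `threshold`, with consecutive sites no more than `max_gap_bp` apart.
#' A covered site at or above the threshold breaks the run; uncovered
#' sites are skipped. Each region spans from its first to its last site
#' plus one base.
#'
#' This is a transparent run-based stand-in for HMM-type segmenters: the
#' decisions that matter downstream are the 20% ceiling and the CG/CHG
#' combination, not the segmentation machinery.
#'
#' @param sites a `methylation_sites` data frame.
#' @param context `"CG"` or `"CHG"`.
#' @param threshold frequency ceiling (strict `<`).
#' @param min_sites minimum run length in sites.
#' @param max_gap_bp maximum distance between consecutive sites in a run.
#' @return merged `interval_set` of low-methylation regions.
#' @export
segment_low_methylation <- function(sites, context,
                                    threshold = 0.20, min_sites = 4L,
                                    max_gap_bp = 300L) {
  stopifnot(context %in% c("CG", "CHG"))
  s <- sites[sites$context == context & sites$coverage > 0, , drop = FALSE]
  if (nrow(s) == 0) {
    warning("no covered ", context, " sites; empty segmentation")
    return(interval_set(merged = TRUE))
  }
  s <- s[order(s$chrom, s$pos), , drop = FALSE]
  out <- list()
  for (ch in unique(s$chrom)) {
    sc <- s[s$chrom == ch, , drop = FALSE]
    low <- sc$frequency < threshold
    gap_break <- c(TRUE, diff(sc$pos) > max_gap_bp)
    run_id <- cumsum(!low | gap_break)
    runs <- split(which(low), run_id[low])
    for (r in runs) {
      if (length(r) >= min_sites)
        out[[length(out) + 1]] <- data.frame(
          chrom = ch, start = sc$pos[r[1]],
          end = sc$pos[r[length(r)]] + 1L)
    }
  }
  if (length(out) == 0) return(interval_set(merged = TRUE))
  df <- do.call(rbind, out)
  iv_merge(interval_set(df$chrom, df$start, df$end))
}

#' Combine context-wise low-methylation regions into LUMRs
#'
#' Low and unmethylated regions (LUMRs) are regions low in both CG and CHG
#' methylation: the intersection of the two context-wise segmentations.
#'
#' @param cg_low,chg_low `interval_set`s from [segment_low_methylation()].
#' @return merged `interval_set` of LUMRs.
#' @export
combine_lumr <- function(cg_low, chg_low) iv_intersect(cg_low, chg_low)

#' Drop regions whose windowed mean methylation is too high
#'
#' For each region, CG and CHG sites are pooled into fixed 100-bp genomic
#' windows (aligned to absolute coordinates); each window's mean frequency
#' is coverage-weighted, and the region score is the average over its
#' windows. Regions scoring at or above `max_mean` are dropped. Regions
#' containing no covered site are retained with a warning (they cannot be
#' contradicted), and near-threshold regions are flagged.
#'
#' @param regions an `interval_set`.
#' @param sites a `methylation_sites` data frame.
#' @param max_mean inclusive ceiling on the region score.
#' @param window window width in bp.
#' @return the retained `interval_set`, with attributes `score` (per
#'   retained region) and `boundary` (scores within 0.02 of the ceiling).
#' @export
filter_mean_methylation <- function(regions, sites, max_mean = 0.20,
                                    window = 100L) {
  if (nrow(regions) == 0) return(regions)
  s <- sites[sites$context %in% c("CG", "CHG") & sites$coverage > 0, ,
             drop = FALSE]
  score <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    sel <- s$chrom == regions$chrom[i] & s$pos >= regions$start[i] &
      s$pos < regions$end[i]
    if (!any(sel)) {
      score[i] <- NA_real_
      next
    }
    sr <- s[sel, , drop = FALSE]
    win <- sr$pos %/% window
    wmean <- tapply(sr$frequency * sr$coverage, win, sum) /
      tapply(sr$coverage, win, sum)
    score[i] <- mean(wmean)
  }
  if (anyNA(score))
    warning(sum(is.na(score)),
            " region(s) without covered sites retained unfiltered")
  keep <- is.na(score) | score < max_mean
  out <- as_interval_set(as.data.frame(regions)[keep, , drop = FALSE],
                         merged = !is.null(attr(regions, "merged")))
  attr(out, "score") <- score[keep]
  attr(out, "boundary") <- !is.na(score[keep]) &
    abs(score[keep] - max_mean) <= 0.02
  out
}

#' Call low and unmethylated regions (LUMRs)
#'
#' Convenience wrapper: segments CG and CHG contexts independently at the
#' configured threshold, intersects them, and applies the windowed mean
#' methylation filter.
#'
#' @param sites a `methylation_sites` data frame.
#' @param config a [pipeline_config()].
#' @return merged `interval_set` of LUMRs.
#' @export
call_lumrs <- function(sites, config = pipeline_config()) {
  cg <- segment_low_methylation(sites, "CG", config$methylation_threshold,
                                config$lumr_min_sites, config$lumr_max_gap_bp)
  chg <- segment_low_methylation(sites, "CHG", config$methylation_threshold,
                                 config$lumr_min_sites, config$lumr_max_gap_bp)
  lumr <- combine_lumr(cg, chg)
  filter_mean_methylation(lumr, sites, config$methylation_threshold,
                          config$methylation_window_bp)
}

#' Windowed methylation signal track
#'
#' Mean methylation frequency per fixed genomic window for one context,
#' as a `signal_track` (for metaplots and heatmaps).
#'
#' @param sites a `methylation_sites` data frame.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param window window width in bp.
#' @param genome optional named chromosome lengths.
#' @return a `signal_track` of window means.
#' @export
methylation_track <- function(sites, context, window = 100L,
                              genome = NULL) {
  s <- sites[sites$context == context & sites$coverage > 0, , drop = FALSE]
  if (nrow(s) == 0)
    return(signal_track(data.frame(chrom = character(), start = integer(),
                                   end = integer(), value = numeric()),
                        genome))
  key <- paste(s$chrom, s$pos %/% window)
  agg_f <- tapply(s$frequency * s$coverage, key, sum)
  agg_c <- tapply(s$coverage, key, sum)
  parts <- strsplit(names(agg_f), " ", fixed = TRUE)
  steps <- data.frame(
    chrom = vapply(parts, `[[`, character(1), 1L),
    start = as.integer(vapply(parts, `[[`, character(1), 2L)) * window,
    value = as.numeric(agg_f / agg_c), stringsAsFactors = FALSE)
  steps$end <- steps$start + window
  if (!is.null(genome)) steps$end <- pmin(steps$end, genome[steps$chrom])
  signal_track(steps[, c("chrom", "start", "end", "value")], genome)
}
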