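#' Orient DHSs by flanking H3K9ac asymmetry
#'
#' For each DHS the mean H3K9ac signal is computed over the `flank`-bp
#' windows immediately upstream (`[start - flank, start)`) and downstream
#' (`[end, end + flank)`). The side with the higher mean is defined as the
#' 3' end: rows where the upstream flank is higher are marked `flip`,
#' otherwise `keep` (exact ties keep, flagged). A DHS is `eligible` for
#' asymmetry classification when its higher flank reaches `min_rpm`;
#' it is `asymmetric` when additionally the ratio of the higher to the
#' lower flank mean is at least `fold` (a zero lower flank counts as
#' asymmetric). Flanks running past a chromosome edge are clipped
#' (zero-padded) and flagged.
#'
#' @param dhs an `interval_set` of DHSs.
#' @param k9_track H3K9ac `signal_track`.
#' @param flank flank width in bp.
#' @param min_rpm eligibility floor on the higher flank mean (RPM).
#' @param fold minimum high/low ratio for an asymmetry call.
#' @return A data frame of class `oriented_dhs`: coordinates,
#'   `flank_up_rpm`, `flank_down_rpm`, `orientation` (`keep`/`flip`),
#'   `eligible`, `asymmetric`, `tie`, `clipped`.
#' @export
orient_dhs <- function(dhs, k9_track, flank = 300L, min_rpm = 0.5,
                       fold = 2.0) {
  stopifnot(flank > 0)
  n <- nrow(dhs)
  up <- numeric(n); dn <- numeric(n); clipped <- logical(n)
  for (i in seq_len(n)) {
    ch <- dhs$chrom[i]
    bound <- if (!is.null(k9_track$genome) && ch %in% names(k9_track$genome))
      k9_track$genome[[ch]] else Inf
    us <- dhs$start[i] - flank
    de <- dhs$end[i] + flank
    clipped[i] <- us < 0 || de > bound
    up[i] <- mean(track_window(k9_track, ch, us, dhs$start[i]))
    dn[i] <- mean(track_window(k9_track, ch, dhs$end[i], de))
  }
  tie <- up == dn
  orientation <- ifelse(!tie & up > dn, "flip", "keep")
  hi <- pmax(up, dn); lo <- pmin(up, dn)
  eligible <- hi >= min_rpm
  asymmetric <- eligible & (lo == 0 | hi / pmax(lo, .Machine$double.xmin)
                            >= fold)
  out <- data.frame(chrom = dhs$chrom, start = dhs$start, end = dhs$end,
                    flank_up_rpm = up, flank_down_rpm = dn,
                    orientation = orientation, eligible = eligible,
                    asymmetric = asymmetric, tie = tie, clipped = clipped,
                    stringsAsFactors = FALSE)
  if (!is.null(dhs[["name"]])) out$name <- dhs$name
  class(out) <- c("oriented_dhs", "data.frame")
  out
}

# mean signal per bin for one feature body scaled to `body_bins` bins;
# features shorter than body_bins are linearly interpolated per bp.
.scaled_body <- function(w, body_bins) {
  len <- length(w)
  if (len >= body_bins) {
    br <- round(seq(0, len, length.out = body_bins + 1))
    vapply(seq_len(body_bins), function(b)
      mean(w[(br[b] + 1):br[b + 1]]), numeric(1))
  } else if (len == 1) {
    rep(w, body_bins)
  } else {
    stats::approx(seq_len(len), w, xout = seq(1, len,
                                              length.out = body_bins))$y
  }
}

#' Scaled signal matrix around features
#'
#' Builds the heatmap input: per feature, fixed-width bins over the
#' upstream flank, equal-occupancy bins over the feature body scaled to a
#' common width, and fixed-width bins over the downstream flank. Rows
#' marked `flip` are reversed so all rows share the 5'-to-3' orientation
#' defined by [orient_dhs()] (or by gene strand).
#'
#' @param features an `interval_set` (or `oriented_dhs`).
#' @param track a `signal_track` (RPM, methylation frequency, or 0/1 TE
#'   presence).
#' @param flank_bp flank width either side.
#' @param body_bins number of scaled bins across the feature body.
#' @param flank_bin_bp width of each fixed flank bin (must divide
#'   `flank_bp`).
#' @param orientation optional character vector (`"keep"`/`"flip"`) per
#'   feature; taken from the `orientation` column when present.
#' @return numeric matrix, one row per feature, with attributes
#'   `n_flank_bins` and `body_bins`.
#' @export
build_profile_matrix <- function(features, track, flank_bp = 1000L,
                                 body_bins = 50L, flank_bin_bp = 20L,
                                 orientation = NULL) {
  if (flank_bp %% flank_bin_bp != 0)
    stop("flank_bin_bp must divide flank_bp")
  nf <- flank_bp %/% flank_bin_bp
  if (is.null(orientation))
    orientation <- if (!is.null(features[["orientation"]]))
      features$orientation else rep("keep", nrow(features))
  n <- nrow(features)
  mat <- matrix(0, nrow = n, ncol = 2 * nf + body_bins)
  for (i in seq_len(n)) {
    ch <- features$chrom[i]; s <- features$start[i]; e <- features$end[i]
    wu <- track_window(track, ch, s - flank_bp, s)
    wd <- track_window(track, ch, e, e + flank_bp)
    ub <- colMeans(matrix(wu, nrow = flank_bin_bp))
    db <- colMeans(matrix(wd, nrow = flank_bin_bp))
    bb <- .scaled_body(track_window(track, ch, s, e), body_bins)
    row <- c(ub, bb, db)
    if (orientation[i] == "flip") row <- rev(row)
    mat[i, ] <- row
  }
  colnames(mat) <- c(sprintf("u%d", seq_len(nf)),
                     sprintf("b%d", seq_len(body_bins)),
                     sprintf("d%d", seq_len(nf)))
  if (!is.null(features[["name"]])) rownames(mat) <- features$name
  attr(mat, "n_flank_bins") <- nf
  attr(mat, "body_bins") <- body_bins
  mat
}

#' k-means signal-profile categories
#'
#' Clusters profile rows (typically the H3K9ac matrix) into `k` categories
#' with k-means, then relabels clusters deterministically by descending
#' mean enrichment so category 1 is the strongest. The returned labels are
#' reused to order companion matrices (DNase, methylation, TE presence,
#' transcripts). Deterministic given `seed`.
#'
#' @param mat matrix from [build_profile_matrix()].
#' @param k number of categories.
#' @param seed integer seed.
#' @return list with `labels` (integer 1..k per row), `centers` (k x bins
#'   mean profile per category, ordered by label) and `sizes`.
#' @export
kmeans_categories <- function(mat, k = 4L, seed = 1L) {
  if (k > nrow(mat)) stop("k exceeds the number of rows")
  distinct <- unique(mat)
  if (nrow(distinct) < k) {
    warning("fewer distinct profiles than k; assigning by distinct profile")
    key <- apply(mat, 1, paste, collapse = ",")
    ukey <- unique(key)
    means <- vapply(ukey, function(u) mean(mat[key == u, , drop = FALSE]),
                    numeric(1))
    ord <- order(-means)
    labels <- match(key, ukey[ord])
    centers <- distinct[match(ukey[ord], apply(distinct, 1, paste,
                                               collapse = ",")), ,
                        drop = FALSE]
    return(list(labels = labels, centers = centers,
                sizes = as.integer(table(factor(labels,
                                                levels = seq_len(k))))))
  }
  set.seed(seed)
  km <- stats::kmeans(mat, centers = k, nstart = 10, iter.max = 100)
  ord <- order(-rowMeans(km$centers))
  relabel <- match(seq_len(k), ord)
  labels <- relabel[km$cluster]
  centers <- km$centers[ord, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  list(labels = labels, centers = centers,
       sizes = as.integer(table(factor(labels, levels = seq_len(k)))))
}

#' Bin genes by expression level
#'
#' Bin 0 contains genes below `min_rpkm` (including unexpressed genes);
#' the remaining genes are split into `n_var_bins` equal-count bins by
#' ascending RPKM (bin sizes differ by at most one after ties).
#'
#' @param expr expression table (see [read_expression()]).
#' @param tissue tissue column to bin on.
#' @param n_var_bins number of equal-count bins above the floor.
#' @param min_rpkm expression floor defining bin 0.
#' @return data frame `gene_id`, `rpkm`, `bin` (0..n_var_bins), with an
#'   attribute `thresholds` (upper RPKM bound per bin).
#' @export
expression_bins <- function(expr, tissue, n_var_bins = 6L, min_rpkm = 1.0) {
  if (!tissue %in% names(expr)) stop("no expression column for ", tissue)
  rpkm <- expr[[tissue]]
  if (any(rpkm < 0)) stop("RPKM must be >= 0")
  bin <- integer(length(rpkm))
  hi <- which(rpkm >= min_rpkm)
  if (length(hi) < n_var_bins)
    stop("fewer than ", n_var_bins, " genes at or above ", min_rpkm,
         " RPKM")
  sizes <- diff(round(seq(0, length(hi), length.out = n_var_bins + 1)))
  ord <- hi[order(rpkm[hi], expr$gene_id[hi])]
  bin[ord] <- rep(seq_len(n_var_bins), times = sizes)
  out <- data.frame(gene_id = expr$gene_id, rpkm = rpkm, bin = bin,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(min_rpkm,
                               tapply(rpkm[ord],
                                      rep(seq_len(n_var_bins), sizes), max))
  out
}

#' Expression-binned gene metaprofiles
#'
#' Average signal over scaled gene bodies and 1-kb flanks, per expression
#' bin, oriented 5' to 3' by gene strand.
#'
#' @param genes a `gene_models` object.
#' @param track a `signal_track`.
#' @param bins result of [expression_bins()].
#' @param flank_bp,body_bins,flank_bin_bp see [build_profile_matrix()].
#' @return matrix with one row per bin (rownames `bin0`, `bin1`, ...);
#'   rows for empty bins are `NaN` and flagged via the `empty_bins`
#'   attribute.
#' @export
gene_metaprofile <- function(genes, track, bins, flank_bp = 1000L,
                             body_bins = 50L, flank_bin_bp = 20L) {
  g <- genes$genes
  b <- bins$bin[match(g$gene_id, bins$gene_id)]
  keep <- !is.na(b)
  g <- g[keep, , drop = FALSE]; b <- b[keep]
  iv <- data.frame(chrom = g$chrom, start = g$start, end = g$end)
  orientation <- ifelse(g$strand == "-", "flip", "keep")
  mat <- build_profile_matrix(iv, track, flank_bp, body_bins, flank_bin_bp,
                              orientation = orientation)
  levels <- sort(unique(bins$bin))
  prof <- t(vapply(levels, function(l) {
    rows <- which(b == l)
    if (length(rows) == 0) rep(NaN, ncol(mat)) else
      colMeans(mat[rows, , drop = FALSE])
  }, numeric(ncol(mat))))
  rownames(prof) <- paste0("bin", levels)
  attr(prof, "empty_bins") <- rownames(prof)[apply(is.nan(prof), 1, all)]
  prof
}
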