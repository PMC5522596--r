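#' Rounded percentages, reproducing printed table values
#'
#' Computes `100 * numerator / denominator` rounded half-away-from-zero to
#' the requested number of decimals (1 for tables, 0 for prose-style
#' counts). Banker's rounding (the R default in `round()`) is deliberately
#' not used: half-away-from-zero is what reproduces printed values such as
#' 22% from 38/175.
#'
#' @param numerator,denominator counts; `denominator > 0`.
#' @param decimals decimal places.
#' @return numeric percentage.
#' @examples
#' percent(9057, 9212, 1)  # 98.3
#' percent(38, 175, 0)     # 22
#' @export
percent <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  x <- 100 * numerator / denominator
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Region-overlap summary table
#'
#' Builds the bookkeeping table for one assay's consensus regions: one row
#' per tissue, one for regions common to both tissues (>= 1 bp overlap,
#' counted in the first tissue's coordinates) and one for the union of the
#' two tissue sets (overlapping regions merged, hence `Total` can be
#' smaller than the sum of the tissue counts). Columns count regions
#' overlapping (>= 1 bp) the LUMR set and the other assay's regions, with
#' percentages at 1 decimal.
#'
#' @param regions named list (two tissues) of the assay's consensus
#'   `interval_set`s.
#' @param other named list (same tissues) of the other assay's regions.
#' @param lumrs `interval_set` of LUMRs.
#' @return data frame with rows tissue1, tissue2, `Common`, `Total`.
#' @export
overlap_table <- function(regions, other, lumrs) {
  tissues <- names(regions)
  stopifnot(length(tissues) == 2)
  row_for <- function(label, set, other_set) {
    n <- nrow(set)
    nl <- sum(iv_overlaps_any(set, lumrs))
    no <- sum(iv_overlaps_any(set, other_set))
    data.frame(group = label, all = n,
               lumr_n = nl, lumr_pct = if (n > 0) percent(nl, n, 1) else 0,
               other_n = no,
               other_pct = if (n > 0) percent(no, n, 1) else 0,
               stringsAsFactors = FALSE)
  }
  t1 <- regions[[tissues[1]]]; t2 <- regions[[tissues[2]]]
  common <- as_interval_set(
    as.data.frame(t1)[iv_overlaps_any(t1, t2), , drop = FALSE])
  total <- iv_merge(as_interval_set(rbind(as.data.frame(t1)[, 1:3],
                                          as.data.frame(t2)[, 1:3])))
  other_union <- iv_merge(as_interval_set(rbind(
    as.data.frame(other[[tissues[1]]])[, 1:3],
    as.data.frame(other[[tissues[2]]])[, 1:3])))
  rbind(row_for(tissues[1], t1, other[[tissues[1]]]),
        row_for(tissues[2], t2, other[[tissues[2]]]),
        row_for("Common", common, other_union),
        row_for("Total", total, other_union))
}

#' TE-overlap summary per superfamily
#'
#' Tabulates, per tissue, how many candidates fully sit within a TE, are
#' at least 80% contained, or overlap by at least 1 bp, split by TE
#' superfamily, with percentages of the tissue's candidate total.
#'
#' @param containment per-tissue named list of [te_containment()] results.
#' @param totals named integer vector: candidates per tissue.
#' @return long-format data frame: `tissue`, `superfamily`, `category`,
#'   `count`, `pct`.
#' @export
te_overlap_table <- function(containment, totals) {
  rows <- list()
  for (t in names(containment)) {
    ct <- containment[[t]]
    sups <- sort(unique(stats::na.omit(ct$te_superfamily)))
    for (s in sups) {
      sel <- !is.na(ct$te_superfamily) & ct$te_superfamily == s
      for (cat in c("fully_within", "contained")) {
        cnt <- sum(ct[[cat]] & sel)
        rows[[length(rows) + 1]] <- data.frame(
          tissue = t, superfamily = s, category = cat, count = cnt,
          pct = percent(cnt, totals[[t]], 1), stringsAsFactors = FALSE)
      }
    }
    cnt <- sum(ct$any_overlap)
    rows[[length(rows) + 1]] <- data.frame(
      tissue = t, superfamily = "all", category = "any_overlap",
      count = cnt, pct = percent(cnt, totals[[t]], 1),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Distance of candidates to their closest genes
#'
#' Distance is the gap to the closer of the two flanking genes (0 when
#' abutting). Also counts candidates more than 5 kb and more than 10 kb
#' away from their closest gene.
#'
#' @param candidates data frame with `chrom`, `start`, `end`.
#' @param genes a `gene_models` object or gene `interval_set`.
#' @return list: `distances` (per candidate, NA when no flanking gene),
#'   `median`, `max`, `n_beyond_5kb`, `n_beyond_10kb`.
#' @export
distance_stats <- function(candidates, genes) {
  gs <- if (inherits(genes, "gene_models")) gene_spans(genes) else genes
  iv <- interval_set(candidates$chrom, candidates$start, candidates$end)
  fl <- nearest_flanking(iv, gs)
  d_sorted <- pmin(fl$upstream_dist, fl$downstream_dist, na.rm = TRUE)
  d_sorted[is.na(fl$upstream_dist) & is.na(fl$downstream_dist)] <- NA
  d <- rep(NA_real_, nrow(candidates))
  d[order(candidates$chrom, candidates$start, candidates$end)] <- d_sorted
  list(distances = d, median = stats::median(d, na.rm = TRUE),
       max = if (all(is.na(d))) NA_real_ else max(d, na.rm = TRUE),
       n_beyond_5kb = sum(d > 5000, na.rm = TRUE),
       n_beyond_10kb = sum(d > 10000, na.rm = TRUE))
}
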