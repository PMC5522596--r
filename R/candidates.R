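#' Integrate LUMRs, DHSs and H3K9ac regions into enhancer candidates
#'
#' A LUMR becomes an enhancer candidate in a tissue when it overlaps (by at
#' least 1 bp) both a consensus DHS and a consensus H3K9ac region of that
#' tissue, and overlaps no exonic, intronic or promoter base. Candidate
#' coordinates are the LUMR coordinates.
#'
#' @param lumrs merged `interval_set` of LUMRs (tissue-independent).
#' @param dhs named list (by tissue) of consensus DHS `interval_set`s.
#' @param k9 named list (by tissue, same names) of consensus H3K9ac sets.
#' @param partition a [partition_genome()] result used for the
#'   genic/promoter exclusion.
#' @return A data frame of class `enhancer_candidates`: `chrom`, `start`,
#'   `end`, one logical detection column per tissue, and `specificity`
#'   (filled by [classify_specificity()]).
#' @export
integrate_candidates <- function(lumrs, dhs, k9, partition) {
  tissues <- names(dhs)
  if (is.null(tissues) || !identical(sort(tissues), sort(names(k9))))
    stop("dhs and k9 must be named lists over the same tissues")
  if (length(tissues) == 0) stop("no tissue inputs")
  excl <- iv_merge(as_interval_set(rbind(
    as.data.frame(partition$exon)[, 1:3],
    as.data.frame(partition$intron)[, 1:3],
    as.data.frame(partition$promoter)[, 1:3])))
  intergenic <- !iv_overlaps_any(lumrs, excl)
  out <- data.frame(chrom = lumrs$chrom, start = lumrs$start,
                    end = lumrs$end, stringsAsFactors = FALSE)
  any_tissue <- rep(FALSE, nrow(out))
  for (t in tissues) {
    det <- intergenic & iv_overlaps_any(lumrs, dhs[[t]]) &
      iv_overlaps_any(lumrs, k9[[t]])
    out[[t]] <- det
    any_tissue <- any_tissue | det
  }
  out <- out[any_tissue, , drop = FALSE]
  rownames(out) <- NULL
  out$specificity <- NA_character_
  class(out) <- c("enhancer_candidates", "data.frame")
  classify_specificity(out)
}

#' Label candidates as tissue-specific or shared
#'
#' A candidate detected in exactly one tissue is `<tissue>-specific`; a
#' candidate detected in both is `shared`. Counts satisfy
#' `union = specific_1 + specific_2 + shared` exactly, since the same LUMR
#' region underlies both tissues.
#'
#' @param candidates an `enhancer_candidates` data frame.
#' @return the input with its `specificity` column filled.
#' @export
classify_specificity <- function(candidates) {
  tissues <- candidate_tissues(candidates)
  det <- as.matrix(as.data.frame(candidates)[, tissues, drop = FALSE])
  n_det <- rowSums(det)
  spec <- rep("shared", nrow(candidates))
  for (t in tissues) spec[n_det == 1 & det[, t]] <- paste0(t, "-specific")
  candidates$specificity <- spec
  candidates
}

candidate_tissues <- function(candidates) {
  setdiff(names(candidates),
          c("chrom", "start", "end", "specificity", "candidate_id",
            "dnase_diff", "k9_diff", "dnase_rank", "k9_rank", "rank_sum",
            "overall_rank", "rank_p", "cns"))
}

#' @export
print.enhancer_candidates <- function(x, ...) {
  tt <- candidate_tissues(x)
  cat(sprintf("enhancer_candidates: %d region(s)\n", nrow(x)))
  if (nrow(x) > 0) print(table(x$specificity))
  invisible(x)
}

#' Rank candidates by tissue contrast
#'
#' For every candidate detected in `tissue`, the DNase and H3K9ac
#' tissue-contrast is the largest per-bp signed difference
#' (tissue minus the other tissue) over the candidate region. Candidates
#' are ranked separately on each contrast (largest difference = rank 1),
#' the two ranks are summed, and the final rank is the ascending rank of
#' the sum (ties broken by DNase rank, then chromosome, then start).
#' Candidate ids combine the first letter of the tissue with the final
#' rank (e.g. `V2`, `H1233`). Shared candidates are ranked in both
#' tissues' lists.
#'
#' @param candidates an `enhancer_candidates` data frame.
#' @param tissue tissue to rank (one of the detection columns).
#' @param dnase_tracks,k9_tracks named lists (by tissue) of `signal_track`s
#'   covering both tissues.
#' @return A data frame (one row per candidate detected in `tissue`):
#'   coordinates, `specificity`, contrasts, ranks, `rank_sum`,
#'   `overall_rank` and `candidate_id`.
#' @export
rank_candidates <- function(candidates, tissue, dnase_tracks, k9_tracks) {
  tissues <- candidate_tissues(candidates)
  if (!tissue %in% tissues) stop("unknown tissue: ", tissue)
  other <- setdiff(tissues, tissue)
  if (length(other) != 1) stop("ranking requires exactly two tissues")
  sel <- which(candidates[[tissue]])
  cc <- as.data.frame(candidates)[sel, c("chrom", "start", "end",
                                         "specificity"), drop = FALSE]
  if (nrow(cc) == 0) return(cc)
  iv <- cc[, c("chrom", "start", "end")]
  cc$dnase_diff <- track_max_diff(dnase_tracks[[tissue]],
                                  dnase_tracks[[other]], iv)
  cc$k9_diff <- track_max_diff(k9_tracks[[tissue]], k9_tracks[[other]], iv)
  ord_d <- order(-cc$dnase_diff, cc$chrom, cc$start)
  cc$dnase_rank <- integer(nrow(cc)); cc$dnase_rank[ord_d] <- seq_len(nrow(cc))
  ord_k <- order(-cc$k9_diff, cc$chrom, cc$start)
  cc$k9_rank <- integer(nrow(cc)); cc$k9_rank[ord_k] <- seq_len(nrow(cc))
  cc$rank_sum <- cc$dnase_rank + cc$k9_rank
  ord_s <- order(cc$rank_sum, cc$dnase_rank, cc$chrom, cc$start)
  cc$overall_rank <- integer(nrow(cc))
  cc$overall_rank[ord_s] <- seq_len(nrow(cc))
  cc$candidate_id <- paste0(toupper(substr(tissue, 1, 1)), cc$overall_rank)
  rownames(cc) <- NULL
  cc
}

#' Permutation p-values for rank sums
#'
#' The null re-creates the ranking experiment: `n_lists` independent
#' uniform permutations of 1..N are summed position-wise and the sums
#' sorted ascending; this is repeated `n_perm` times. A candidate whose
#' observed sum `s` sits at ascending rank `r` receives
#' `p = (1 + #\{null r-th smallest sum <= s\}) / (n_perm + 1)`, the
#' add-one empirical estimator, so p is never exactly 0 and lies in
#' (0, 1]. Deterministic given `seed`.
#'
#' Because rank sums are integers with heavy ties, the add-one estimator
#' is conservative (super-uniform under the null); `estimator = "mid"`
#' applies the Lancaster mid-p continuity correction, which is the
#' appropriate variant when assessing calibration against Uniform(0, 1).
#'
#' @param rank_sums observed rank sums, one per candidate (any order).
#' @param n_lists number of feature rankings summed (2, or 3 when a tissue
#'   had three replicate-derived rankings).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param estimator `"add_one"` (default, reported p-values) or `"mid"`
#'   (continuity-corrected, for calibration checks).
#' @return numeric p-values aligned with `rank_sums`.
#' @export
rank_permutation_p <- function(rank_sums, n_lists = 2, n_perm = 1000,
                               seed = 1, estimator = c("add_one", "mid")) {
  estimator <- match.arg(estimator)
  N <- length(rank_sums)
  if (N == 0) return(numeric())
  if (!is.null(seed)) set.seed(seed)
  null_sorted <- matrix(0L, nrow = n_perm, ncol = N)
  for (b in seq_len(n_perm)) {
    s <- integer(N)
    for (l in seq_len(n_lists)) s <- s + sample.int(N)
    null_sorted[b, ] <- sort(s)
  }
  r <- rank(rank_sums, ties.method = "first")
  s_sorted <- sort(rank_sums)
  p_by_rank <- vapply(seq_len(N), function(rr) {
    v <- null_sorted[, rr]
    if (estimator == "add_one")
      (1 + sum(v <= s_sorted[rr])) / (n_perm + 1)
    else
      (sum(v < s_sorted[rr]) + 0.5 * sum(v == s_sorted[rr])) / n_perm
  }, numeric(1))
  p_by_rank[r]
}
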