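#' Baseline TE set for family enrichment
#'
#' Prepares the baseline against which family enrichment is tested:
#' nested TE insertions are resolved by keeping the outermost element and
#' excluding elements fully contained in another TE; TEs fully inside
#' introns are dropped; and TEs must be longer than `min_len` bp (long
#' enough that a short enhancer candidate could still be 80% contained).
#'
#' @param tes a `te_annotation` data frame.
#' @param introns `interval_set` of introns (may be empty or `NULL`).
#' @param min_len strict length floor in bp.
#' @return the filtered `te_annotation`.
#' @export
te_baseline <- function(tes, introns = NULL, min_len = 635L) {
  df <- as.data.frame(tes)
  n <- nrow(df)
  nested <- logical(n)
  for (ch in unique(df$chrom)) {
    i <- which(df$chrom == ch)
    ir <- IRanges::IRanges(df$start[i] + 1L, df$end[i])
    hits <- IRanges::findOverlaps(ir, ir, type = "within")
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    keep <- qi != si &
      (IRanges::width(ir)[si] > IRanges::width(ir)[qi] |
         (IRanges::width(ir)[si] == IRanges::width(ir)[qi] & si < qi))
    nested[i[unique(qi[keep])]] <- TRUE
  }
  df <- df[!nested, , drop = FALSE]
  if (!is.null(introns) && nrow(introns) > 0 && nrow(df) > 0) {
    iv <- interval_set(df$chrom, df$start, df$end)
    ovb <- iv_overlap_bp(iv, introns)
    # iv is sorted; map back to df row order
    ord <- order(df$chrom, df$start, df$end)
    inside <- logical(nrow(df))
    inside[ord] <- ovb == (iv$end - iv$start)
    df <- df[!inside, , drop = FALSE]
  }
  df <- df[df$end - df$start > min_len, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("te_annotation", "data.frame")
  df
}

#' TE containment of enhancer candidates
#'
#' Reports, per candidate, the single TE (if any) containing at least
#' `min_frac` of the candidate's length, plus any-overlap and
#' full-containment tallies and the candidate's relative position within
#' the TE (for randomness checks of positions within elements).
#'
#' @param candidates data frame with `chrom`, `start`, `end` and
#'   optionally `candidate_id`.
#' @param tes a `te_annotation` data frame.
#' @param min_frac containment fraction of the candidate length.
#' @return A data frame, one row per candidate: `any_overlap`,
#'   `contained` (>= `min_frac` within a single TE), `fully_within`,
#'   `te_family`, `te_superfamily`, `overlap_frac`, `position_frac`.
#' @export
te_containment <- function(candidates, tes, min_frac = 0.80) {
  n <- nrow(candidates)
  out <- data.frame(
    candidate_id = if (!is.null(candidates[["candidate_id"]]))
      candidates$candidate_id else sprintf("cand_%d", seq_len(n)),
    any_overlap = logical(n), contained = logical(n),
    fully_within = logical(n), te_family = NA_character_,
    te_superfamily = NA_character_, overlap_frac = 0,
    position_frac = NA_real_, stringsAsFactors = FALSE)
  if (n == 0 || nrow(tes) == 0) return(out)
  for (i in seq_len(n)) {
    len <- candidates$end[i] - candidates$start[i]
    sel <- tes$chrom == candidates$chrom[i] &
      tes$start < candidates$end[i] & tes$end > candidates$start[i]
    if (!any(sel)) next
    out$any_overlap[i] <- TRUE
    ov <- pmin(tes$end[sel], candidates$end[i]) -
      pmax(tes$start[sel], candidates$start[i])
    best <- which.max(ov)
    out$overlap_frac[i] <- ov[best] / len
    if (ov[best] >= min_frac * len) {
      out$contained[i] <- TRUE
      out$fully_within[i] <- ov[best] == len
      out$te_family[i] <- tes$family[sel][best]
      out$te_superfamily[i] <- tes$superfamily[sel][best]
      mid <- candidates$start[i] + len / 2
      out$position_frac[i] <- (mid - tes$start[sel][best]) /
        (tes$end[sel][best] - tes$start[sel][best])
    }
  }
  out
}

#' TE family enrichment for enhancer-containing elements
#'
#' Given the baseline TE set and a flag marking which baseline elements
#' contain an enhancer candidate, tests each family for enrichment under a
#' binomial model: with `K` enhancer-containing TEs among `M` baseline
#' elements, the number from a family of `M_f` members is
#' Binomial(K, M_f / M) under the null, and `p = P(X >= k_f)`. Bonferroni
#' correction multiplies by the number of families with at least one
#' enhancer-containing member.
#'
#' @param baseline a filtered `te_annotation` (see [te_baseline()]).
#' @param contains logical vector over baseline rows: element contains
#'   (at least 80% of) an enhancer candidate.
#' @param alpha significance level on the adjusted p-value.
#' @return A data frame per family: `family`, `superfamily`, `members`,
#'   `containing`, `p`, `p_adj`, `enriched`, sorted by `p`.
#' @export
family_enrichment <- function(baseline, contains, alpha = 0.05) {
  stopifnot(length(contains) == nrow(baseline))
  M <- nrow(baseline)
  K <- sum(contains)
  fam <- unique(baseline$family)
  Mf <- vapply(fam, function(f) sum(baseline$family == f), integer(1))
  kf <- vapply(fam, function(f) sum(contains & baseline$family == f),
               integer(1))
  p <- ifelse(kf == 0 | K == 0, 1,
              stats::pbinom(kf - 1, K, Mf / M, lower.tail = FALSE))
  n_tested <- sum(kf >= 1)
  p_adj <- ifelse(kf >= 1, pmin(1, p * max(n_tested, 1)), 1)
  sup <- baseline$superfamily[match(fam, baseline$family)]
  out <- data.frame(family = fam, superfamily = sup, members = Mf,
                    containing = kf, p = p, p_adj = p_adj,
                    enriched = p_adj < alpha & kf >= 1,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact-match motif scan on both strands
#'
#' Counts exact occurrences of a motif and of its reverse complement in
#' each sequence; overlapping matches are counted.
#'
#' @param sequences a `Biostrings::DNAStringSet` or character vector.
#' @param motif non-degenerate DNA motif (default the site II motif
#'   GGCCCA; its reverse complement TGGGCC is scanned as well).
#' @return data frame with `count` and `present` per sequence.
#' @export
motif_scan <- function(sequences, motif = "GGCCCA") {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  m <- Biostrings::DNAString(motif)
  rc <- Biostrings::reverseComplement(m)
  cnt <- Biostrings::vcountPattern(m, sequences)
  if (as.character(rc) != as.character(m))
    cnt <- cnt + Biostrings::vcountPattern(rc, sequences)
  data.frame(count = cnt, present = cnt > 0)
}

# Extract the sequences of intervals from a genome DNAStringSet.
extract_sequences <- function(genome_seq, x) {
  if (nrow(x) == 0) return(Biostrings::DNAStringSet())
  miss <- setdiff(unique(x$chrom), names(genome_seq))
  if (length(miss) > 0)
    stop("chromosome(s) absent from genome sequence: ",
         paste(miss, collapse = ", "))
  Biostrings::DNAStringSet(vapply(seq_len(nrow(x)), function(i)
    as.character(Biostrings::subseq(genome_seq[[x$chrom[i]]],
                                    x$start[i] + 1L, x$end[i])),
    character(1)))
}

#' Motif enrichment against random intergenic sequence
#'
#' Compares the fraction of candidate regions containing at least one
#' motif occurrence with the same fraction in `n_draws` sets of
#' length-matched windows drawn uniformly from intergenic space. Reports
#' the fold enrichment and an empirical p (fraction of draws reaching the
#' observed fraction). Deterministic given `seed`.
#'
#' @param candidates data frame with `chrom`, `start`, `end`.
#' @param genome_seq named `DNAStringSet` of chromosome sequences.
#' @param intergenic an `interval_set` from which random windows are drawn.
#' @param n_draws number of random draws.
#' @param seed integer seed.
#' @param motif motif to scan.
#' @return list: `observed_frac`, `null_mean_frac`, `fold`, `p`,
#'   `motif_found` (FALSE when the motif occurs nowhere, in which case
#'   `fold` is `NaN`).
#' @export
motif_enrichment <- function(candidates, genome_seq, intergenic,
                             n_draws = 1000, seed = 1, motif = "GGCCCA") {
  if (!is.null(seed)) set.seed(seed)
  obs <- motif_scan(extract_sequences(genome_seq, candidates), motif)
  obs_frac <- mean(obs$present)
  lens <- candidates$end - candidates$start
  seg <- as.data.frame(iv_merge(intergenic))
  seg_len <- seg$end - seg$start
  if (max(seg_len) < max(lens))
    stop("insufficient intergenic space for length-matched draws")
  null_frac <- numeric(n_draws)
  for (d in seq_len(n_draws)) {
    windows <- vapply(seq_along(lens), function(j) {
      ok <- which(seg_len >= lens[j])
      w <- seg_len[ok] - lens[j] + 1
      si <- ok[sample.int(length(ok), 1, prob = w)]
      s0 <- seg$start[si] + sample.int(seg_len[si] - lens[j] + 1, 1) - 1L
      as.character(Biostrings::subseq(genome_seq[[seg$chrom[si]]],
                                      s0 + 1L, s0 + lens[j]))
    }, character(1))
    null_frac[d] <- mean(motif_scan(windows, motif)$present)
  }
  motif_found <- obs_frac > 0 || any(null_frac > 0)
  fold <- if (!motif_found) NaN else obs_frac / mean(null_frac)
  list(observed_frac = obs_frac, null_mean_frac = mean(null_frac),
       fold = fold, p = mean(null_frac >= obs_frac),
       motif_found = motif_found, n_draws = n_draws)
}

# Core placement on precomputed merged segments (chrom/start/end columns).
# Returns a plain data frame; features never overlap each other.
.place_lengths <- function(lengths, seg, max_retries = 1000) {
  seg_len <- seg$end - seg$start
  if (max(seg_len) < max(lengths))
    stop("feature longer than the largest mask segment")
  n <- length(lengths)
  out_chrom <- character(n); out_s <- integer(n)
  occ_s <- list(); occ_e <- list()
  for (j in order(-lengths)) {   # longest first keeps tight masks feasible
    L <- lengths[j]
    ok <- which(seg_len >= L)
    w <- seg_len[ok] - L + 1
    tries <- 0
    repeat {
      tries <- tries + 1
      if (tries > max_retries)
        stop("could not place feature of length ", L,
             " without overlap after ", max_retries, " retries")
      si <- ok[sample.int(length(ok), 1, prob = w)]
      s0 <- seg$start[si] + sample.int(seg_len[si] - L + 1, 1) - 1L
      key <- seg$chrom[si]
      os <- occ_s[[key]]
      if (is.null(os) || !any(os < s0 + L & occ_e[[key]] > s0)) {
        occ_s[[key]] <- c(os, s0)
        occ_e[[key]] <- c(occ_e[[key]], s0 + L)
        out_chrom[j] <- key; out_s[j] <- s0
        break
      }
    }
  }
  data.frame(chrom = out_chrom, start = out_s, end = out_s + lengths,
             stringsAsFactors = FALSE)
}

#' Place features uniformly at random within a mask
#'
#' Draws length-preserved, non-overlapping features uniformly from the
#' mappable mask (rejection sampling among placed features), the
#' randomisation underlying [permutation_enrichment()].
#'
#' @param lengths integer feature lengths in bp.
#' @param mask `interval_set` to place within.
#' @param max_retries resampling attempts per feature before erroring.
#' @return an `interval_set` of placed features.
#' @export
random_placement <- function(lengths, mask, max_retries = 1000) {
  if (length(lengths) == 0) return(interval_set())
  df <- .place_lengths(lengths, as.data.frame(iv_merge(mask)), max_retries)
  interval_set(df$chrom, df$start, df$end)
}

# Fast overlap indicator of features against a precomputed merged set
# given as a list per chromosome: list(starts = sorted starts,
# emax = running maximum of ends).
.overlap_index <- function(merged_df) {
  lapply(split(merged_df, merged_df$chrom), function(d) {
    o <- order(d$start)
    list(starts = d$start[o], emax = cummax(d$end[o]))
  })
}

.count_overlapping <- function(df, idx) {
  total <- 0L
  for (ch in unique(df$chrom)) {
    ix <- idx[[ch]]
    if (is.null(ix)) next
    sel <- df$chrom == ch
    j <- findInterval(df$end[sel] - 1L, ix$starts)
    total <- total + sum(j >= 1 & ix$emax[pmax(j, 1L)] > df$start[sel])
  }
  total
}

#' Permutation enrichment of features in a region class
#'
#' Tests whether more features overlap a region class than expected by
#' chance, by repeatedly placing length-preserved features uniformly at
#' random (non-overlapping) within the uniquely mappable genome and
#' counting overlaps. The empirical p uses the add-one estimator
#' `(1 + b) / (n + 1)` so that `p = 1/(n+1)` reports "less than 1/n" when
#' no null permutation reaches the observed count.
#'
#' Overlap counts have a discrete null, so the add-one estimator is
#' conservative; `p_mid` (Lancaster mid-p continuity correction) is
#' returned alongside for calibration assessment.
#'
#' @param features an `interval_set`.
#' @param region_class an `interval_set` (e.g. one partition class).
#' @param mask `interval_set` of mappable regions to permute within.
#' @param n number of permutations.
#' @param seed integer seed.
#' @return list: `observed`, `null_mean`, `null_sd`, `p_enrich`,
#'   `p_deplete`, `p_mid`, `n`.
#' @export
permutation_enrichment <- function(features, region_class, mask,
                                   n = 1000, seed = 1) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(features) == 0)
    return(list(observed = 0L, null_mean = 0, null_sd = 0, p_enrich = 1,
                p_deplete = 1, p_mid = 1, n = n))
  idx <- .overlap_index(as.data.frame(iv_merge(region_class)))
  fdf <- as.data.frame(features)
  observed <- .count_overlapping(fdf, idx)
  lengths <- features$end - features$start
  seg <- as.data.frame(iv_merge(mask))
  null_counts <- integer(n)
  for (b in seq_len(n))
    null_counts[b] <- .count_overlapping(.place_lengths(lengths, seg), idx)
  list(observed = observed, null_mean = mean(null_counts),
       null_sd = stats::sd(null_counts),
       p_enrich = (1 + sum(null_counts >= observed)) / (n + 1),
       p_deplete = (1 + sum(null_counts <= observed)) / (n + 1),
       p_mid = (sum(null_counts > observed) +
                  0.5 * sum(null_counts == observed)) / n,
       n = n)
}

#' Conserved non-coding sequence overlap
#'
#' Flags candidates overlapping (>= 1 bp, half-open semantics) a conserved
#' non-coding sequence.
#'
#' @param candidates data frame with `chrom`, `start`, `end`.
#' @param cns `interval_set` of CNS intervals (may be empty).
#' @return logical vector per candidate, with attribute `count`.
#' @export
cns_overlap <- function(candidates, cns) {
  n <- nrow(candidates)
  if (is.null(cns) || nrow(cns) == 0) {
    out <- rep(FALSE, n)
  } else {
    iv <- interval_set(candidates$chrom, candidates$start, candidates$end)
    hit <- iv_overlaps_any(iv, cns)
    out <- logical(n)
    out[order(candidates$chrom, candidates$start, candidates$end)] <- hit
  }
  attr(out, "count") <- sum(out)
  out
}
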