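#' Run the full enhancer prediction pipeline
#'
#' Executes the three-step integration — consensus peaks per tissue and
#' assay, LUMR calling from CG/CHG methylation, and the
#' LUMR-with-DHS-and-H3K9ac intersection excluding genic and promoter
#' regions — followed by tissue-specificity classification, contrast
#' ranking with permutation p-values, DHS orientation and k-means profile
#' categories, target-gene linking, TE containment and family enrichment,
#' optional motif enrichment and CNS flags, and the bookkeeping reports.
#'
#' @param paths named list of input paths, as returned by
#'   [generate_synthetic_data()]: `genes`, `tes`, `chrom_sizes`, `mask`,
#'   `methylation`, `expression`, per-tissue lists `dnase_peaks`,
#'   `k9_peaks` (replicate BED vectors), `dnase_tracks`, `k9_tracks`
#'   (bedGraph), and optionally `genome_fasta` and `cns`.
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, candidate tables, BEDs,
#'   reports and a run manifest are written there.
#' @param profile logical; compute orientation/heatmap matrices (the
#'   slowest optional stage).
#' @return An object of class `enhancer_scan`.
#' @export
run_enhancer_pipeline <- function(paths, config = pipeline_config(),
                                  outdir = NULL, profile = TRUE) {
  tissues <- names(paths$dnase_peaks)
  if (length(tissues) != 2 ||
      !identical(sort(tissues), sort(names(paths$k9_peaks))))
    stop("exactly two tissues with DNase and H3K9ac inputs are required")
  genome <- read_chrom_sizes(paths$chrom_sizes)
  genes <- read_gene_models(paths$genes)
  tes <- read_te_annotation(paths$tes)
  mask <- read_bed(paths$mask)
  expression <- read_expression(paths$expression)
  meth <- read_methylation(paths$methylation)

  partition <- partition_genome(genes, tes, genome, config)

  dhs_cons <- list(); k9_cons <- list()
  dnase_tracks <- list(); k9_tracks <- list()
  for (t in tissues) {
    dhs_cons[[t]] <- consensus_peaks(lapply(paths$dnase_peaks[[t]],
                                            read_bed),
                                     config$replicate_overlap_frac)
    k9_cons[[t]] <- consensus_peaks(lapply(paths$k9_peaks[[t]], read_bed),
                                    config$replicate_overlap_frac)
    dnase_tracks[[t]] <- read_bedgraph(paths$dnase_tracks[[t]], genome)
    k9_tracks[[t]] <- read_bedgraph(paths$k9_tracks[[t]], genome)
  }

  lumrs <- call_lumrs(meth, config)
  candidates <- integrate_candidates(lumrs, dhs_cons, k9_cons, partition)

  ranked <- list()
  for (t in tissues) {
    r <- rank_candidates(candidates, t, dnase_tracks, k9_tracks)
    if (nrow(r) > 0)
      r$rank_p <- rank_permutation_p(
        r$rank_sum, n_lists = 2, n_perm = config$n_permutations,
        seed = config$random_seed)
    ranked[[t]] <- r
  }

  profiles <- NULL
  if (profile) {
    profiles <- list()
    cand_iv <- interval_set(candidates$chrom, candidates$start,
                            candidates$end)
    for (t in tissues) {
      if (!any(candidates[[t]])) next
      dhs_in <- as_interval_set(as.data.frame(dhs_cons[[t]])[
        iv_overlaps_any(dhs_cons[[t]], cand_iv), , drop = FALSE])
      if (nrow(dhs_in) == 0) next
      ori <- orient_dhs(dhs_in, k9_tracks[[t]], config$orientation_flank_bp,
                        config$asym_min_rpm, config$asym_fold)
      mat <- build_profile_matrix(ori, k9_tracks[[t]],
                                  config$heatmap_flank_bp,
                                  config$body_bins, config$flank_bin_bp)
      cats <- if (nrow(mat) >= config$kmeans_k)
        kmeans_categories(mat, config$kmeans_k, config$random_seed)
      else NULL
      profiles[[t]] <- list(oriented = ori, k9_matrix = mat,
                            categories = cats)
    }
  }

  # union candidate ids: tissue-specific candidates carry their tissue id,
  # shared candidates both
  cand <- candidates
  cand$candidate_id <- NA_character_
  for (t in tissues) {
    r <- ranked[[t]]
    if (nrow(r) == 0) next
    key <- paste(r$chrom, r$start, r$end)
    m <- match(paste(cand$chrom, cand$start, cand$end), key)
    ids <- ifelse(is.na(cand$candidate_id), r$candidate_id[m],
                  paste(cand$candidate_id, r$candidate_id[m], sep = "/"))
    cand$candidate_id[!is.na(m)] <- ids[!is.na(m)]
  }

  links <- link_targets(cand, genes, expression, config)

  baseline <- te_baseline(tes, partition$intron,
                          config$te_baseline_min_len_bp)
  containment <- lapply(tissues, function(t)
    te_containment(cand[cand[[t]], , drop = FALSE], baseline,
                   config$te_containment_frac))
  names(containment) <- tissues
  cont_union <- te_containment(cand, baseline, config$te_containment_frac)
  # mark baseline TEs containing >= 80% of a candidate
  contains <- logical(nrow(baseline))
  for (i in seq_len(nrow(cand))) {
    len <- cand$end[i] - cand$start[i]
    sel <- baseline$chrom == cand$chrom[i] &
      baseline$start < cand$end[i] & baseline$end > cand$start[i]
    if (!any(sel)) next
    ov <- pmin(baseline$end[sel], cand$end[i]) -
      pmax(baseline$start[sel], cand$start[i])
    contains[which(sel)[ov >= config$te_containment_frac * len]] <- TRUE
  }
  families <- family_enrichment(baseline, contains)

  motif <- NULL
  if (!is.null(paths$genome_fasta) && file.exists(paths$genome_fasta)) {
    genome_seq <- Biostrings::readDNAStringSet(paths$genome_fasta)
    names(genome_seq) <- sub("\\s.*$", "", names(genome_seq))
    intergenic <- iv_merge(as_interval_set(rbind(
      as.data.frame(partition$flanking)[, 1:3],
      as.data.frame(partition$TE)[, 1:3],
      as.data.frame(partition$distal)[, 1:3])))
    motif <- motif_enrichment(cand, genome_seq, intergenic,
                              n_draws = config$n_permutations,
                              seed = config$random_seed)
  }

  if (!is.null(paths$cns) && file.exists(paths$cns)) {
    cns <- read_bed(paths$cns)
    cand$cns <- as.logical(cns_overlap(cand, cns))
  }

  # bookkeeping reports on intergenic (non-genic, non-promoter) regions
  intergenic_of <- function(set) {
    excl <- iv_merge(as_interval_set(rbind(
      as.data.frame(partition$exon)[, 1:3],
      as.data.frame(partition$intron)[, 1:3],
      as.data.frame(partition$promoter)[, 1:3])))
    mid <- set$start + (set$end - set$start) %/% 2L
    pts <- interval_set(set$chrom, mid, mid + 1L)
    as_interval_set(as.data.frame(set)[!iv_overlaps_any(pts, excl), ,
                                       drop = FALSE])
  }
  dhs_ig <- lapply(dhs_cons, intergenic_of)
  k9_ig <- lapply(k9_cons, intergenic_of)
  lumr_ig <- intergenic_of(lumrs)
  reports <- list(
    dhs_table = overlap_table(dhs_ig, k9_ig, lumr_ig),
    k9_table = overlap_table(k9_ig, dhs_ig, lumr_ig),
    te_table = te_overlap_table(containment, vapply(tissues, function(t)
      sum(cand[[t]]), integer(1))),
    distances = lapply(stats::setNames(tissues, tissues), function(t)
      distance_stats(cand[cand[[t]], , drop = FALSE], genes)),
    feature_distribution = list(
      dhs = lapply(dhs_cons, classify_features, partition, mask),
      lumr = classify_features(lumrs, partition, mask)))

  scan <- structure(list(
    tissues = tissues, config = config, genome = genome,
    partition = partition, dhs_consensus = dhs_cons,
    k9_consensus = k9_cons, lumrs = lumrs, candidates = cand,
    ranked = ranked, profiles = profiles, links = links,
    te_baseline = baseline, te_containment = containment,
    te_families = families, motif = motif, reports = reports),
    class = "enhancer_scan")

  if (!is.null(outdir)) write_scan_outputs(scan, paths, outdir)
  scan
}

write_scan_outputs <- function(scan, paths, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_bed(interval_set(scan$candidates$chrom, scan$candidates$start,
                         scan$candidates$end,
                         name = scan$candidates$candidate_id),
            file.path(outdir, "candidates.bed"))
  write_bed(scan$lumrs, file.path(outdir, "lumrs.bed"))
  for (t in scan$tissues) {
    r <- scan$ranked[[t]]
    safe <- gsub("[^A-Za-z0-9]+", "", t)
    if (nrow(r) > 0) {
      out <- r[, c("chrom", "start", "end", "candidate_id", "dnase_rank",
                   "k9_rank", "rank_sum", "overall_rank", "rank_p")]
      utils::write.table(out, file.path(outdir,
                                        sprintf("candidates_%s.tsv", safe)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_bed(scan$dhs_consensus[[t]],
              file.path(outdir, sprintf("dhs_consensus_%s.bed", safe)))
    write_bed(scan$k9_consensus[[t]],
              file.path(outdir, sprintf("k9_consensus_%s.bed", safe)))
  }
  utils::write.table(scan$links, file.path(outdir, "target_links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scan$te_families,
                     file.path(outdir, "te_family_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (cl in names(scan$partition))
    write_bed(scan$partition[[cl]],
              file.path(outdir, sprintf("partition_%s.bed", cl)))
  manifest <- list(
    inputs = rapply(paths, as.character, how = "unlist"),
    config = unclass(scan$config),
    seed = scan$config$random_seed,
    package = "enhscan",
    version = as.character(utils::packageVersion("enhscan")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.enhancer_scan <- function(x, ...) {
  cat("enhancer_scan\n")
  cat(sprintf("  tissues:    %s\n", paste(x$tissues, collapse = ", ")))
  cat(sprintf("  LUMRs:      %d\n", nrow(x$lumrs)))
  for (t in x$tissues)
    cat(sprintf("  %-10s DHS consensus %d, H3K9ac consensus %d, candidates %d\n",
                paste0(t, ":"), nrow(x$dhs_consensus[[t]]),
                nrow(x$k9_consensus[[t]]), sum(x$candidates[[t]])))
  cat(sprintf("  candidates: %d total (%s)\n", nrow(x$candidates),
              paste(sprintf("%s: %d", names(table(x$candidates$specificity)),
                            table(x$candidates$specificity)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.enhancer_scan <- function(object, ...) {
  print(object)
  cat("\nTarget linking:\n")
  print(table(object$links$specificity, object$links$link_category))
  cat("\nTE family enrichment (top rows):\n")
  print(utils::head(object$te_families, 5))
  if (!is.null(object$motif))
    cat(sprintf("\nMotif enrichment: fold %.2f (p %s)\n",
                object$motif$fold, format.pval(object$motif$p)))
  invisible(object)
}

#' Compare a pipeline run to the planted truth
#'
#' Matches predicted candidates to planted enhancers by >= 1 bp overlap
#' and reports precision (candidates matching a planted enhancer), recall
#' (planted enhancers recovered by at least one candidate) and the
#' fraction of recovered enhancers whose detected tissue pattern equals
#' the planted one.
#'
#' @param scan an `enhancer_scan`.
#' @param truth the `truth` element from [generate_synthetic_data()] (or a
#'   path to `truth.json`).
#' @return list: `precision`, `recall`, `pattern_accuracy`, `n_candidates`,
#'   `n_planted`, `n_matched`.
#' @export
compare_to_truth <- function(scan, truth) {
  if (is.character(truth)) truth <- jsonlite::read_json(truth,
                                                        simplifyVector = TRUE)
  te <- as.data.frame(truth$enhancers)
  cand <- scan$candidates
  tiv <- interval_set(te$chrom, te$start, te$end,
                      name = sprintf("T%d", seq_len(nrow(te))))
  civ <- interval_set(cand$chrom, cand$start, cand$end)
  cand_hit <- logical(nrow(cand))
  cand_hit[order(cand$chrom, cand$start, cand$end)] <-
    iv_overlaps_any(civ, tiv)
  truth_hit <- logical(nrow(te))
  truth_hit[order(te$chrom, te$start, te$end)] <- iv_overlaps_any(tiv, civ)
  # detected pattern per planted enhancer: union of detections of
  # overlapping candidates
  tissues <- scan$tissues
  pattern_ok <- logical(nrow(te))
  for (i in which(truth_hit)) {
    ov <- cand$chrom == te$chrom[i] & cand$start < te$end[i] &
      cand$end > te$start[i]
    det <- vapply(tissues, function(t) any(cand[[t]][ov]), logical(1))
    got <- if (all(det)) "shared" else tissues[det]
    pattern_ok[i] <- length(got) == 1 && got == te$pattern[i]
  }
  list(precision = if (nrow(cand) > 0) mean(cand_hit) else NA_real_,
       recall = mean(truth_hit),
       pattern_accuracy = if (any(truth_hit))
         sum(pattern_ok) / sum(truth_hit) else NA_real_,
       n_candidates = nrow(cand), n_planted = nrow(te),
       n_matched = sum(truth_hit))
}
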