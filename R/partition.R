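#' Partition the genome into region classes
#'
#' Assigns every base to exactly one of six classes: `exon` (annotated
#' exons including UTRs), `intron` (genic minus exon; intronic TE bases
#' count as intron), `promoter` (1 kb upstream to 200 bp downstream of the
#' TSS, strand-aware, minus genic bases; overlapping promoters of adjacent
#' genes merge), `flanking` (4 kb upstream of the promoter plus 5 kb
#' downstream of the TTS), `TE` (remaining intergenic TE bases) and
#' `distal` (everything else). Precedence when definitions overlap:
#' exon > intron > promoter > flanking > TE > distal, so `TE` means
#' intergenic TE space outside promoters and gene flanks.
#'
#' @param genes a `gene_models` object.
#' @param tes a `te_annotation` (or any `interval_set`); may be `NULL`.
#' @param genome named numeric vector of chromosome lengths.
#' @param config a [pipeline_config()].
#' @return A list of class `region_partition` mapping class name to a
#'   merged `interval_set`; classes are pairwise disjoint and jointly cover
#'   the genome.
#' @export
partition_genome <- function(genes, tes, genome,
                             config = pipeline_config()) {
  stopifnot(inherits(genes, "gene_models"))
  genome_set <- interval_set(names(genome), rep(0, length(genome)), genome)
  clip <- function(x) iv_intersect(x, genome_set)
  g <- genes$genes
  out_of_bounds <- g$start < 0 | g$end > genome[g$chrom]
  if (any(out_of_bounds, na.rm = TRUE))
    warning("gene(s) extend past chromosome bounds; clipped")

  genic <- clip(iv_merge(gene_spans(genes)))
  exon <- clip(iv_merge(genes$exons))
  exon <- iv_intersect(exon, genic)
  intron <- iv_subtract(genic, exon)

  up <- config$promoter_upstream_bp
  dn <- config$promoter_downstream_bp
  ps <- ifelse(g$strand == "+", g$tss - up, g$tss - dn)
  pe <- ifelse(g$strand == "+", g$tss + dn, g$tss + up)
  prom_raw <- interval_set(g$chrom, pmax(ps, 0), pmin(pe, genome[g$chrom]))
  promoter <- iv_subtract(clip(prom_raw), genic)

  fu <- config$flank_upstream_bp
  fd <- config$flank_downstream_bp
  fs_up <- ifelse(g$strand == "+", g$tss - up - fu, g$tss + up)
  fe_up <- ifelse(g$strand == "+", g$tss - up, g$tss + up + fu)
  fs_dn <- ifelse(g$strand == "+", g$tts, g$tts - fd)
  fe_dn <- ifelse(g$strand == "+", g$tts + fd, g$tts)
  fl <- data.frame(chrom = c(g$chrom, g$chrom), start = c(fs_up, fs_dn),
                   end = c(fe_up, fe_dn))
  fl$start <- pmax(fl$start, 0)
  fl$end <- pmin(fl$end, genome[fl$chrom])
  fl <- fl[fl$end > fl$start, , drop = FALSE]
  flanking <- iv_subtract(iv_subtract(
    clip(interval_set(fl$chrom, fl$start, fl$end)), genic), promoter)

  te_class <- if (!is.null(tes) && nrow(tes) > 0) {
    te_iv <- clip(iv_merge(interval_set(tes$chrom, tes$start, tes$end)))
    iv_subtract(iv_subtract(iv_subtract(te_iv, genic), promoter), flanking)
  } else interval_set()

  covered <- iv_merge(as_interval_set(rbind(
    as.data.frame(genic)[, 1:3], as.data.frame(promoter)[, 1:3],
    as.data.frame(flanking)[, 1:3], as.data.frame(te_class)[, 1:3])))
  distal <- iv_subtract(genome_set, covered)

  part <- list(promoter = promoter, exon = exon, intron = intron,
               flanking = flanking, TE = te_class, distal = distal)
  structure(part, genome = genome, class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("region_partition (bp per class):\n")
  for (nm in names(x))
    cat(sprintf("  %-9s %12d\n", nm, iv_total_bp(x[[nm]])))
  invisible(x)
}

#' Distribute features over genomic region classes
#'
#' Each feature is counted once, in the class containing its midpoint.
#' Occupancy is the number of feature bases falling in each class (within
#' the mappability mask, when one is given).
#'
#' @param features an `interval_set` (e.g. DHSs, H3K9ac regions, LUMRs).
#' @param partition a [partition_genome()] result.
#' @param mask optional `interval_set` of uniquely mappable regions.
#' @return A data frame with one row per class: `class`, `count`,
#'   `occupied_bp`, `count_fraction`, plus attributes `n_features`.
#' @export
classify_features <- function(features, partition, mask = NULL) {
  classes <- names(partition)
  counts <- stats::setNames(integer(length(classes)), classes)
  occ <- stats::setNames(numeric(length(classes)), classes)
  n <- nrow(features)
  if (n > 0) {
    mid <- features$start + (features$end - features$start) %/% 2L
    pts <- interval_set(features$chrom, mid, mid + 1L)
    assigned <- rep(NA_character_, n)
    # pts is sorted by (chrom, start); recover the original row order
    ord <- order(features$chrom, mid, mid + 1L)
    for (cl in classes) {
      hit <- iv_overlaps_any(pts, partition[[cl]])
      take <- hit & is.na(assigned[ord])
      assigned[ord[take]] <- cl
    }
    tab <- table(factor(assigned, levels = classes))
    counts[] <- as.integer(tab)
    fm <- if (is.null(mask)) features else {
      ivm <- iv_intersect(features, mask)
      ivm
    }
    for (cl in classes)
      occ[cl] <- iv_total_bp(iv_intersect(fm, partition[[cl]]))
  }
  data.frame(class = classes, count = as.integer(counts),
             occupied_bp = as.numeric(occ),
             count_fraction = if (n > 0) as.numeric(counts) / n else 0,
             stringsAsFactors = FALSE)
}
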