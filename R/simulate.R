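#' Synthetic dataset configuration
#'
#' Parameters of the truth-annotated toy dataset. Defaults emulate the
#' processed data the pipeline consumes: two 1-Mb chromosomes carrying
#' about 200 genes; 60 planted intergenic enhancers (tissue-specific and
#' shared) each combining a methylation valley, a DHS and a one-sided
#' H3K9ac region; replicate peak calls with +/-30 bp boundary jitter and a
#' 5% per-tissue dropout rate; methylation background centred at 86% (CG),
#' 74% (CHG) and 2% (CHH) with planted valleys at 5% and a small CHH bump
#' at valley 5' edges; five TE families across the LTR/TIR/helitron
#' superfamilies with one family enriched for enhancer-containing members;
#' an expression table whose differential-expression flags are consistent
#' with the planted tissue patterns; a mappability mask with excluded
#' blocks; and the GGCCCA motif planted in a fraction of enhancers.
#'
#' @param ... named overrides (see the source for the full field list).
#' @param noise logical; `FALSE` switches off jitter, dropout and
#'   methylation sampling noise (frequencies exactly at their means).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(..., noise = TRUE) {
  cfg <- list(
    chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
    tissues = c("V2-IST", "husk"),
    gap_range = c(4600, 9000),
    gene_len_range = c(2000, 5000),
    n_exons_range = c(1, 4),
    n_enh = c(tissue1_only = 10, tissue2_only = 35, shared = 15),
    n_lumr_only = 30, n_dhs_only = 15, n_k9_only = 15, n_dhs_k9 = 10,
    valley_len_range = c(900, 1400),
    dhs_len_range = c(300, 450),
    k9_len_range = c(400, 700),
    k9_overlap_bp = 50,
    dnase_rpm_range = c(1, 5),
    k9_rpm_range = c(1, 4),
    asym_fold = 4,
    n_reps_dnase = c(2, 2),
    n_reps_k9 = c(2, 3),
    jitter_bp = 30, dropout = 0.05,
    meth_means = c(CG = 0.86, CHG = 0.74, CHH = 0.02),
    valley_mean = 0.05, chh_bump = 0.10,
    meth_spacing = c(CG = 80, CHG = 100, CHH = 150),
    beta_conc = 60, coverage_lambda = 10,
    promoter_peak_frac = 0.5,
    de_frac = 0.10,
    motif = "GGCCCA", motif_fraction = 0.6,
    cns_fraction = 0.3, n_cns_background = 20,
    n_mask_holes = 4, hole_len_range = c(2000, 4000),
    te_wrap_pad = 300,
    noise = noise
  )
  over <- list(...)
  if (length(over) > 0) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0)
      stop("unknown sim_config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg$noise <- isTRUE(cfg$noise)
  class(cfg) <- "sim_config"
  cfg
}

runifi <- function(n, lo, hi) as.integer(round(stats::runif(n, lo, hi)))

rbeta_mean <- function(n, mean, conc) {
  stats::rbeta(n, shape1 = mean * conc, shape2 = (1 - mean) * conc)
}

#' Generate a truth-annotated synthetic input bundle
#'
#' Writes, under `dir`, every file the pipeline reads: `genes.gff3`,
#' `tes.gff3`, `chrom.sizes`, `genome.fa`, `mask.bed`, `cns.bed`,
#' per-replicate peak BEDs (`dnase_<tissue>_rep<k>.bed`,
#' `k9_<tissue>_rep<k>.bed`), pooled RPM tracks
#' (`dnase_<tissue>.bedgraph`, `k9_<tissue>.bedgraph`,
#' `rna_<tissue>.bedgraph`), `methylation.tsv`, `expression.tsv` and the
#' ground truth `truth.json`. Deterministic given `seed`; errors when the
#' requested loci do not fit the intergenic space.
#'
#' @param dir output directory (created if needed).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return invisibly, a list with `paths` (named file paths, with
#'   per-tissue peak/track lists), `truth` (planted features) and `config`.
#' @export
generate_synthetic_data <- function(dir, config = sim_config(), seed = 1L) {
  set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cl <- config$chrom_lengths
  tissues <- config$tissues
  noise <- config$noise
  J <- if (noise) config$jitter_bp else 0
  dropout <- if (noise) config$dropout else 0

  ## ---- gene layout and intergenic gaps ----------------------------------
  genes <- list(); gaps <- list()
  for (ch in names(cl)) {
    cursor <- 2000; prev <- NULL
    repeat {
      gap <- runifi(1, config$gap_range[1], config$gap_range[2])
      glen <- runifi(1, config$gene_len_range[1], config$gene_len_range[2])
      if (cursor + gap + glen > cl[[ch]] - 5000) break
      gstart <- cursor + gap
      gid <- sprintf("gene%04d", length(genes) + 1)
      nex <- sample(seq(config$n_exons_range[1], config$n_exons_range[2]), 1)
      genes[[gid]] <- list(gene_id = gid, chrom = ch, start = gstart,
                           end = gstart + glen,
                           strand = sample(c("+", "-"), 1), n_exons = nex)
      if (!is.null(prev))
        gaps[[length(gaps) + 1]] <- list(chrom = ch, start = prev$end,
                                         end = gstart,
                                         left = prev$gene_id, right = gid)
      prev <- genes[[gid]]
      cursor <- gstart + glen
    }
  }
  gdf <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
               end = g$end, strand = g$strand, n_exons = g$n_exons,
               stringsAsFactors = FALSE)))
  rownames(gdf) <- NULL

  # exon/intron structure: 2k-1 alternating segments per gene
  exon_rows <- list(); intron_rows <- list()
  for (i in seq_len(nrow(gdf))) {
    glen <- gdf$end[i] - gdf$start[i]
    k <- gdf$n_exons[i]
    if (k == 1) {
      exon_rows[[length(exon_rows) + 1]] <-
        data.frame(gene_id = gdf$gene_id[i], chrom = gdf$chrom[i],
                   start = gdf$start[i], end = gdf$end[i])
      next
    }
    cuts <- sort(sample(seq(200, glen - 200, by = 50), 2 * k - 2))
    bounds <- c(0, cuts, glen) + gdf$start[i]
    for (s in seq_len(2 * k - 1)) {
      row <- data.frame(gene_id = gdf$gene_id[i], chrom = gdf$chrom[i],
                        start = bounds[s], end = bounds[s + 1])
      if (s %% 2 == 1) exon_rows[[length(exon_rows) + 1]] <- row
      else intron_rows[[length(intron_rows) + 1]] <- row
    }
  }
  exons <- do.call(rbind, exon_rows)
  introns <- if (length(intron_rows) > 0) do.call(rbind, intron_rows) else
    NULL

  ## ---- assign loci to gaps ----------------------------------------------
  margin <- 1500
  gapdf <- do.call(rbind, lapply(gaps, as.data.frame,
                                 stringsAsFactors = FALSE))
  eligible <- which(gapdf$end - gapdf$start >= 2 * margin +
                      max(config$valley_len_range))
  n_enh <- sum(config$n_enh)
  n_loci <- n_enh + config$n_lumr_only + config$n_dhs_only +
    config$n_k9_only + config$n_dhs_k9
  if (length(eligible) < n_loci)
    stop("infeasible placement: ", n_loci, " loci for ",
         length(eligible), " eligible intergenic gaps")
  slots <- sample(eligible, n_loci)
  slot_at <- 0
  next_slot <- function() {
    slot_at <<- slot_at + 1
    gapdf[slots[slot_at], , drop = FALSE]
  }
  place_valley <- function(g) {
    vlen <- runifi(1, config$valley_len_range[1], config$valley_len_range[2])
    zs <- g$start + margin
    ze <- g$end - margin
    vs <- zs + sample.int(max(ze - zs - vlen, 1), 1) - 1L
    c(vs, vs + vlen)
  }

  patterns <- c(rep(tissues[1], config$n_enh[["tissue1_only"]]),
                rep(tissues[2], config$n_enh[["tissue2_only"]]),
                rep("shared", config$n_enh[["shared"]]))
  enh <- vector("list", n_enh)
  designated <- character()
  for (i in seq_len(n_enh)) {
    g <- next_slot()
    v <- place_valley(g)
    dlen <- runifi(1, config$dhs_len_range[1], config$dhs_len_range[2])
    ds <- v[1] + 100L
    klen <- runifi(1, config$k9_len_range[1], config$k9_len_range[2])
    side <- sample(c("left", "right"), 1)
    # the H3K9ac region straddles one DHS boundary so that it always
    # intersects the LUMR regardless of methylation site spacing
    ovl <- config$k9_overlap_bp
    k9 <- if (side == "right") c(ds + dlen - ovl, ds + dlen - ovl + klen)
    else c(ds + ovl - klen, ds + ovl)
    pat <- patterns[i]
    active <- if (pat == "shared") tissues else pat
    heights <- lapply(tissues, function(t) {
      if (t %in% active)
        c(dnase = stats::runif(1, config$dnase_rpm_range[1],
                               config$dnase_rpm_range[2]),
          k9 = stats::runif(1, config$k9_rpm_range[1],
                            config$k9_rpm_range[2]))
      else c(dnase = 0, k9 = 0)
    })
    names(heights) <- tissues
    # designate a flanking target gene not yet claimed
    sides <- c(g$left, g$right)
    free <- sides[!sides %in% designated]
    target <- if (length(free) > 0) sample(free, 1) else NA_character_
    if (!is.na(target)) designated <- c(designated, target)
    enh[[i]] <- list(chrom = g$chrom, valley = v, dhs = c(ds, ds + dlen),
                     k9 = k9, side = side, pattern = pat, target = target,
                     heights = heights, fold = config$asym_fold,
                     has_motif = FALSE, te_family = NA_character_)
  }

  bg_valleys <- list(); bg_dhs <- list(); bg_k9 <- list()
  for (i in seq_len(config$n_lumr_only)) {
    g <- next_slot(); v <- place_valley(g)
    bg_valleys[[i]] <- data.frame(chrom = g$chrom, start = v[1], end = v[2])
  }
  mk_peak <- function(g, len_range) {
    len <- runifi(1, len_range[1], len_range[2])
    zs <- g$start + margin
    s <- zs + sample.int(max(g$end - margin - zs - len, 1), 1) - 1L
    c(s, s + len)
  }
  for (i in seq_len(config$n_dhs_only)) {
    g <- next_slot(); p <- mk_peak(g, config$dhs_len_range)
    bg_dhs[[i]] <- data.frame(chrom = g$chrom, start = p[1], end = p[2])
  }
  for (i in seq_len(config$n_k9_only)) {
    g <- next_slot(); p <- mk_peak(g, config$k9_len_range)
    bg_k9[[i]] <- data.frame(chrom = g$chrom, start = p[1], end = p[2])
  }
  for (i in seq_len(config$n_dhs_k9)) {
    g <- next_slot(); p <- mk_peak(g, config$dhs_len_range)
    bg_dhs[[length(bg_dhs) + 1]] <-
      data.frame(chrom = g$chrom, start = p[1], end = p[2])
    bg_k9[[length(bg_k9) + 1]] <-
      data.frame(chrom = g$chrom, start = p[2] - config$k9_overlap_bp,
                 end = p[2] - config$k9_overlap_bp + 400L)
  }
  free_gaps <- setdiff(eligible, slots)

  ## ---- expression and designated targets --------------------------------
  rpkm <- lapply(tissues, function(t)
    round(stats::rlnorm(nrow(gdf), meanlog = 1.2, sdlog = 1), 3))
  names(rpkm) <- tissues
  sig <- rep(FALSE, nrow(gdf))
  higher <- rep("none", nrow(gdf))
  for (e in enh) {
    if (is.na(e$target)) next
    gi <- match(e$target, gdf$gene_id)
    if (e$pattern == "shared") {
      for (t in tissues) rpkm[[t]][gi] <- round(stats::runif(1, 2, 20), 3)
    } else {
      other <- setdiff(tissues, e$pattern)
      hi_val <- round(stats::runif(1, 5, 50), 3)
      rpkm[[e$pattern]][gi] <- hi_val
      rpkm[[other]][gi] <- round(hi_val / stats::runif(1, 4, 10), 3)
      sig[gi] <- TRUE
      higher[gi] <- e$pattern
    }
  }
  extra <- which(!gdf$gene_id %in% designated &
                   stats::runif(nrow(gdf)) < config$de_frac)
  for (gi in extra) {
    t <- sample(tissues, 1)
    sig[gi] <- TRUE; higher[gi] <- t
    rpkm[[t]][gi] <- round(rpkm[[t]][gi] * 4 + 2, 3)
  }

  ## ---- TE annotation -----------------------------------------------------
  fams <- data.frame(
    family = c("RLG00010", "RLG00233", "DTA00100", "DTH00201", "DHH00045"),
    superfamily = c("LTR", "LTR", "TIR", "TIR", "helitron"),
    n_free = c(6, 13, 10, 8, 9), stringsAsFactors = FALSE)
  te_rows <- list()
  add_te <- function(chrom, start, end, family, superfamily) {
    te_rows[[length(te_rows) + 1]] <<- data.frame(
      chrom = chrom, start = start, end = end, family = family,
      superfamily = superfamily, stringsAsFactors = FALSE)
  }
  # enhancer-wrapping members: enriched family around 8 enhancers,
  # one more in each of two other families
  wrap_idx <- sample(seq_len(n_enh), 10)
  wrap_fams <- c(rep("RLG00010", 8), "RLG00233", "DHH00045")
  pad <- config$te_wrap_pad
  for (w in seq_along(wrap_idx)) {
    e <- enh[[wrap_idx[w]]]
    f <- wrap_fams[w]
    add_te(e$chrom, e$valley[1] - pad, e$valley[2] + pad, f,
           fams$superfamily[match(f, fams$family)])
    enh[[wrap_idx[w]]]$te_family <- f
  }
  te_gap_pool <- sample(free_gaps)
  pool_at <- 0
  next_free_gap <- function() {
    pool_at <<- pool_at + 1
    if (pool_at > length(te_gap_pool))
      stop("infeasible placement: not enough free gaps for TEs/mask")
    gapdf[te_gap_pool[pool_at], , drop = FALSE]
  }
  big_f2 <- list()
  for (f in seq_len(nrow(fams))) {
    for (m in seq_len(fams$n_free[f])) {
      g <- next_free_gap()
      len <- runifi(1, 1000, min(3000, g$end - g$start - 2 * margin))
      s <- g$start + margin
      add_te(g$chrom, s, s + len, fams$family[f], fams$superfamily[f])
      if (fams$family[f] == "RLG00233" && len > 1500)
        big_f2[[length(big_f2) + 1]] <- c(s, s + len, g$chrom)
    }
  }
  # nested insertions inside large members (resolved out of the baseline)
  for (nb in utils::head(big_f2, 3)) {
    s <- as.integer(nb[1]) + 200L
    add_te(nb[3], s, s + 400L, "DTA00100", "TIR")
  }
  # short elements (below the baseline length floor)
  for (i in seq_len(5)) {
    g <- next_free_gap()
    s <- g$start + margin
    add_te(g$chrom, s, s + runifi(1, 200, 600), "DTA00100", "TIR")
  }
  # intronic elements (excluded from the baseline)
  if (!is.null(introns)) {
    big_introns <- introns[introns$end - introns$start >= 500, , drop = FALSE]
    for (i in seq_len(min(5, nrow(big_introns)))) {
      it <- big_introns[i, ]
      add_te(it$chrom, it$start + 50L, it$start + 450L, "DTH00201", "TIR")
    }
  }
  tedf <- do.call(rbind, te_rows)

  ## ---- mask and CNS ------------------------------------------------------
  holes <- list()
  for (i in seq_len(config$n_mask_holes)) {
    g <- next_free_gap()
    len <- runifi(1, config$hole_len_range[1],
                  min(config$hole_len_range[2], g$end - g$start - 1000))
    holes[[i]] <- data.frame(chrom = g$chrom, start = g$start + 500L,
                             end = g$start + 500L + len)
  }
  holedf <- do.call(rbind, holes)
  mask <- iv_subtract(interval_set(names(cl), rep(0, length(cl)), cl),
                      interval_set(holedf$chrom, holedf$start, holedf$end))

  cns_rows <- list()
  cns_enh <- sample(seq_len(n_enh), round(config$cns_fraction * n_enh))
  for (i in cns_enh)
    cns_rows[[length(cns_rows) + 1]] <- data.frame(
      chrom = enh[[i]]$chrom, start = enh[[i]]$dhs[1] + 10L,
      end = enh[[i]]$dhs[1] + 60L)
  for (i in seq_len(config$n_cns_background)) {
    g <- gapdf[sample(seq_len(nrow(gapdf)), 1), ]
    cns_rows[[length(cns_rows) + 1]] <- data.frame(
      chrom = g$chrom, start = g$start + 300L, end = g$start + 350L)
  }
  cnsdf <- do.call(rbind, cns_rows)

  ## ---- peaks, replicates, tracks ----------------------------------------
  prom_genes <- which(stats::runif(nrow(gdf)) < config$promoter_peak_frac)
  tss <- ifelse(gdf$strand == "+", gdf$start, gdf$end)
  peaks <- list()   # per tissue/assay: chrom,start,end,height,locus
  for (t in tissues) {
    dn <- list(); k9l <- list()
    for (i in seq_along(enh)) {
      e <- enh[[i]]
      if (e$heights[[t]][["dnase"]] > 0) {
        dn[[length(dn) + 1]] <- data.frame(
          chrom = e$chrom, start = e$dhs[1], end = e$dhs[2],
          height = e$heights[[t]][["dnase"]],
          locus = sprintf("enh%03d", i))
        k9l[[length(k9l) + 1]] <- data.frame(
          chrom = e$chrom, start = e$k9[1], end = e$k9[2],
          height = e$heights[[t]][["k9"]], locus = sprintf("enh%03d", i))
      }
    }
    for (i in seq_along(bg_dhs))
      dn[[length(dn) + 1]] <- cbind(bg_dhs[[i]],
                                    height = stats::runif(1, 1, 4),
                                    locus = sprintf("bgd%03d", i))
    for (i in seq_along(bg_k9))
      k9l[[length(k9l) + 1]] <- cbind(bg_k9[[i]],
                                      height = stats::runif(1, 1, 4),
                                      locus = sprintf("bgk%03d", i))
    for (gi in prom_genes) {
      if (rpkm[[t]][gi] < 1) next
      h <- 0.5 + rpkm[[t]][gi] / 10
      s <- max(tss[gi] - 150L, 0L)
      loc <- sprintf("prom%04d", gi)
      dn[[length(dn) + 1]] <- data.frame(chrom = gdf$chrom[gi], start = s,
                                         end = tss[gi] + 150L, height = h,
                                         locus = loc)
      ks <- if (gdf$strand[gi] == "+") tss[gi] + 50L else tss[gi] - 550L
      k9l[[length(k9l) + 1]] <- data.frame(chrom = gdf$chrom[gi],
                                           start = max(ks, 0L),
                                           end = max(ks, 0L) + 500L,
                                           height = h, locus = loc)
    }
    peaks[[t]] <- list(dnase = do.call(rbind, dn), k9 = do.call(rbind, k9l))
  }

  jitter_peaks <- function(p) {
    if (J == 0) return(p)
    p$start <- pmax(p$start + runifi(nrow(p), -J, J), 0L)
    p$end <- p$end + runifi(nrow(p), -J, J)
    p$end <- pmax(p$end, p$start + 50L)
    p
  }

  paths <- list(dir = dir)
  paths$dnase_peaks <- list(); paths$k9_peaks <- list()
  paths$dnase_tracks <- list(); paths$k9_tracks <- list()
  paths$rna_tracks <- list()
  safe <- function(t) gsub("[^A-Za-z0-9]+", "", t)
  for (ti in seq_along(tissues)) {
    t <- tissues[ti]
    # dropout: per locus and tissue, with probability `dropout` the peak
    # of one randomly chosen assay is missed in one randomly chosen
    # replicate (a replicate-specific peak-calling failure)
    nreps <- c(dnase = config$n_reps_dnase[ti], k9 = config$n_reps_k9[ti])
    loci <- unique(c(peaks[[t]]$dnase$locus, peaks[[t]]$k9$locus))
    ev <- loci[stats::runif(length(loci)) < dropout]
    ev_assay <- sample(c("dnase", "k9"), length(ev), replace = TRUE)
    ev_rep <- vapply(ev_assay, function(a)
      sample.int(nreps[[a]], 1), integer(1))
    for (assay in c("dnase", "k9")) {
      p <- peaks[[t]][[assay]]
      nrep <- nreps[[assay]]
      drop_rep <- integer(nrow(p))
      hitev <- match(p$locus, ev)
      sel <- !is.na(hitev) & ev_assay[pmax(hitev, 1L)] == assay
      drop_rep[sel] <- ev_rep[hitev[sel]]
      files <- character(nrep)
      for (r in seq_len(nrep)) {
        pr <- jitter_peaks(p[drop_rep != r, , drop = FALSE])
        f <- file.path(dir, sprintf("%s_%s_rep%d.bed", assay, safe(t), r))
        write_bed(iv_merge(interval_set(pr$chrom, pr$start, pr$end)), f)
        files[r] <- f
      }
      if (assay == "dnase") paths$dnase_peaks[[t]] <- files
      else paths$k9_peaks[[t]] <- files
    }
    # pooled RPM tracks at true positions; the H3K9ac track adds the
    # sub-threshold plateau on the low side of each planted enhancer
    dn <- peaks[[t]]$dnase
    k9p <- peaks[[t]]$k9
    lowside <- list()
    for (e in enh) {
      h <- e$heights[[t]][["k9"]]
      if (h <= 0) next
      klen <- e$k9[2] - e$k9[1]
      ovl <- config$k9_overlap_bp
      low <- if (e$side == "right")
        c(e$dhs[1] + ovl - klen, e$dhs[1] + ovl)
      else c(e$dhs[2] - ovl, e$dhs[2] - ovl + klen)
      lowside[[length(lowside) + 1]] <- data.frame(
        chrom = e$chrom, start = low[1], end = low[2],
        height = h / e$fold, locus = NA_character_)
    }
    k9all <- rbind(k9p, do.call(rbind, lowside))
    f1 <- file.path(dir, sprintf("dnase_%s.bedgraph", safe(t)))
    f2 <- file.path(dir, sprintf("k9_%s.bedgraph", safe(t)))
    write_bedgraph(signal_track(
      data.frame(chrom = dn$chrom, start = dn$start, end = dn$end,
                 value = dn$height), cl), f1)
    write_bedgraph(signal_track(
      data.frame(chrom = k9all$chrom, start = k9all$start, end = k9all$end,
                 value = k9all$height), cl), f2)
    paths$dnase_tracks[[t]] <- f1
    paths$k9_tracks[[t]] <- f2
    f3 <- file.path(dir, sprintf("rna_%s.bedgraph", safe(t)))
    write_bedgraph(signal_track(
      data.frame(chrom = gdf$chrom, start = gdf$start, end = gdf$end,
                 value = round(rpkm[[t]] / 10, 4)), cl), f3)
    paths$rna_tracks[[t]] <- f3
  }

  ## ---- methylation -------------------------------------------------------
  valleys <- rbind(
    do.call(rbind, lapply(enh, function(e)
      data.frame(chrom = e$chrom, start = e$valley[1], end = e$valley[2]))),
    do.call(rbind, bg_valleys))
  meth_rows <- list()
  for (ch in names(cl)) {
    vch <- valleys[valleys$chrom == ch, , drop = FALSE]
    ech <- do.call(rbind, lapply(enh[vapply(enh, function(e)
      e$chrom == ch, logical(1))], function(e)
        data.frame(v5 = if (e$side == "right") e$valley[1] else e$valley[2])))
    for (ctx in c("CG", "CHG", "CHH")) {
      sp <- config$meth_spacing[[ctx]]
      pos <- seq(sp, cl[[ch]] - sp, by = sp)
      mu <- rep(config$meth_means[[ctx]], length(pos))
      if (nrow(vch) > 0 && ctx != "CHH") {
        inval <- vapply(pos, function(p)
          any(p >= vch$start & p < vch$end), logical(1))
        mu[inval] <- config$valley_mean
      }
      if (ctx == "CHH" && !is.null(ech) && nrow(ech) > 0) {
        near5 <- vapply(pos, function(p)
          any(abs(p - ech$v5) <= 100), logical(1))
        mu[near5] <- config$chh_bump
      }
      freq <- if (noise) round(rbeta_mean(length(pos), mu,
                                          config$beta_conc), 4) else mu
      cov <- if (noise) stats::rpois(length(pos), config$coverage_lambda)
      else rep(10L, length(pos))
      meth_rows[[length(meth_rows) + 1]] <- data.frame(
        chrom = ch, pos = pos, context = ctx, frequency = freq,
        coverage = cov, stringsAsFactors = FALSE)
    }
  }
  meth <- do.call(rbind, meth_rows)
  meth <- meth[order(meth$chrom, meth$pos), ]
  paths$methylation <- file.path(dir, "methylation.tsv")
  utils::write.table(meth, paths$methylation, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## ---- genome sequence with planted motifs ------------------------------
  seqs <- lapply(names(cl), function(ch)
    paste(sample(c("A", "C", "G", "T"), cl[[ch]], replace = TRUE),
          collapse = ""))
  names(seqs) <- names(cl)
  motif_idx <- sample(seq_len(n_enh), round(config$motif_fraction * n_enh))
  for (i in motif_idx) {
    e <- enh[[i]]
    mid <- (e$dhs[1] + e$dhs[2]) %/% 2
    substr(seqs[[e$chrom]], mid + 1, mid + nchar(config$motif)) <-
      config$motif
    enh[[i]]$has_motif <- TRUE
  }
  genome_seq <- Biostrings::DNAStringSet(unlist(seqs))
  paths$genome_fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome_seq, paths$genome_fasta)

  ## ---- annotations and bookkeeping files --------------------------------
  gff <- c("##gff-version 3")
  for (i in seq_len(nrow(gdf))) {
    gff <- c(gff, sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                          gdf$chrom[i], gdf$start[i] + 1L, gdf$end[i],
                          gdf$strand[i], gdf$gene_id[i]))
    ex <- exons[exons$gene_id == gdf$gene_id[i], , drop = FALSE]
    for (j in seq_len(nrow(ex)))
      gff <- c(gff, sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                            ex$chrom[j], ex$start[j] + 1L, ex$end[j],
                            gdf$strand[i], gdf$gene_id[i]))
  }
  paths$genes <- file.path(dir, "genes.gff3")
  writeLines(gff, paths$genes)

  tegff <- c("##gff-version 3",
             sprintf(paste0("%s\tsim\ttransposable_element\t%d\t%d\t.\t+",
                            "\t.\tID=te%04d;family=%s;superfamily=%s"),
                     tedf$chrom, tedf$start + 1L, tedf$end,
                     seq_len(nrow(tedf)), tedf$family, tedf$superfamily))
  paths$tes <- file.path(dir, "tes.gff3")
  writeLines(tegff, paths$tes)

  paths$chrom_sizes <- file.path(dir, "chrom.sizes")
  writeLines(sprintf("%s\t%d", names(cl), as.integer(cl)),
             paths$chrom_sizes)
  paths$mask <- file.path(dir, "mask.bed")
  write_bed(mask, paths$mask)
  paths$cns <- file.path(dir, "cns.bed")
  write_bed(interval_set(cnsdf$chrom, cnsdf$start, cnsdf$end), paths$cns)

  expr <- data.frame(gene_id = gdf$gene_id, stringsAsFactors = FALSE)
  for (t in tissues) expr[[t]] <- rpkm[[t]]
  expr$significant_de <- sig
  expr$higher_tissue <- higher
  paths$expression <- file.path(dir, "expression.tsv")
  hdr <- paste(c("gene_id", tissues, "significant_de", "higher_tissue"),
               collapse = "\t")
  body <- do.call(paste, c(unname(as.list(expr)), sep = "\t"))
  writeLines(c(hdr, body), paths$expression)

  truth <- list(
    seed = seed,
    tissues = tissues,
    enhancers = do.call(rbind, lapply(enh, function(e) data.frame(
      chrom = e$chrom, start = e$valley[1], end = e$valley[2],
      dhs_start = e$dhs[1], dhs_end = e$dhs[2],
      k9_start = e$k9[1], k9_end = e$k9[2],
      pattern = e$pattern, asym_side = e$side, fold = e$fold,
      target_gene = e$target, te_family = e$te_family,
      has_motif = e$has_motif, stringsAsFactors = FALSE))),
    background = list(n_lumr_only = config$n_lumr_only,
                      n_dhs_only = config$n_dhs_only,
                      n_k9_only = config$n_k9_only,
                      n_dhs_k9 = config$n_dhs_k9),
    mask_holes = holedf)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(paths = paths, truth = truth, config = config))
}
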