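#' Pipeline configuration
#'
#' All numeric thresholds of the prediction pipeline in one validated
#' record. Defaults are the published operating point: reciprocal 70%
#' replicate overlap, 20% methylation ceiling over 100-bp windows, 80% TE
#' containment, 635-bp TE baseline length floor, 300-bp orientation flanks
#' with a 0.5 RPM eligibility floor and 2-fold asymmetry call, k = 4
#' signal-profile categories over +/-1 kb, 1000 permutations, promoters
#' from 1 kb upstream to 200 bp downstream of the TSS, flanking regions
#' 4 kb upstream of promoters and 5 kb downstream of TTSs, a 1 RPKM
#' expression floor and a 90% uniqueness mappability mask.
#'
#' @param ... named overrides of the defaults listed above.
#' @return A validated list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(n_permutations = 200)
#' cfg$methylation_threshold
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    replicate_overlap_frac = 0.70,
    methylation_threshold = 0.20,
    methylation_window_bp = 100L,
    lumr_min_sites = 4L,
    lumr_max_gap_bp = 300L,
    te_containment_frac = 0.80,
    te_baseline_min_len_bp = 635L,
    orientation_flank_bp = 300L,
    asym_min_rpm = 0.5,
    asym_fold = 2.0,
    kmeans_k = 4L,
    heatmap_flank_bp = 1000L,
    body_bins = 50L,
    flank_bin_bp = 20L,
    n_permutations = 1000L,
    promoter_upstream_bp = 1000L,
    promoter_downstream_bp = 200L,
    flank_upstream_bp = 4000L,
    flank_downstream_bp = 5000L,
    expressed_min_rpkm = 1.0,
    n_expression_bins = 6L,
    mappability_min_uniqueness = 0.90,
    random_seed = 1L
  )
  over <- list(...)
  if (length(over) > 0) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("configuration overrides must be named")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0)
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  frac <- c("replicate_overlap_frac", "methylation_threshold",
            "te_containment_frac", "mappability_min_uniqueness")
  for (f in frac)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] > 1)
      stop(f, " must be in (0, 1], got ", cfg[[f]])
  lens <- c("methylation_window_bp", "lumr_min_sites", "lumr_max_gap_bp",
            "te_baseline_min_len_bp", "orientation_flank_bp",
            "heatmap_flank_bp", "body_bins", "flank_bin_bp",
            "promoter_upstream_bp", "promoter_downstream_bp",
            "flank_upstream_bp", "flank_downstream_bp", "kmeans_k",
            "n_expression_bins")
  for (f in lens)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop(f, " must be > 0, got ", cfg[[f]])
  if (cfg$n_permutations < 1) stop("n_permutations must be >= 1")
  if (cfg$asym_fold < 1) stop("asym_fold must be >= 1")
  if (cfg$asym_min_rpm < 0) stop("asym_min_rpm must be >= 0")
  if (cfg$expressed_min_rpkm < 0) stop("expressed_min_rpkm must be >= 0")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("pipeline_config:\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
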