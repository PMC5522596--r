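#' Link enhancer candidates to putative target genes
#'
#' Links each candidate to its nearest flanking genes (directly upstream
#' and downstream by genomic coordinate) using the candidate's
#' tissue-specificity and the genes' expression. For a tissue-specific
#' candidate, a flanking gene links when it is significantly
#' differentially expressed with the higher expression in the candidate's
#' tissue. For a shared candidate, a flanking gene links when it is
#' expressed (RPKM at or above `config$expressed_min_rpkm`) in both
#' tissues. Candidates are categorised as `one_gene`, `both_genes` or
#' `unlinked`; genes overlapping the candidate are excluded defensively.
#'
#' @param candidates an `enhancer_candidates` data frame with filled
#'   `specificity` (ids are taken from a `candidate_id` column if present).
#' @param genes a `gene_models` object.
#' @param expression expression table (see [read_expression()]); its
#'   tissue columns must match the candidate detection columns.
#' @param config a [pipeline_config()].
#' @return A data frame of class `target_links`, one row per candidate:
#'   coordinates, specificity, upstream/downstream gene ids, distances,
#'   per-gene linked flags, `link_category` and linked gene id(s).
#' @export
link_targets <- function(candidates, genes, expression,
                         config = pipeline_config()) {
  tissues <- candidate_tissues(candidates)
  if (!all(tissues %in% names(expression)))
    stop("expression table lacks tissue column(s): ",
         paste(setdiff(tissues, names(expression)), collapse = ", "))
  gs <- gene_spans(genes)
  # interval_set() sorts; map flanking results back to candidate row order
  fl <- nearest_flanking(
    interval_set(candidates$chrom, candidates$start, candidates$end),
    gs)
  ord <- order(candidates$chrom, candidates$start, candidates$end)
  fl_orig <- fl
  fl_orig[ord, ] <- fl
  fl <- fl_orig

  link_gene <- function(gene_id, spec) {
    if (is.na(gene_id)) return(FALSE)
    row <- expression[match(gene_id, expression$gene_id), , drop = FALSE]
    if (nrow(row) == 0 || is.na(row$gene_id)) return(FALSE)
    if (spec == "shared")
      return(all(vapply(tissues, function(t)
        row[[t]] >= config$expressed_min_rpkm, logical(1))))
    tis <- sub("-specific$", "", spec)
    isTRUE(row$significant_de) && identical(row$higher_tissue, tis)
  }

  n <- nrow(candidates)
  up_link <- logical(n); dn_link <- logical(n)
  for (i in seq_len(n)) {
    up_link[i] <- link_gene(fl$upstream[i], candidates$specificity[i])
    dn_link[i] <- link_gene(fl$downstream[i], candidates$specificity[i])
  }
  category <- ifelse(up_link & dn_link, "both_genes",
                     ifelse(up_link | dn_link, "one_gene", "unlinked"))
  no_flank <- is.na(fl$upstream) & is.na(fl$downstream)
  if (any(no_flank))
    warning(sum(no_flank), " candidate(s) with no flanking gene")
  linked <- mapply(function(u, d, ul, dl) {
    g <- c(if (ul) u, if (dl) d)
    if (length(g) == 0) NA_character_ else paste(g, collapse = ",")
  }, fl$upstream, fl$downstream, up_link, dn_link)
  out <- data.frame(
    chrom = candidates$chrom, start = candidates$start,
    end = candidates$end,
    candidate_id = if (!is.null(candidates[["candidate_id"]]))
      candidates$candidate_id else sprintf("cand_%d", seq_len(n)),
    specificity = candidates$specificity,
    upstream_gene = fl$upstream, upstream_dist = fl$upstream_dist,
    upstream_linked = up_link,
    downstream_gene = fl$downstream, downstream_dist = fl$downstream_dist,
    downstream_linked = dn_link,
    link_category = category, linked_genes = unname(linked),
    stringsAsFactors = FALSE)
  class(out) <- c("target_links", "data.frame")
  out
}

#' @export
print.target_links <- function(x, ...) {
  cat(sprintf("target_links: %d candidate(s)\n", nrow(x)))
  print(table(x$specificity, x$link_category))
  invisible(x)
}
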