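#' Gene models from GFF3
#'
#' Reads `gene` and `exon` features from a GFF3 file (1-based closed
#' coordinates, converted on read to the package's 0-based half-open
#' convention). Exons are attached to genes through their `Parent`
#' attribute. A gene without annotated exons is treated as a single exon
#' spanning the gene, with a warning.
#'
#' @param path GFF3 file.
#' @return An object of class `gene_models`: a list with `genes` (data
#'   frame: `gene_id`, `chrom`, `start`, `end`, `strand`, `tss`, `tts`) and
#'   `exons` (an `interval_set` named by gene id). The TSS is the 5' gene
#'   boundary on the gene's strand (start for `+`, end for `-`), the TTS
#'   the 3' boundary.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  gr$seqnames <- as.character(gr$seqnames)
  gr$strand <- as.character(gr$strand)
  genes <- gr[gr$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) stop("no gene features in ", path)
  gene_id <- if (!is.null(genes$ID)) as.character(genes$ID) else
    sprintf("gene_%d", seq_len(nrow(genes)))
  gdf <- data.frame(gene_id = gene_id, chrom = genes$seqnames,
                    start = genes$start - 1L, end = genes$end,
                    strand = ifelse(genes$strand %in% c("+", "-"),
                                    genes$strand, "+"),
                    stringsAsFactors = FALSE)
  gdf$tss <- ifelse(gdf$strand == "+", gdf$start, gdf$end)
  gdf$tts <- ifelse(gdf$strand == "+", gdf$end, gdf$start)
  ex <- gr[gr$type == "exon", , drop = FALSE]
  parent <- if (nrow(ex) > 0 && !is.null(ex$Parent))
    vapply(ex$Parent, function(p) as.character(p)[1], character(1))
  else character(nrow(ex))
  edf <- data.frame(chrom = ex$seqnames, start = ex$start - 1L, end = ex$end,
                    name = parent, stringsAsFactors = FALSE)
  missing_ex <- setdiff(gdf$gene_id, edf$name)
  if (length(missing_ex) > 0) {
    warning(length(missing_ex),
            " gene(s) without exons treated as single-exon")
    add <- gdf[gdf$gene_id %in% missing_ex,
               c("chrom", "start", "end", "gene_id")]
    names(add)[4] <- "name"
    edf <- rbind(edf, add)
  }
  exons <- interval_set(edf$chrom, edf$start, edf$end, name = edf$name)
  structure(list(genes = gdf[order(gdf$chrom, gdf$start), , drop = FALSE],
                 exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d exons\n",
              nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

# Gene spans of a gene_models object as an interval_set named by gene id.
gene_spans <- function(gm) {
  interval_set(gm$genes$chrom, gm$genes$start, gm$genes$end,
               name = gm$genes$gene_id, strand = gm$genes$strand)
}

#' Transposable-element annotation
#'
#' Reads TE features from GFF3 carrying `family` and `superfamily`
#' attributes (superfamily one of LTR, TIR, helitron, other).
#'
#' @param path GFF3 file of TE features.
#' @return A data frame of class `te_annotation` with columns `chrom`,
#'   `start`, `end` (0-based half-open), `family`, `superfamily`.
#' @export
read_te_annotation <- function(path) {
  if (!file.exists(path)) stop("TE annotation not found: ", path)
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  fam <- if (!is.null(gr$family)) as.character(gr$family) else
    if (!is.null(gr$ID)) as.character(gr$ID) else
      sprintf("TE%05d", seq_len(nrow(gr)))
  if (any(is.na(fam) | !nzchar(fam))) stop("TE family ids must be non-empty")
  sup <- if (!is.null(gr$superfamily)) as.character(gr$superfamily) else
    rep("other", nrow(gr))
  df <- data.frame(chrom = as.character(gr$seqnames), start = gr$start - 1L,
                   end = gr$end, family = fam, superfamily = sup,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("te_annotation", "data.frame")
  df
}

te_intervals <- function(tes) {
  interval_set(tes$chrom, tes$start, tes$end, name = tes$family)
}

#' Chromosome lengths
#'
#' Reads a two-column tab-delimited file (chromosome, length in bp).
#'
#' @param path file path.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("chromosome size file needs two columns")
  if (any(df[[2]] <= 0)) stop("chromosome lengths must be > 0")
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Gene expression table
#'
#' Reads a tab-delimited table with header: `gene_id`, one RPKM column per
#' tissue (named by tissue label), `significant_de` (logical) and
#' `higher_tissue` (tissue label or `none`). `higher_tissue` is meaningful
#' only for significantly differentially expressed genes.
#'
#' @param path file path.
#' @return data frame with the columns above.
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("gene_id", "significant_de", "higher_tissue")
  if (!all(need %in% names(df)))
    stop("expression table must contain columns: ",
         paste(need, collapse = ", "))
  df$significant_de <- as.logical(df$significant_de)
  df
}

# tissue RPKM columns of an expression table (everything that is not a
# bookkeeping column)
expression_tissues <- function(expr) {
  setdiff(names(expr), c("gene_id", "significant_de", "higher_tissue"))
}
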