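mk_gene_models <- function(df, exons = NULL) {
  df$tss <- ifelse(df$strand == "+", df$start, df$end)
  df$tts <- ifelse(df$strand == "+", df$end, df$start)
  if (is.null(exons))
    exons <- interval_set(df$chrom, df$start, df$end, name = df$gene_id)
  structure(list(genes = df, exons = exons), class = "gene_models")
}

test_that("promoters and flanks follow the strand-aware definitions", {
  genome <- c(c = 20000)
  gm <- mk_gene_models(data.frame(
    gene_id = "g1", chrom = "c", start = 5000, end = 8000, strand = "+",
    stringsAsFactors = FALSE))
  p <- partition_genome(gm, NULL, genome)
  expect_equal(as.data.frame(p$promoter)[, 2:3],
               data.frame(start = 4000L, end = 5000L))
  # upstream flank 4 kb before the promoter, downstream 5 kb after the TTS
  fl <- as.data.frame(p$flanking)
  expect_true(any(fl$start == 0 & fl$end == 4000))
  expect_true(any(fl$start == 8000 & fl$end == 13000))

  gm2 <- mk_gene_models(data.frame(
    gene_id = "g1", chrom = "c", start = 5000, end = 8000, strand = "-",
    stringsAsFactors = FALSE))
  p2 <- partition_genome(gm2, NULL, genome)
  expect_equal(as.data.frame(p2$promoter)[, 2:3],
               data.frame(start = 8000L, end = 9000L))
})

test_that("partition classes are disjoint and cover the genome", {
  set.seed(21)
  genome <- c(c1 = 100000, c2 = 60000)
  gdf <- data.frame(
    gene_id = sprintf("g%d", 1:8),
    chrom = rep(c("c1", "c2"), c(5, 3)),
    start = c(sort(sample(seq(2000, 90000, by = 12000), 5)),
              sort(sample(seq(3000, 50000, by = 16000), 3))),
    strand = sample(c("+", "-"), 8, replace = TRUE),
    stringsAsFactors = FALSE)
  gdf$end <- gdf$start + sample(2000:4000, 8)
  gm <- mk_gene_models(gdf)
  tes <- data.frame(chrom = c("c1", "c2"), start = c(50000, 10000),
                    end = c(52000, 11000),
                    family = "F", superfamily = "LTR")
  class(tes) <- c("te_annotation", "data.frame")
  p <- partition_genome(gm, tes, genome)
  total <- sum(vapply(p, iv_total_bp, numeric(1)))
  expect_equal(total, sum(genome))
  for (i in seq_along(p)) for (j in seq_along(p)) {
    if (i < j)
      expect_equal(iv_total_bp(iv_intersect(p[[i]], p[[j]])), 0L)
  }
})

test_that("genes without exons and intronic TEs are handled", {
  genome <- c(c = 30000)
  # two-exon gene: intron in the middle; TE inside the intron counts intron
  gdf <- data.frame(gene_id = "g1", chrom = "c", start = 10000, end = 16000,
                    strand = "+", stringsAsFactors = FALSE)
  exons <- interval_set(c("c", "c"), c(10000, 14000), c(12000, 16000),
                        name = c("g1", "g1"))
  gm <- mk_gene_models(gdf, exons)
  tes <- data.frame(chrom = "c", start = 12500, end = 13500,
                    family = "F", superfamily = "LTR")
  class(tes) <- c("te_annotation", "data.frame")
  p <- partition_genome(gm, tes, genome)
  expect_equal(iv_total_bp(p$intron), 2000L)
  expect_equal(iv_total_bp(p$TE), 0L)   # intronic TE bases are intron
})

test_that("features are assigned to the class of their midpoint", {
  genome <- c(c = 30000)
  gm <- mk_gene_models(data.frame(
    gene_id = "g1", chrom = "c", start = 10000, end = 16000, strand = "+",
    stringsAsFactors = FALSE))
  p <- partition_genome(gm, NULL, genome)
  feats <- interval_set(rep("c", 3),
                        c(9500, 9900, 25000),   # promoter, straddler, distal
                        c(9700, 10100, 25200))
  tab <- classify_features(feats, p)
  # the straddler's midpoint (10000) falls on the first exonic base
  expect_equal(tab$count[tab$class == "promoter"], 1L)
  expect_equal(tab$count[tab$class == "exon"], 1L)
  expect_equal(tab$count[tab$class == "distal"], 1L)
  expect_equal(sum(tab$count), 3L)
  expect_true(all(tab$count_fraction >= 0 & tab$count_fraction <= 1))

  empty <- classify_features(interval_set(), p)
  expect_true(all(empty$count == 0))

  # occupancy sums to feature-within-mask bp across classes
  mask <- interval_set("c", 0, 30000)
  tab2 <- classify_features(feats, p, mask)
  expect_equal(sum(tab2$occupied_bp), iv_total_bp(feats))
})
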