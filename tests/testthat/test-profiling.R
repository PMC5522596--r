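test_that("DHS orientation applies the 0.5 RPM / 2-fold rules", {
  g <- c(c = 10000)
  dhs <- interval_set("c", 2000, 2400)
  # upstream flank [1700,2000), downstream [2400,2700)
  tr <- function(up, dn) make_track("c", c(1700, 2400), c(2000, 2700),
                                    c(up, dn), genome = g)
  o <- orient_dhs(dhs, tr(0.2, 1.0))
  expect_equal(o$orientation, "keep")
  expect_true(o$eligible)
  expect_true(o$asymmetric)      # fold 5

  o2 <- orient_dhs(dhs, tr(0.4, 0.6))
  expect_true(o2$eligible)       # 0.6 >= 0.5
  expect_false(o2$asymmetric)    # fold 1.5 < 2

  o3 <- orient_dhs(dhs, tr(0.3, 0.4))
  expect_false(o3$eligible)
  expect_false(o3$asymmetric)

  o4 <- orient_dhs(dhs, tr(1.0, 0.2))
  expect_equal(o4$orientation, "flip")   # higher side becomes 3'

  o5 <- orient_dhs(dhs, tr(0.8, 0.8))
  expect_equal(o5$orientation, "keep")
  expect_true(o5$tie)

  # fold exactly 2 is asymmetric; zero low flank is asymmetric if eligible
  expect_true(orient_dhs(dhs, tr(0.5, 1.0))$asymmetric)
  expect_true(orient_dhs(dhs, tr(0, 1.0))$asymmetric)

  # chromosome-edge DHS: clipped and flagged
  o6 <- orient_dhs(interval_set("c", 100, 400), tr(0.2, 1.0))
  expect_true(o6$clipped)
})

test_that("profile matrices scale bodies, bin flanks and honour flips", {
  g <- c(c = 100000)
  const <- make_track("c", 0, 100000, 3, genome = g)
  feats <- interval_set("c", 5000, 6000)
  m <- build_profile_matrix(feats, const, flank_bp = 1000, body_bins = 50,
                            flank_bin_bp = 20)
  expect_equal(dim(m), c(1L, 150L))
  expect_true(all(m == 3))

  # asymmetric step: flipped row is the mirror of the unflipped row
  step <- make_track("c", c(4000, 5500), c(5500, 7000), c(1, 4), genome = g)
  mk <- build_profile_matrix(feats, step, orientation = "keep")
  mf <- build_profile_matrix(feats, step, orientation = "flip")
  expect_equal(unname(mf[1, ]), rev(unname(mk[1, ])))
  # flipping twice restores the original (involution)
  expect_equal(unname(rev(rev(mk[1, ]))), unname(mk[1, ]))

  # planted narrow peak at +300 bp shows as a spike in the mean profile
  spike <- make_track("c", 6300, 6320, 10, genome = g)
  ms <- build_profile_matrix(feats, spike)
  prof <- colMeans(ms)
  expect_equal(unname(which.max(prof)), 50 + 50 + 16L)  # 300 bp into 3' flank
  expect_equal(sum(prof > 0), 1L)

  # features shorter than body_bins are interpolated per bp
  short <- build_profile_matrix(interval_set("c", 5000, 5010), const)
  expect_true(all(short[1, 51:100] == 3))
})

test_that("k-means categories are deterministic and conserve the mean", {
  set.seed(2)
  a <- matrix(rep(c(rep(5, 20), rep(0, 20)), each = 30), nrow = 30) +
    rnorm(30 * 40, sd = 0.05)
  b <- matrix(rep(c(rep(0, 20), rep(5, 20)), each = 30), nrow = 30) +
    rnorm(30 * 40, sd = 0.05)
  m <- rbind(a, b)
  k2 <- kmeans_categories(m, k = 2, seed = 9)
  expect_equal(length(unique(k2$labels[1:30])), 1L)
  expect_equal(length(unique(k2$labels[31:60])), 1L)
  expect_false(k2$labels[1] == k2$labels[31])
  expect_identical(k2$labels, kmeans_categories(m, k = 2, seed = 9)$labels)

  # weighted mean of category profiles equals the global mean profile
  glob <- colMeans(m)
  wmean <- colSums(k2$centers * k2$sizes) / sum(k2$sizes)
  expect_equal(unname(wmean), unname(glob), tolerance = 1e-6)

  expect_error(kmeans_categories(m, k = 100), "exceeds")
  ident <- matrix(1, nrow = 5, ncol = 10)
  expect_warning(kd <- kmeans_categories(ident, k = 3, seed = 1),
                 "distinct")
  expect_equal(unique(kd$labels), 1L)
})

test_that("expression bins split genes above 1 RPKM into equal counts", {
  expr <- data.frame(gene_id = sprintf("g%d", 1:7),
                     t1 = c(0.5, 2, 3, 4, 5, 6, 7),
                     significant_de = FALSE, higher_tissue = "none",
                     stringsAsFactors = FALSE)
  b <- expression_bins(expr, "t1")
  expect_equal(b$bin[1], 0L)
  expect_equal(sort(b$bin[-1]), 1:6)

  expr$t1 <- rep(0.1, 7)
  expect_error(expression_bins(expr, "t1"), "fewer than")

  set.seed(4)
  expr2 <- data.frame(gene_id = sprintf("g%d", 1:200),
                      t1 = c(runif(40, 0, 0.9), rlnorm(160, 1, 1) + 1),
                      significant_de = FALSE, higher_tissue = "none")
  b2 <- expression_bins(expr2, "t1")
  sizes <- table(b2$bin[b2$bin > 0])
  expect_lte(max(sizes) - min(sizes), 1)
})

test_that("gene metaprofiles are oriented and ordered by expression bin", {
  g <- c(c = 200000)
  n <- 12
  starts <- seq(10000, 180000, length.out = n)
  gdf <- data.frame(gene_id = sprintf("g%d", 1:n), chrom = "c",
                    start = as.integer(starts),
                    end = as.integer(starts) + 2000L,
                    strand = "+", stringsAsFactors = FALSE)
  gdf$tss <- gdf$start; gdf$tts <- gdf$end
  gm <- structure(list(genes = gdf,
                       exons = interval_set(gdf$chrom, gdf$start, gdf$end,
                                            name = gdf$gene_id)),
                  class = "gene_models")
  # TSS-proximal peak height grows with expression
  rpkm <- seq(2, 24, length.out = n)
  tr <- make_track("c", gdf$start, gdf$start + 200L, rpkm, genome = g)
  expr <- data.frame(gene_id = gdf$gene_id, t1 = rpkm,
                     significant_de = FALSE, higher_tissue = "none")
  bins <- expression_bins(expr, "t1")
  prof <- gene_metaprofile(gm, tr, bins)
  maxima <- apply(prof, 1, max)
  expect_true(all(diff(maxima) > 0))   # monotone across bins 1..6

  flat <- gene_metaprofile(gm, make_track("c", 0, 200000, 1, genome = g),
                           bins)
  expect_true(all(abs(flat - 1) < 1e-9))
})
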