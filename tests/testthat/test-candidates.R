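mk_partition <- function(genome = c(c = 100000), gene = NULL) {
  gdf <- if (is.null(gene))
    data.frame(gene_id = "g1", chrom = "c", start = 50000, end = 55000,
               strand = "+", stringsAsFactors = FALSE)
  else gene
  gdf$tss <- ifelse(gdf$strand == "+", gdf$start, gdf$end)
  gdf$tts <- ifelse(gdf$strand == "+", gdf$end, gdf$start)
  gm <- structure(list(
    genes = gdf,
    exons = interval_set(gdf$chrom, gdf$start, gdf$end,
                         name = gdf$gene_id)), class = "gene_models")
  partition_genome(gm, NULL, genome)
}

test_that("integration requires all three features and intergenic space", {
  part <- mk_partition()
  lumrs <- interval_set("c", c(1000, 10000, 48950), c(2000, 11000, 49500))
  dhs <- list(t1 = interval_set("c", c(1200, 10100, 49000),
                                c(1300, 10200, 49100)))
  k9_all <- list(t1 = interval_set("c", c(1400, 10500, 49050),
                                   c(1600, 10600, 49150)))
  cand <- integrate_candidates(lumrs, dhs, k9_all, part)
  # third LUMR overlaps the promoter ([49000, 50000)) and is excluded
  expect_equal(nrow(cand), 2L)
  expect_equal(cand$start, c(1000L, 10000L))

  # remove H3K9ac support for the first LUMR: no longer a candidate
  k9_b <- list(t1 = interval_set("c", 10500, 10600))
  cand2 <- integrate_candidates(lumrs, dhs, k9_b, part)
  expect_equal(nrow(cand2), 1L)
  expect_equal(cand2$start, 10000L)
})

test_that("specificity counts satisfy the union identity", {
  part <- mk_partition()
  lumrs <- interval_set("c", c(1000, 10000, 20000), c(2000, 11000, 21000))
  mk <- function(starts)
    interval_set("c", starts, starts + 100)
  dhs <- list(a = mk(c(1100, 10100)), b = mk(c(10100, 20100)))
  k9 <- list(a = mk(c(1500, 10500)), b = mk(c(10500, 20500)))
  cand <- integrate_candidates(lumrs, dhs, k9, part)
  tab <- table(cand$specificity)
  expect_equal(unname(tab[["a-specific"]]), 1L)
  expect_equal(unname(tab[["b-specific"]]), 1L)
  expect_equal(unname(tab[["shared"]]), 1L)
  expect_equal(sum(tab), nrow(cand))
})

test_that("ranking combines signed contrasts with deterministic ties", {
  lumrs <- interval_set("c", c(1000, 10000, 20000), c(2000, 11000, 21000))
  dhs_set <- interval_set("c", c(1100, 10100, 20100),
                          c(1200, 10200, 20200))
  k9_set <- interval_set("c", c(1500, 10500, 20500),
                         c(1600, 10600, 20600))
  part2 <- mk_partition(genome = c(c = 100000))
  cand <- integrate_candidates(lumrs, list(a = dhs_set, b = dhs_set),
                               list(a = k9_set, b = k9_set), part2)
  # craft tracks: candidate 1 strongest DNase contrast, candidate 2
  # strongest H3K9ac contrast, candidate 3 negative in both
  dn_a <- make_track("c", c(1000, 10000, 20000), c(2000, 11000, 21000),
                     c(5, 3, 0.2), genome = c(c = 100000))
  dn_b <- make_track("c", c(1000, 10000, 20000), c(2000, 11000, 21000),
                     c(1, 1, 1), genome = c(c = 100000))
  k9_a <- make_track("c", c(1000, 10000, 20000), c(2000, 11000, 21000),
                     c(2, 4, 0.2), genome = c(c = 100000))
  k9_b <- make_track("c", c(1000, 10000, 20000), c(2000, 11000, 21000),
                     c(1, 1, 1), genome = c(c = 100000))
  r <- rank_candidates(cand, "a", list(a = dn_a, b = dn_b),
                       list(a = k9_a, b = k9_b))
  expect_equal(r$dnase_rank, c(1L, 2L, 3L))
  expect_equal(r$k9_rank, c(2L, 1L, 3L))
  expect_equal(r$rank_sum, c(3L, 3L, 6L))
  # tie on the sum broken by DNase rank
  expect_equal(r$overall_rank, c(1L, 2L, 3L))
  expect_equal(r$candidate_id, c("A1", "A2", "A3"))
  # candidate below the other tissue everywhere: negative diff, last rank
  expect_lt(r$dnase_diff[3], 0)

  r1 <- rank_candidates(cand[1, ], "a", list(a = dn_a, b = dn_b),
                        list(a = k9_a, b = k9_b))
  expect_equal(r1$overall_rank, 1L)
  expect_equal(r1$candidate_id, "A1")
})

test_that("rank-sum permutation p matches exhaustive enumeration at N = 3", {
  # all 36 pairs of permutations of (1,2,3): position-wise sums, sorted
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  hits <- 0
  for (i in 1:6) for (j in 1:6)
    if (sort(perms[i, ] + perms[j, ])[1] <= 2) hits <- hits + 1
  expect_equal(hits / 36, 1 / 3)   # the exhaustive null probability

  p <- rank_permutation_p(c(2, 4, 6), n_lists = 2, n_perm = 20000, seed = 5)
  expect_lt(abs(p[1] - 1 / 3), 0.02)

  # the maximal possible sum at the last rank can never be exceeded
  p2 <- rank_permutation_p(c(2, 4, 2 * 3), n_perm = 500, seed = 1)
  expect_equal(p2[3], 1)

  # determinism contract
  pa <- rank_permutation_p(c(5, 3, 8, 2), n_perm = 200, seed = 42)
  pb <- rank_permutation_p(c(5, 3, 8, 2), n_perm = 200, seed = 42)
  pc <- rank_permutation_p(c(5, 3, 8, 2), n_perm = 200, seed = 43)
  expect_identical(pa, pb)
  expect_false(identical(pa, pc))
  expect_true(all(pa > 0 & pa <= 1))
})
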