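mk_tes <- function(start, end, family = "F1", superfamily = "LTR",
                   chrom = "c") {
  df <- data.frame(chrom = chrom, start = start, end = end,
                   family = family, superfamily = superfamily,
                   stringsAsFactors = FALSE)
  class(df) <- c("te_annotation", "data.frame")
  df
}

test_that("the TE baseline drops short, intronic and nested elements", {
  tes <- mk_tes(c(0, 5000, 5100, 20000, 30000),
                c(500, 8000, 5600, 21000, 30700),
                family = c("A", "B", "C", "D", "E"))
  introns <- interval_set("c", 29500, 31000)
  base <- te_baseline(tes, introns, min_len = 635)
  # A is short (500), C nested inside B, E intronic -> B and D remain
  expect_equal(sort(base$family), c("B", "D"))

  # boundary: exactly 635 bp is dropped ("longer than")
  tes2 <- mk_tes(c(0, 1000), c(635, 1636), family = c("X", "Y"))
  expect_equal(te_baseline(tes2, NULL)$family, "Y")
})

test_that("TE containment needs 80% within a single element", {
  cands <- data.frame(chrom = "c", start = c(1000, 5000, 9000),
                      end = c(2000, 6000, 9500))
  tes <- mk_tes(c(900, 4500, 5500, 8800),
                c(1850, 5500, 6500, 9600),
                family = c("F1", "F2", "F3", "F4"))
  ct <- te_containment(cands, tes, min_frac = 0.80)
  expect_true(ct$contained[1])              # 850/1000 within F1
  expect_false(ct$contained[2])             # two adjacent TEs, 500 bp each
  expect_true(ct$any_overlap[2])
  expect_true(ct$contained[3])
  expect_true(ct$fully_within[3])           # entirely inside F4
  expect_equal(ct$te_family[3], "F4")
  expect_true(ct$position_frac[3] > 0 && ct$position_frac[3] < 1)
})

test_that("family enrichment reproduces the closed-form binomial tail", {
  base <- mk_tes(seq(0, 99000, by = 1000), seq(700, 99700, by = 1000),
                 family = rep(c("f", sprintf("g%d", 1:9)), each = 10))
  contains <- rep(FALSE, 100)
  contains[c(1, 2, 3, 11, 21)] <- TRUE      # K = 5, k_f = 3 for family f
  fe <- family_enrichment(base, contains)
  row_f <- fe[fe$family == "f", ]
  expect_equal(row_f$members, 10L)
  expect_equal(row_f$containing, 3L)
  expect_equal(row_f$p, pbinom(2, 5, 0.1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(row_f$p, 0.00856, tolerance = 1e-6)
  n_tested <- sum(fe$containing >= 1)
  expect_equal(row_f$p_adj, min(1, row_f$p * n_tested))
  expect_true(all(fe$p[fe$containing == 0] == 1))
  expect_equal(sum(fe$containing), 5L)

  # a single family covering the whole baseline can never be enriched
  base2 <- mk_tes(seq(0, 9000, by = 1000), seq(700, 9700, by = 1000),
                  family = "only")
  fe2 <- family_enrichment(base2, rep(c(TRUE, FALSE), 5))
  expect_equal(fe2$p, 1)

  # monotone: more containing members never increases p
  ps <- vapply(1:5, function(k) {
    cc <- rep(FALSE, 100); cc[seq_len(k)] <- TRUE; cc[c(11, 21)] <- TRUE
    fe <- family_enrichment(base, cc)
    fe$p[fe$family == "f"]
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("motif scanning counts both strands and matches brute force", {
  expect_equal(motif_scan("AAGGCCCATT")$count, 1L)
  expect_equal(motif_scan("AATGGGCCTT")$count, 1L)   # reverse-strand hit
  expect_equal(motif_scan("")$count, 0L)
  # overlapping occurrences are counted
  expect_equal(motif_scan("AAAAAA", motif = "AAA")$count,
               bf_motif_count("AAAAAA", "AAA"))
  set.seed(31)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(500:10000, 1),
                      replace = TRUE), collapse = "")
    expect_equal(motif_scan(s)$count, bf_motif_count(s, "GGCCCA"))
  }
})

test_that("motif enrichment detects planted motifs and stays null-calibrated", {
  set.seed(17)
  chrom <- paste(sample(c("A", "C", "T"), 50000, replace = TRUE),
                 collapse = "")   # G-free background: no chance motifs
  cand <- data.frame(chrom = "c", start = seq(1000, 19000, by = 2000),
                     end = seq(1000, 19000, by = 2000) + 500)
  for (s in cand$start)
    substr(chrom, s + 100, s + 105) <- "GGCCCA"
  genome_seq <- Biostrings::DNAStringSet(c(c = chrom))
  intergenic <- interval_set("c", 25000, 50000)
  me <- motif_enrichment(cand, genome_seq, intergenic, n_draws = 100,
                         seed = 3)
  expect_equal(me$observed_frac, 1)
  expect_true(is.infinite(me$fold) || me$fold > 100)
  expect_lte(me$p, 1 / 100)

  # candidates drawn from the background itself: fold near 1 on average
  g2 <- paste(sample(c("A", "C", "G", "T"), 200000, replace = TRUE),
              collapse = "")
  genome2 <- Biostrings::DNAStringSet(c(c = g2))
  all_iv <- interval_set("c", 0, 200000)
  reps <- lapply(1:6, function(r) {
    set.seed(100 + r)
    bgc <- as.data.frame(enhscan:::random_placement(rep(600, 100), all_iv))
    motif_enrichment(bgc, genome2, all_iv, n_draws = 150, seed = 200 + r)
  })
  folds <- vapply(reps, `[[`, numeric(1), "fold")
  ps <- vapply(reps, `[[`, numeric(1), "p")
  expect_lt(abs(mean(folds) - 1), 0.15)
  expect_gt(stats::median(ps), 0.05)

  # motif absent everywhere: flagged, fold undefined
  me3 <- motif_enrichment(cand[1, ], genome2, all_iv, n_draws = 20,
                          seed = 1, motif = "GGTAGGTAGGTAGGTA")
  expect_false(me3$motif_found)
  expect_true(is.nan(me3$fold))
})

test_that("permutation enrichment flags planted structure and boundaries", {
  mask <- interval_set("m", 0, 100000)
  cls <- interval_set("m", 40000, 60000)
  inside <- interval_set("m", seq(41000, 58000, by = 2000),
                         seq(41000, 58000, by = 2000) + 300)
  pe <- permutation_enrichment(inside, cls, mask, n = 200, seed = 2)
  expect_equal(pe$observed, nrow(inside))
  expect_equal(pe$p_enrich, 1 / 201)      # no null reaches the maximum

  pe0 <- permutation_enrichment(interval_set(), cls, mask, n = 50, seed = 1)
  expect_equal(pe0$p_enrich, 1)

  expect_error(permutation_enrichment(interval_set("m", 0, 99999),
                                      cls,
                                      interval_set("m", 0, 1000),
                                      n = 5, seed = 1),
               "longer than")
})

test_that("CNS overlap uses half-open >= 1 bp semantics", {
  cand <- data.frame(chrom = "c", start = c(100, 500), end = c(200, 600))
  cns <- interval_set("c", c(150, 200), c(160, 210))
  fl <- cns_overlap(cand, cns)
  expect_true(fl[1])
  expect_false(fl[2])      # abutting [200,210) does not overlap [100,200)
  expect_equal(attr(fl, "count"), 1L)
  expect_false(any(cns_overlap(cand, interval_set())))
})
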