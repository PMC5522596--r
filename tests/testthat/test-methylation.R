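mk_sites <- function(pos, freq, context = "CG", chrom = "c", coverage = 10) {
  df <- data.frame(chrom = chrom, pos = pos, context = context,
                   frequency = freq, coverage = coverage,
                   stringsAsFactors = FALSE)
  class(df) <- c("methylation_sites", "data.frame")
  df
}

test_that("low-methylation segmentation follows the run rules", {
  # five low sites within 200 bp: one region spanning first..last+1
  s <- mk_sites(c(100, 150, 200, 250, 300), 0.10)
  r <- segment_low_methylation(s, "CG", min_sites = 4)
  expect_equal(nrow(r), 1L)
  expect_equal(c(r$start, r$end), c(100L, 301L))

  # a high site splits the run; both halves still pass min_sites = 2
  s2 <- mk_sites(seq(100, 600, by = 100),
                 c(0.1, 0.1, 0.9, 0.1, 0.1, 0.1))
  r2 <- segment_low_methylation(s2, "CG", min_sites = 2, max_gap_bp = 300)
  expect_equal(nrow(r2), 2L)

  # sites at exactly the threshold are not low (strict <)
  s3 <- mk_sites(c(100, 150, 200, 250), 0.20)
  expect_equal(nrow(segment_low_methylation(s3, "CG", min_sites = 2)), 0L)

  # a gap wider than max_gap_bp splits the run
  s4 <- mk_sites(c(100, 150, 800, 850), 0.05)
  r4 <- segment_low_methylation(s4, "CG", min_sites = 2, max_gap_bp = 300)
  expect_equal(nrow(r4), 2L)

  # zero-coverage sites are skipped, not imputed
  s5 <- mk_sites(c(100, 150, 200, 250), c(0.1, 0.9, 0.1, 0.1),
                 coverage = c(10, 0, 10, 10))
  r5 <- segment_low_methylation(s5, "CG", min_sites = 3)
  expect_equal(nrow(r5), 1L)

  expect_warning(segment_low_methylation(mk_sites(1, 0.5, coverage = 0),
                                         "CG"), "no covered")
})

test_that("LUMRs are the CG/CHG intersection", {
  cg <- interval_set("c", 0, 1000)
  chg <- interval_set("c", 500, 1500)
  lum <- combine_lumr(cg, chg)
  expect_equal(c(lum$start, lum$end), c(500L, 1000L))
  expect_equal(nrow(combine_lumr(cg, interval_set("c", 2000, 3000))), 0L)
  expect_equal(as.data.frame(combine_lumr(cg, cg))[, 1:3],
               as.data.frame(cg)[, 1:3], ignore_attr = TRUE)
})

test_that("the windowed mean filter drops regions at or above 20%", {
  reg <- interval_set("c", c(0, 1000, 2000), c(500, 1500, 2500))
  sites <- rbind(
    mk_sites(seq(50, 450, by = 50), 0.05),
    mk_sites(seq(1050, 1450, by = 50), 0.25),
    mk_sites(seq(2050, 2450, by = 50), 0.20))
  out <- filter_mean_methylation(reg, sites, max_mean = 0.20)
  expect_equal(nrow(out), 1L)                 # 0.25 and exactly 0.20 dropped
  expect_equal(out$start, 0L)
  expect_warning(
    keepall <- filter_mean_methylation(interval_set("c", 9000, 9500), sites),
    "without covered sites")
  expect_equal(nrow(keepall), 1L)             # uncontradicted: retained
})

test_that("every called LUMR satisfies the 20% ceiling by construction", {
  set.seed(8)
  pos <- seq(100, 20000, by = 60)
  freq_cg <- ifelse(pos > 5000 & pos < 8000, 0.03, 0.9)
  freq_chg <- ifelse(pos > 5000 & pos < 8000, 0.05, 0.8)
  sites <- rbind(mk_sites(pos, freq_cg, "CG"),
                 mk_sites(pos + 7, freq_chg, "CHG"))
  lum <- call_lumrs(sites, pipeline_config())
  expect_gt(nrow(lum), 0)
  for (i in seq_len(nrow(lum))) {
    for (ctx in c("CG", "CHG")) {
      sel <- sites$context == ctx & sites$pos >= lum$start[i] &
        sites$pos < lum$end[i]
      expect_lt(mean(sites$frequency[sel]), 0.20)
    }
  }
  # recovered LUMR covers >= 99% of the planted valley
  valley <- interval_set("c", 5060, 7941)   # first..last low site + 1
  expect_gte(iv_total_bp(iv_intersect(lum, valley)) / iv_total_bp(valley),
             0.99)

  # lowering the threshold never increases total LUMR bp
  bp_prev <- Inf
  for (th in c(0.5, 0.3, 0.2, 0.1, 0.02)) {
    bp <- iv_total_bp(call_lumrs(sites, pipeline_config(
      methylation_threshold = th)))
    expect_lte(bp, bp_prev)
    bp_prev <- bp
  }
})
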