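test_that("interval_set enforces its invariants", {
  x <- interval_set("chr1", c(500, 0), c(900, 100))
  expect_s3_class(x, "interval_set")
  expect_equal(x$start, c(0L, 500L))        # sorted on construction
  expect_error(interval_set("chr1", 200, 100), "greater than start")
  expect_error(interval_set("chr1", -5, 100), ">= 0")
  expect_error(interval_set("", 0, 10), "non-empty")
})

test_that("BED round-trips and rejects malformed input", {
  x <- interval_set(c("chr2", "chr1", "chr1"), c(10, 100, 0),
                    c(50, 200, 30), name = c("a", "b", "c"))
  f <- tempfile(fileext = ".bed")
  write_bed(x, f)
  y <- read_bed(f)
  expect_equal(as.data.frame(y)[, c("chrom", "start", "end", "name")],
               as.data.frame(x)[, c("chrom", "start", "end", "name")])

  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("chr1\t100"), f)
  expect_error(read_bed(f), "fewer than 3")
  writeLines(c("track name=x", "chr1\tabc\t200"), f)
  expect_error(read_bed(f), "line 2")
})

test_that("overlap_stats matches its arithmetic definition", {
  a <- list(chrom = "c", start = 100, end = 200)
  expect_equal(overlap_stats(a, list(chrom = "c", start = 150, end = 250)),
               list(overlap_bp = 50L, frac_of_a = 0.5, frac_of_b = 0.5))
  expect_equal(overlap_stats(a, a),
               list(overlap_bp = 100L, frac_of_a = 1, frac_of_b = 1))
  expect_equal(overlap_stats(a, list(chrom = "c", start = 300,
                                     end = 400))$overlap_bp, 0L)
  expect_equal(overlap_stats(a, list(chrom = "d", start = 100,
                                     end = 200))$overlap_bp, 0L)
  # symmetry of overlap_bp on random pairs
  set.seed(1)
  for (i in 1:50) {
    p <- list(chrom = "c", start = (s <- sample(900, 1)),
              end = s + sample(200, 1))
    q <- list(chrom = "c", start = (s2 <- sample(900, 1)),
              end = s2 + sample(200, 1))
    expect_identical(overlap_stats(p, q)$overlap_bp,
                     overlap_stats(q, p)$overlap_bp)
  }
})

test_that("set algebra matches the textbook examples", {
  a <- interval_set("c", 0, 1000)
  b <- interval_set("c", 500, 1500)
  expect_equal(as.data.frame(iv_intersect(a, b))[, 2:3],
               data.frame(start = 500L, end = 1000L))
  s <- iv_subtract(interval_set("c", 0, 1000), interval_set("c", 200, 300))
  expect_equal(s$start, c(0L, 300L))
  expect_equal(s$end, c(200L, 1000L))
  m <- iv_merge(interval_set("c", c(0, 100), c(100, 200)))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(0L, 200L))
})

test_that("set algebra agrees with the per-base oracle on random sets", {
  set.seed(42)
  for (i in 1:150) {
    a <- random_ivs(sample(50, 1))
    b <- random_ivs(sample(50, 1))
    for (op in c("intersect", "subtract")) {
      got <- if (op == "intersect") iv_intersect(a, b) else iv_subtract(a, b)
      want <- bf_setop(a, b, op, "c", 10000)
      expect_equal(as.data.frame(got)[, c("start", "end")],
                   want[, c("start", "end")], ignore_attr = TRUE)
    }
    got <- iv_merge(a)
    want <- bf_setop(a, interval_set(), "union", "c", 10000)
    expect_equal(as.data.frame(got)[, c("start", "end")],
                 want[, c("start", "end")], ignore_attr = TRUE)
  }
})

test_that("signal_stat means, maxima and mass conservation hold", {
  tr <- make_track("c", 0, 100, 2.0, genome = c(c = 100))
  iv <- interval_set("c", 10, 60)
  expect_equal(signal_stat(tr, iv, "mean"), 2.0)
  expect_equal(signal_stat(tr, iv, "max"), 2.0)

  tr2 <- make_track(c("c", "c"), c(0, 50), c(50, 100), c(4, 0))
  iv2 <- interval_set("c", 0, 100)
  expect_equal(signal_stat(tr2, iv2, "mean"), 2.0)
  expect_equal(signal_stat(tr2, iv2, "max"), 4.0)

  expect_error(signal_stat(tr, interval_set("zz", 0, 10)), "zz")

  # conservation: whole-chromosome mean x length = total mass
  set.seed(3)
  st <- data.frame(chrom = "c", start = seq(0, 900, by = 100),
                   end = seq(50, 950, by = 100),
                   value = runif(10, 0, 5))
  tr3 <- signal_track(st, genome = c(c = 1000))
  expect_equal(signal_stat(tr3, interval_set("c", 0, 1000), "mean") * 1000,
               sum((st$end - st$start) * st$value))
})

test_that("bedGraph round-trips and WIG converts to the same track", {
  st <- data.frame(chrom = c("c", "c", "d"), start = c(0, 200, 10),
                   end = c(100, 350, 20), value = c(1.5, 2, 0.25))
  tr <- signal_track(st)
  f <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  tr2 <- read_bedgraph(f)
  expect_equal(signal_stat(tr2, interval_set("c", 0, 350), "mean"),
               signal_stat(tr, interval_set("c", 0, 350), "mean"))

  w <- tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=c start=1 step=10 span=10",
               "1.0", "2.0", "3.0"), w)
  tw <- read_wig(w)
  expect_equal(signal_stat(tw, interval_set("c", 0, 30), "mean"), 2.0)
  expect_equal(signal_stat(tw, interval_set("c", 10, 20), "max"), 2.0)
})

test_that("nearest_flanking finds closest genes by coordinate", {
  genes <- interval_set(c("c", "c"), c(1000, 9000), c(2000, 10000),
                        name = c("g1", "g2"))
  fl <- nearest_flanking(interval_set("c", 5000, 6000), genes)
  expect_equal(fl$upstream, "g1")
  expect_equal(fl$downstream, "g2")
  expect_equal(fl$upstream_dist, 3000L)
  expect_equal(fl$downstream_dist, 3000L)

  fl2 <- nearest_flanking(interval_set("c", 100, 200), genes)
  expect_true(is.na(fl2$upstream))
  expect_equal(fl2$downstream, "g1")

  # abutting gene: distance 0
  fl3 <- nearest_flanking(interval_set("c", 2000, 2500), genes)
  expect_equal(fl3$upstream, "g1")
  expect_equal(fl3$upstream_dist, 0L)
})
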