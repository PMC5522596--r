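#' Consensus peaks across replicates
#'
#' Collapses per-replicate peak calls into high-confidence consensus
#' regions. A pair of peaks (one per replicate) passes when their overlap
#' covers at least `min_frac` of *both* peak lengths (reciprocal rule,
#' equivalent to BEDtools `-f 0.70 -r` at the default). The retained
#' region is the union of the passing pair; chains (one peak passing
#' against several in the other replicate) merge into a single region.
#' With three replicates, replicates 1 and 2 are integrated first and the
#' result is then compared against replicate 3 by the same rule.
#'
#' @param replicates list of >= 2 `interval_set`s (peaks per replicate,
#'   disjoint within a replicate).
#' @param min_frac required reciprocal overlap fraction, in (0, 1].
#' @return A merged `interval_set` of consensus regions, with an attribute
#'   `report`: per pairwise stage, the number of peaks tested and passing.
#' @examples
#' r1 <- interval_set("c", c(100), c(200))
#' r2 <- interval_set("c", c(110), c(205))
#' consensus_peaks(list(r1, r2))  # kept as [100, 205)
#' @export
consensus_peaks <- function(replicates, min_frac = 0.70) {
  if (!is.list(replicates) || length(replicates) < 2)
    stop("consensus requires at least 2 replicate peak sets")
  if (min_frac <= 0 || min_frac > 1) stop("min_frac must be in (0, 1]")
  report <- list()
  cur <- iv_merge(replicates[[1]])
  for (k in 2:length(replicates)) {
    nxt <- iv_merge(replicates[[k]])
    if (nrow(cur) == 0 || nrow(nxt) == 0) {
      warning("empty replicate peak set; consensus is empty")
      cur <- interval_set(merged = TRUE)
      report[[length(report) + 1]] <-
        data.frame(stage = k - 1, pairs_tested = 0L, pairs_passing = 0L)
      next
    }
    st <- pairwise_consensus(cur, nxt, min_frac)
    cur <- st$regions
    report[[length(report) + 1]] <-
      data.frame(stage = k - 1, pairs_tested = st$tested,
                 pairs_passing = st$passing)
  }
  attr(cur, "report") <- do.call(rbind, report)
  cur
}

pairwise_consensus <- function(a, b, min_frac) {
  ira <- .iv_to_ir(a)
  irb <- .iv_to_ir(b)
  keep <- list()
  tested <- 0L; passing <- 0L
  for (ch in intersect(names(ira), names(irb))) {
    ra <- ira[[ch]]; rb <- irb[[ch]]
    hits <- IRanges::findOverlaps(ra, rb)
    tested <- tested + length(hits)
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- pmin(IRanges::end(ra)[qi], IRanges::end(rb)[si]) -
      pmax(IRanges::start(ra)[qi], IRanges::start(rb)[si]) + 1L
    ok <- ov >= min_frac * IRanges::width(ra)[qi] &
      ov >= min_frac * IRanges::width(rb)[si]
    passing <- passing + sum(ok)
    if (!any(ok)) next
    us <- pmin(IRanges::start(ra)[qi[ok]], IRanges::start(rb)[si[ok]]) - 1L
    ue <- pmax(IRanges::end(ra)[qi[ok]], IRanges::end(rb)[si[ok]])
    keep[[ch]] <- data.frame(chrom = ch, start = us, end = ue)
  }
  regions <- if (length(keep) == 0) interval_set(merged = TRUE) else {
    df <- do.call(rbind, keep)
    iv_merge(interval_set(df$chrom, df$start, df$end))
  }
  list(regions = regions, tested = tested, passing = passing)
}
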