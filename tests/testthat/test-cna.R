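# CNA classification, genome fraction altered, bin profiles, chromosome
# calls, gene status and clustering.

mkSeg <- function(sample_id, chrom, start, end, log2fc) {
  data.frame(sample_id = sample_id, chrom = chrom, start = start, end = end,
             log2fc = log2fc, stringsAsFactors = FALSE)
}

test_that("segment classification honors thresholds and boundaries", {
  s <- rbind(mkSeg("S1", "A1", 1, 5e6, 0.32),       # boundary gain, focal
             mkSeg("S1", "A2", 1, 1e6, 0.0),        # neutral
             mkSeg("S1", "A3", 1, 15e6, -0.40),     # boundary loss, broad
             mkSeg("S1", "B1", 1, 10e6, 0.5))       # exactly 10 Mb -> focal
  c <- classifySegments(s)
  expect_equal(c$direction, c("gain", "neutral", "loss", "gain"))
  expect_equal(c$scope, c("focal", "focal", "broad", "focal"))
  expect_error(classifySegments(s, gain_threshold = -1), "thresholds")
  # idempotent and threshold-monotone
  c2 <- classifySegments(c[, names(s)])
  expect_equal(c2$direction, c$direction)
  hi <- classifySegments(s, gain_threshold = 0.6)
  expect_true(all(!(c$direction == "neutral" & hi$direction == "gain")))
})

test_that("genome fraction altered is exact arithmetic and grid-consistent", {
  layout <- GenomeLayout(c("A1", "A2"), c(1.2e9, 1.2e9))
  expect_equal(genomeFractionAltered(
    classifySegments(mkSeg("S1", "A1", 1, 1, 0)[0, ]), layout), 0)
  c1 <- classifySegments(mkSeg("S1", "A1", 1, 24e6, 0.5))
  expect_equal(genomeFractionAltered(c1, layout), 1.0)
  # brute force on a 1-kb grid for random segment sets
  set.seed(9)
  lay <- GenomeLayout("A1", 1e6)
  for (i in 1:15) {
    n <- sample(1:6, 1)
    st <- (sample(0:990, n) * 1000) + 1
    en <- pmin(st + sample(1:20, n, replace = TRUE) * 1000 - 1, 1e6)
    s <- classifySegments(mkSeg(rep("S1", n), "A1", st, en,
                                stats::runif(n, -1, 1)))
    got <- genomeFractionAltered(s, lay)
    grid <- seq(500, 1e6, by = 1000)   # 1-kb cell midpoints
    alt <- s[s$direction != "neutral", ]
    covered <- vapply(grid, function(g)
      any(alt$start <= g & alt$end >= g), logical(1))
    expect_equal(got, 100 * mean(covered), tolerance = 1e-6)
  }
})

test_that("GFA is monotone non-decreasing as altered segments are added", {
  lay <- GenomeLayout("A1", 1e8)
  s1 <- classifySegments(mkSeg("S1", "A1", 1, 1e6, 0.5))
  s2 <- rbind(s1, classifySegments(mkSeg("S1", "A1", 5e6, 7e6, -0.8)))
  expect_gte(genomeFractionAltered(s2, lay), genomeFractionAltered(s1, lay))
})

test_that("bin profiles use the length-weighted mean and exact denominators", {
  lay <- GenomeLayout("A1", 5e6)   # 5 bins of 1 Mb
  meta <- mkMeta(c("S1", "S2"), "MAM")
  # S1: gain spanning bins 3-5 entirely
  segs <- classifySegments(mkSeg("S1", "A1", 2e6 + 1, 5e6, 0.5))
  bp <- binProfiles(segs, meta, lay)
  expect_equal(nrow(bp), 5L)
  expect_equal(bp$gain_fraction, c(0, 0, 0.5, 0.5, 0.5))  # 1 of 2 samples
  # weighted mean: half-bin gain 0.5 + half-bin neutral 0 -> 0.25 < 0.32
  segs2 <- classifySegments(rbind(mkSeg("S2", "A1", 1, 5e5, 0.5),
                                  mkSeg("S2", "A1", 5e5 + 1, 1e6, 0.0)))
  bp2 <- binProfiles(segs2, meta, lay)
  expect_equal(bp2$gain_fraction[1], 0)
  # any-overlap mode flags it
  bp3 <- binProfiles(segs2, meta, lay, any_overlap = TRUE)
  expect_equal(bp3$gain_fraction[1], 0.5)
  # empty segments -> all zero
  bp0 <- binProfiles(segs[0, ], meta, lay)
  expect_true(all(bp0$gain_fraction == 0 & bp0$loss_fraction == 0))
  # denominators: fractions are multiples of 1 / n_type
  co <- fixCohort()
  cls <- classifySegments(cnSegments(co))
  bpc <- binProfiles(cls, sampleMeta(co), syntheticLayout())
  for (tt in unique(bpc$tumor_type)) {
    n <- sum(sampleMeta(co)$tumor_type == tt)
    fr <- bpc$gain_fraction[bpc$tumor_type == tt]
    expect_true(all(abs(fr * n - round(fr * n)) < 1e-9))
  }
})

test_that("whole-chromosome calls require the coverage minimum", {
  lay <- GenomeLayout(c("F2", "X"), c(1e8, 1e8))
  cls <- classifySegments(rbind(mkSeg("S1", "F2", 1, 1e8, 0.5),
                                mkSeg("S1", "X", 1, 5e7, 0.5)))
  calls <- chromosomeCalls(cls, lay)
  expect_equal(calls$call[calls$chrom == "F2"], "gain")
  expect_equal(calls$call[calls$chrom == "X"], "none")
})

test_that("planted whole-X losses are recovered at the configured frequency", {
  co <- fullCohort()
  cls <- classifySegments(cnSegments(co))
  calls <- chromosomeCalls(cls, panelLayout(fullPanel()))
  tr <- cohortTruth(co)$cn_events
  planted <- unique(tr$sample_id[grepl("wc_loss_X", tr$label)])
  called <- calls$sample_id[calls$chrom == "X" & calls$call == "loss"]
  # every planted whole-X loss is recovered (coverage 1 > 0.8)
  expect_true(all(planted %in% called))
})

test_that("gene CN status follows the weighted mean over the CDS", {
  p <- fixPanel()
  g <- geneModels(p)
  myc <- g[g$gene == "MYC", ]
  cls <- classifySegments(mkSeg("S1", myc$chrom, myc$cds_start - 10,
                                myc$cds_end + 10, 0.6))
  st <- geneCnStatus(cls, p, sample_ids = "S1")
  expect_equal(st$status[st$gene == "MYC"], "gain")
  expect_equal(st$status[st$gene == "TP53"], "neutral")  # no overlap
})

test_that("average-linkage clustering matches a manual trace and is invariant", {
  # three 1-D profiles with pairwise distances 1, 4, 5
  mkProfile <- function(tt, val) data.frame(
    tumor_type = tt, chrom = "A1", start = 1, end = 1e6,
    gain_fraction = 0, loss_fraction = 0, net = val)
  pr <- rbind(mkProfile("AAA", 0), mkProfile("BBB", 1), mkProfile("CCC", 5))
  hc <- clusterTumorTypes(pr)
  # manual: merge AAA+BBB at 1; then with CCC at mean(5, 4) = 4.5
  expect_equal(hc$height, c(1, 4.5))
  m1 <- sort(hc$labels[abs(hc$merge[1, ])])
  expect_equal(m1, c("AAA", "BBB"))
  # identical profiles merge at height 0
  pr2 <- rbind(mkProfile("AAA", 2), mkProfile("BBB", 2))
  expect_equal(clusterTumorTypes(pr2)$height, 0)
  expect_error(clusterTumorTypes(mkProfile("AAA", 1)), "at least 2")
  # permuting input order leaves the tree unchanged
  hc2 <- clusterTumorTypes(pr[c(3, 1, 2), ])
  expect_equal(hc2$height, hc$height)
  expect_equal(hc2$merge, hc$merge)
})
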