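# Readers/writers, coordinate conventions and the percent convention.

test_that("variant reader maps fields, infers classes and applies aliases", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tchrom\tpos\tref\talt\tconsequence\tgene\tprotein_pos\taa_ref\taa_alt",
    "S1\tchrA1\t100\tC\tT\tmissense\tTP53\t132\tR\tW",
    "S2\tchrA1\t200\tC\tCA\tframeshift\tTP53\t70\t\t",
    "S3\tchrB1\t300\tGAT\tG\tstop_gained\tKIT\t55\tQ\t*",
    "S4\tchrB1\t400\tAC\tGT\tmissense\tKIT\t90\tL\tV"), f)
  v <- readVariants(f)
  expect_equal(v$variant_class, c("SNV", "INS", "DEL", "MNV"))
  expect_equal(v$consequence[3], "nonsense")   # alias applied
  expect_equal(v$protein_pos[1], 132L)
  expect_equal(v$gene[1], "TP53")
})

test_that("variant reader rejects malformed input with named errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tchrom\tref\talt\tconsequence", "S1\tA1\tC\tT\tmissense"), f)
  expect_error(readVariants(f), "pos")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tchrom\tpos\tref\talt\tconsequence",
               "S1\tA1\tx9\tC\tT\tmissense"), f2)
  expect_error(readVariants(f2), "line")
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tchrom\tpos\tref\talt\tconsequence",
               "S1\tA1\t9\tC\tT\tweird_consequence"), f3)
  expect_error(readVariants(f3), "weird_consequence")
})

test_that("variant write/read round-trips all fields", {
  som <- somaticVariants(fixCohort())
  f <- withr::local_tempfile(fileext = ".tsv")
  writeVariants(som, f)
  back <- readVariants(f)
  rownames(som) <- NULL
  expect_equal(back$pos, som$pos)
  expect_equal(back$consequence, som$consequence)
  expect_equal(back$aa_alt, som$aa_alt)
  expect_equal(back[, c("sample_id", "chrom", "ref", "alt", "gene")],
               som[, c("sample_id", "chrom", "ref", "alt", "gene")])
})

test_that("segment reader clips to chromosome bounds and rejects overlaps", {
  layout <- GenomeLayout(c("B4", "X"), c(6e6, 5e6))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tchrom\tstart\tend\tlog2fc",
               "S1\tB4\t1\t5000000\t0.5",
               "S1\tX\t4000000\t9000000\t-0.6"), f)
  segs <- readSegments(f, layout)
  expect_equal(segs$end[segs$chrom == "B4"], 5000000)
  expect_equal(segs$end[segs$chrom == "X"], 5e6)   # clipped
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tchrom\tstart\tend\tlog2fc",
               "S1\tB4\t1\t100\t0.5",
               "S1\tB4\t50\t200\t0.4"), f2)
  expect_error(readSegments(f2, layout), "overlap")
})

test_that("BED conversion is 0-based half-open to 1-based inclusive and back", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrA1\t0\t100\tTP53", "chrA1\t50\t150\tTP53"), f)
  gr <- readPanelBed(f)
  expect_equal(GenomicRanges::start(gr), c(1L, 51L))
  expect_equal(GenomicRanges::end(gr), c(100L, 150L))
  # deduplicated footprint over overlapping regions
  expect_equal(unname(regionFootprint(gr, by_gene = TRUE)["TP53"]), 150)
  expect_equal(regionFootprint(gr), 150)
  # round trip
  f2 <- withr::local_tempfile(fileext = ".bed")
  writePanelBed(gr, f2)
  expect_equal(readLines(f2), readLines(f))
  # empty file
  f3 <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(0), f3)
  expect_equal(regionFootprint(readPanelBed(f3)), 0)
  # invalid row
  f4 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrA1\t100\t100\tTP53", f4)
  expect_error(readPanelBed(f4), "row")
})

test_that("footprint is invariant under region order and splitting", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    st <- sample(1:500, n)
    en <- st + sample(10:100, n, replace = TRUE)
    gr <- GenomicRanges::GRanges("A1", IRanges::IRanges(st, en))
    S4Vectors::mcols(gr)$gene <- "G"
    fp <- regionFootprint(gr)
    expect_equal(regionFootprint(rev(gr)), fp)
    # split the first region into two adjacent halves
    mid <- floor((st[1] + en[1]) / 2)
    gr2 <- c(GenomicRanges::GRanges("A1", IRanges::IRanges(
      c(st[1], mid + 1), c(mid, en[1]))), gr[-1])
    expect_equal(regionFootprint(gr2), fp)
  }
})

test_that("percent convention reproduces the printed cohort percents", {
  expect_equal(roundPercent(19, 493), 4L)
  expect_equal(roundPercent(102, 493), 21L)
  expect_equal(roundPercent(181, 493), 37L)
  expect_equal(roundPercent(67, 493), 14L)
  expect_equal(roundPercent(6, 31), 19L)
  expect_error(roundPercent(1, 0), "positive")
})

test_that("cohort summary counts each facet to the cohort size", {
  meta <- mkMeta(sprintf("S%d", 1:5), c("MAM", "MAM", "CRC", "LYM", "LYM"))
  meta$sex <- c("F", "F", "F", "M", "M")
  meta$age_years <- c(10, 11, 12, 9, 14)
  s <- cohortSummary(meta)
  expect_equal(sum(s$tumor_type$n), 5L)
  expect_equal(s$sex$n[s$sex$level == "F"], 3L)
  expect_equal(s$sex$n[s$sex$level == "M"], 2L)
  expect_equal(s$age$value[s$age$stat == "median"], 11)
  e <- cohortSummary(meta[0, ])
  expect_equal(nrow(e$tumor_type), 0L)
})
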