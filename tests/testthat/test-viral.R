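# k-mer containment screening of off-target reads.

test_that("index construction: counts, canonical form, exclusion subtraction", {
  set.seed(6)
  vseq <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                collapse = "")
  vir <- Biostrings::DNAStringSet(c(V1 = vseq))
  idx <- buildViralIndex(vir, k = 31)
  # L - k + 1 k-mers before dedup; random sequence has few duplicates
  expect_lte(length(idx@sets$V1), 500 - 31 + 1)
  expect_gt(length(idx@sets$V1), 400)
  # reverse-complemented virus gives the identical index
  rc <- Biostrings::DNAStringSet(c(V1 = as.character(
    Biostrings::reverseComplement(vir[[1]]))))
  idx_rc <- buildViralIndex(rc, k = 31)
  expect_setequal(idx@sets$V1, idx_rc@sets$V1)
  # a virus identical to an exclusion sequence loses every k-mer
  idx0 <- buildViralIndex(vir, exclusions = vir, k = 31)
  expect_equal(length(idx0@sets$V1), 0L)
  expect_error(buildViralIndex(vir, k = 30), "odd")
  expect_error(buildViralIndex(vir, k = 13), ">= 15")
})

test_that("reads are assigned by containment with exclusion and thresholds", {
  viruses <- syntheticViralGenomes(3)
  idx <- buildViralIndex(viruses[c("DyoPV", "TauPV")],
                         exclusions = viruses[c("FIV", "FeLV")], k = 31)
  dyo <- as.character(viruses[["DyoPV"]])
  reads <- substring(dyo, seq(1, 2000, by = 200), seq(150, 2150, by = 200))
  res <- screenReads(reads, idx, sample_min_reads = 5)
  expect_equal(res$hits$virus, "DyoPV")
  expect_equal(res$hits$supporting_reads, length(reads))
  expect_equal(res$hits$mean_containment, 1.0)
  # reads from an excluded retrovirus are never assigned
  fiv <- as.character(viruses[["FIV"]])
  fr <- substring(fiv, seq(1, 2000, by = 200), seq(150, 2150, by = 200))
  res2 <- screenReads(fr, idx, sample_min_reads = 1)
  expect_equal(nrow(res2$hits), 0L)
  # reads shorter than k are skipped and counted
  res3 <- screenReads(c("ACGT", reads[1:5]), idx, sample_min_reads = 1)
  expect_equal(res3$n_too_short, 1L)
})

test_that("containment is invariant under reverse-complementing reads", {
  viruses <- syntheticViralGenomes(3)
  idx <- buildViralIndex(viruses["DyoPV"], k = 31)
  rd <- substring(as.character(viruses[["DyoPV"]]), 101, 250)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rd)))
  r1 <- screenReads(rd, idx, sample_min_reads = 1)
  r2 <- screenReads(rc, idx, sample_min_reads = 1)
  expect_equal(r1$hits$mean_containment, r2$hits$mean_containment)
})

test_that("raising thresholds only removes hits, and totals are bounded", {
  co <- fixCohort()
  viruses <- syntheticViralGenomes(fixtureSyntheticConfig(42L)$seed)
  idx <- buildViralIndex(viruses[c("DyoPV", "TauPV")],
                         exclusions = viruses[c("FIV", "FeLV")], k = 31)
  loose <- screenCohortReads(offTargetReads(co), idx,
                             read_min_containment = 0.4, sample_min_reads = 2)
  tight <- screenCohortReads(offTargetReads(co), idx,
                             read_min_containment = 0.7, sample_min_reads = 8)
  expect_lte(nrow(tight), nrow(loose))
  key <- function(x) paste(x$sample_id, x$virus)
  expect_true(all(key(tight) %in% key(loose)))
  nreads <- vapply(offTargetReads(co), length, 1L)
  for (i in seq_len(nrow(loose))) {
    expect_lte(loose$supporting_reads[i], nreads[[loose$sample_id[i]]])
  }
})

test_that("planted viral reads are recovered per sample at 1% error", {
  co <- fixCohort()
  tr <- cohortTruth(co)$viral
  viruses <- syntheticViralGenomes(fixtureSyntheticConfig(42L)$seed)
  idx <- buildViralIndex(viruses[c("DyoPV", "TauPV")],
                         exclusions = viruses[c("FIV", "FeLV")], k = 31)
  hits <- screenCohortReads(offTargetReads(co), idx)
  planted <- tr[tr$virus %in% c("DyoPV", "TauPV"), ]
  if (nrow(planted) > 0) {
    for (i in seq_len(nrow(planted))) {
      h <- hits[hits$sample_id == planted$sample_id[i] &
                  hits$virus == planted$virus[i], ]
      expect_equal(nrow(h), 1L)
      expect_gte(h$supporting_reads, 5L)
    }
  }
  # FeLV plants never surface as hits
  felv <- tr[tr$virus == "FeLV", ]
  if (nrow(felv) > 0)
    expect_false(any(hits$sample_id %in% felv$sample_id &
                       hits$virus %in% c("FIV", "FeLV")))
})
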