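# Generator contracts: determinism, spike recovery, TMB calibration,
# UV spectra, truth tables.

test_that("generation is deterministic for a fixed seed and empty for n = 0", {
  cfg <- fixtureSyntheticConfig(7L)
  p <- fixPanel()
  a <- suppressWarnings(generateCohort(cfg, panel = p))
  b <- suppressWarnings(generateCohort(cfg, panel = p))
  expect_identical(somaticVariants(a), somaticVariants(b))
  expect_identical(cnSegments(a), cnSegments(b))
  expect_identical(offTargetReads(a), offTargetReads(b))
  cfg0 <- cfg
  cfg0$per_type_n[] <- 0L
  e <- generateCohort(cfg0, panel = p)
  expect_equal(nrow(sampleMeta(e)), 0L)
  expect_equal(nrow(somaticVariants(e)), 0L)
})

test_that("spike carrier fraction falls in the exact binomial 99% interval", {
  cfg <- nullConfig(13L, n = 400L, tmb = 2)
  cfg$per_type_n <- c(MAM = 400L)
  cfg$driver_spikes <- data.frame(
    tumor_type = "MAM", gene = "PIK3CA", frequency = 0.5,
    consequence = "missense", hotspot_residue = 1047L, aa_alt = "R")
  co <- suppressWarnings(generateCohort(cfg, panel = fixPanel()))
  tr <- cohortTruth(co)$drivers
  k <- length(unique(tr$sample_id))
  ci <- stats::binom.test(k, 400, 0.5, conf.level = 0.99)$conf.int
  expect_gte(0.5, ci[1])
  expect_lte(0.5, ci[2])
  # spiked change is the planted H1047R
  som <- somaticVariants(co)
  sp <- som[som$gene == "PIK3CA" & som$protein_pos == 1047, ]
  expect_true(all(sp$aa_ref == "H" & sp$aa_alt == "R"))
})

test_that("passenger TMB medians recover configured medians within 25%", {
  p <- fullPanel()
  fp <- panelFootprintMb(p)
  for (tmb in c(2, 20)) {
    cfg <- nullConfig(5L, n = 40L, tmb = tmb)
    co <- generateCohort(cfg, panel = p)
    t <- cohortTmb(somaticVariants(co), sampleMeta(co), fp)
    expect_lt(abs(stats::median(t$tmb) - tmb) / tmb, 0.25)
  }
})

test_that("UV samples' spectra match the UV profile (cosine >= 0.8)", {
  p <- fullPanel()
  cfg <- nullConfig(3L)
  cfg$per_type_n <- c(cSCC = 6L)
  cfg$tmb_log_median["cSCC"] <- 150   # >= 200 mutations per sample
  cfg$uv_fraction <- 1
  co <- generateCohort(cfg, panel = p)
  sp <- buildSpectra(somaticVariants(co), p)
  uv <- uvSignatureProfile()
  for (j in seq_len(ncol(sp))) {
    expect_gte(sum(sp[, j]), 150)
    expect_gte(cosineSim(sp[, j], uv), 0.8)
  }
})

test_that("latent anticorrelation induces a negative burden correlation", {
  co <- fullCohort()
  lat <- cohortTruth(co)$latent
  ct <- stats::cor.test(lat$z_mut, lat$z_cna, method = "spearman",
                        exact = FALSE)
  expect_lt(ct$estimate, -0.6)
  expect_lt(ct$p.value, 0.01)
})

test_that("truth table lists every planted event exactly once", {
  co <- fixCohort()
  tr <- cohortTruth(co)
  tt <- truthTable(co)
  expect_equal(sum(tt$event_type == "driver"),
               nrow(tr$drivers))
  expect_equal(sum(tt$event_type == "cn_event"), nrow(tr$cn_events))
  expect_equal(sum(tt$event_type == "viral"), nrow(tr$viral))
  # no viral plant -> zero viral rows
  cfg <- fixtureSyntheticConfig(3L)
  cfg$viral_plant <- cfg$viral_plant[0, ]
  co2 <- suppressWarnings(generateCohort(cfg, panel = fixPanel()))
  expect_equal(sum(truthTable(co2)$event_type == "viral"), 0L)
})

test_that("spiking an absent gene is a config error", {
  cfg <- fixtureSyntheticConfig(1L)
  cfg$driver_spikes <- data.frame(
    tumor_type = "MAM", gene = "NOT_A_GENE", frequency = 0.5,
    consequence = "missense", hotspot_residue = NA_integer_,
    aa_alt = NA_character_)
  expect_error(generateCohort(cfg, panel = fixPanel()), "NOT_A_GENE")
})

test_that("generated variants satisfy the record invariants", {
  som <- somaticVariants(fixCohort())
  expect_true(all(som$ref != som$alt))
  snv <- som[som$variant_class == "SNV", ]
  expect_true(all(nchar(snv$ref) == 1 & nchar(snv$alt) == 1))
  coding <- som$consequence %in% c("missense", "nonsense", "synonymous",
                                   "start_loss", "nonstop", "inframe_indel",
                                   "frameshift")
  expect_true(all(!is.na(som$protein_pos[coding])))
  expect_true(all(som$consequence %in% consequenceClasses()))
})
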