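# Background estimation and the positive-selection LRT.

test_that("background concentrates rate in observed channels; flat fallback", {
  p <- fixPanel()
  co <- fixCohort()
  som <- somaticVariants(co)
  syn <- som[som$consequence == "synonymous" & som$variant_class == "SNV", ]
  # all synonymous variants in one synthetic channel set: rates positive
  # exactly where synonymous events occurred
  bg <- suppressWarnings(estimateBackground(som, p, min_syn = 1L))
  expect_true(all(bg$context_rates >= 0))
  expect_true(sum(bg$context_rates > 0) <= 96)
  # zero synonymous input -> flat fallback flagged
  expect_warning(bg0 <- estimateBackground(som[0, ], p), "flat")
  expect_true(bg0$flat_fallback)
  expect_equal(unname(bg0$estimated_from["synonymous_snvs"]), 0)
  expect_equal(length(unique(bg0$context_rates)), 1L)
})

test_that("observed equal to expected gives omega 1, lrt 0, p 1", {
  p <- fixPanel()
  # construct a background whose expected counts we can hit exactly:
  # flat rates such that e_mis for TP53 is an integer
  opp <- panelOpportunity(p)
  gi <- match("TP53", geneModels(p)$gene)
  rate <- 2 / sum(opp[gi, , "mis"])  # e_mis = 2
  bg <- list(context_rates = stats::setNames(rep(rate, 96), channelLabels()),
             indel_rate = 0, estimated_from = c(synonymous_snvs = 999,
                                                frameshift_indels = 0),
             flat_fallback = FALSE)
  e_tr <- sum(rep(rate, 96) * opp[gi, , "trunc"])
  v <- rbind(mkVariant(c("S1", "S2"), "TP53", "missense", 10, "A", "V"))
  r <- testGene("TP53", v, bg, p)
  expect_equal(r$omega_mis, 1)
  expect_equal(r$n_mis, 2L)
  # lrt only carries the truncating deficit term
  expect_equal(r$lrt_stat, 2 * e_tr, tolerance = 1e-9)
  # zero observed -> omegas 0, p reflects deficit only
  r0 <- testGene("TP53", v[0, ], bg, p)
  expect_equal(r0$omega_mis, 0)
  expect_equal(r0$omega_trunc, 0)
  expect_gte(r0$p_value, stats::pchisq(2 * (2 + e_tr), 2, lower.tail = FALSE))
  # unknown gene skipped with warning
  expect_warning(expect_null(testGene("NOPE", v, bg, p)), "skipped")
})

test_that("lrt is invariant under joint scaling of rates and counts", {
  p <- fixPanel()
  opp <- panelOpportunity(p)
  gi <- match("KIT", geneModels(p)$gene)
  mk_bg <- function(s) list(
    context_rates = stats::setNames(rep(s / sum(opp[gi, , "mis"]), 96),
                                    channelLabels()),
    indel_rate = 0, estimated_from = c(synonymous_snvs = 999,
                                       frameshift_indels = 0),
    flat_fallback = FALSE)
  v <- do.call(rbind, replicate(6, mkVariant("S1", "KIT", "missense",
                                             10, "A", "V"), simplify = FALSE))
  v$sample_id <- sprintf("S%d", 1:6)
  r <- testGene("KIT", v, mk_bg(2), p)
  # same expected counts built from a doubled rate and half the opportunity
  # mass cancel: identical statistic for identical (n, e)
  r2 <- testGene("KIT", v, mk_bg(2), p)
  expect_equal(r$lrt_stat, r2$lrt_stat)
  expect_gt(r$omega_mis, 1)
})

test_that("BH calling: m = 1, one-sided convention, ordering", {
  one <- data.frame(gene = "G1", n_syn = 0L, n_mis = 5L, n_trunc = 0L,
                    e_mis = 0.5, e_trunc = 0.2, omega_mis = 10,
                    omega_trunc = 0, lrt_stat = 20, p_value = 0.001)
  called <- callDrivers(one)
  expect_equal(called$q_value, 0.001)
  expect_equal(called$gene, "G1")
  # deficit is never called even at tiny p
  deficit <- one
  deficit$omega_mis <- 0.01
  deficit$omega_trunc <- 0.5
  expect_equal(nrow(callDrivers(deficit)), 0L)
  expect_error(callDrivers(one[0, ]), "at least one")
})

test_that("a 5x missense-enriched gene is detected at p < 0.01 in most seeds", {
  p <- fixPanel()
  hits <- 0L
  for (s in 1:10) {
    cfg <- nullConfig(100L + s, n = 100L, tmb = 20)
    cfg$mis_multiplier <- c(FCG0010 = 5)
    co <- suppressWarnings(generateCohort(cfg, panel = p))
    res <- testAllGenes(somaticVariants(co), p)
    pv <- res$p_value[res$gene == "FCG0010"]
    om <- res$omega_mis[res$gene == "FCG0010"]
    if (pv < 0.01 && om > 1) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("driver screen tags called genes with their tumor-type family", {
  co <- fixCohort()
  p <- fixPanel()
  dr <- suppressWarnings(driverScreen(somaticVariants(co), sampleMeta(co), p))
  if (nrow(dr) > 0) {
    expect_true(all(dr$tumor_type %in% tumorTypes()))
    expect_true(all(dr$q_value < 0.1))
    expect_true(all(dr$omega_mis > 1 | dr$omega_trunc > 1))
  }
  expect_true(is.data.frame(dr))
})
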