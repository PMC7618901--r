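# Ortholog alignment, residue maps and humanization.

test_that("identical sequences give the identity map", {
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  m <- alignOrthologs(s, s)
  expect_equal(nrow(m$pairs), nchar(s))
  expect_equal(m$pairs$cat_pos, m$pairs$human_pos)
  expect_equal(m$identity_fraction, 1.0)
  expect_false(m$low_confidence)
})

test_that("an N-terminal extension shifts every mapping by its length", {
  cat_p <- "MKTAYIAKQR"
  hum_p <- paste0("GS", cat_p)      # human has 2 extra N-terminal residues
  m <- alignOrthologs(cat_p, hum_p)
  expect_equal(m$pairs$human_pos, m$pairs$cat_pos + 2L)
  expect_equal(nrow(m$pairs), 10L)
})

test_that("alignment errors and low-identity flags", {
  expect_error(alignOrthologs("", "MKT"), "non-empty")
  set.seed(4)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  s1 <- paste(sample(aa, 60, replace = TRUE), collapse = "")
  s2 <- paste(sample(rev(aa), 60, replace = TRUE), collapse = "")
  m <- alignOrthologs(s1, s2)
  if (m$identity_fraction < 0.5) expect_true(m$low_confidence)
})

test_that("residue maps are strictly monotone on random pairs", {
  set.seed(8)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:15) {
    s1 <- paste(sample(aa, sample(30:80, 1), replace = TRUE), collapse = "")
    # derived sequence: mutate / delete / insert
    x <- strsplit(s1, "")[[1]]
    x[sample(seq_along(x), 5)] <- sample(aa, 5, replace = TRUE)
    x <- x[-sample(seq_along(x), 3)]
    s2 <- paste(x, collapse = "")
    m <- alignOrthologs(s1, s2)
    expect_true(all(diff(m$pairs$cat_pos) > 0))
    expect_true(all(diff(m$pairs$human_pos) > 0))
  }
})

test_that("swapping the species transposes the pair set", {
  s1 <- "MKTAYIAKQRQISFVK"
  s2 <- "MKTAYIGKQRQISF"
  a <- alignOrthologs(s1, s2)
  b <- alignOrthologs(s2, s1)
  expect_equal(a$pairs$cat_pos, b$pairs$human_pos)
  expect_equal(a$pairs$human_pos, b$pairs$cat_pos)
})

test_that("humanize statuses: mapped, ref_mismatch, gap; identity round trip", {
  cat_p <- "MKTAYIAKQR"
  m_id <- alignOrthologs(cat_p, cat_p)
  v <- mkVariant("S1", "G", "missense", 5, "Y", "C")
  h <- humanize(v, m_id)
  expect_equal(h$status, "mapped")
  expect_equal(h$human_change, "Y5C")    # identity on protein changes
  # mismatching human residue
  hum_p <- "MKTAFIAKQR"                  # position 5 Y -> F
  m2 <- alignOrthologs(cat_p, hum_p)
  h2 <- humanize(v, m2)
  expect_equal(h2$status, "ref_mismatch")
  expect_equal(h2$human_change, "")
  h2b <- humanize(v, m2, require_ref_match = FALSE)
  expect_equal(h2b$status, "mapped")
  # residue aligned to a gap
  hum_p3 <- "MKTAIAKQR"                  # position 5 deleted
  m3 <- alignOrthologs(cat_p, hum_p3)
  if (!5 %in% m3$pairs$cat_pos) {
    h3 <- humanize(v, m3)
    expect_equal(h3$status, "gap")
  }
  expect_error(humanize(mkVariant("S1", "G", "frameshift"), m_id),
               "protein_pos")
})

test_that("cohort humanization maps the planted PIK3CA hotspot to H1047R", {
  p <- fullPanel()
  co <- fullCohort()
  som <- somaticVariants(co)
  pik <- som[som$gene == "PIK3CA" & !is.na(som$protein_pos) &
               som$protein_pos == 1047, ]
  expect_gt(nrow(pik), 0)
  hz <- humanizeVariants(pik, p)
  expect_true(all(hz$status == "mapped"))
  expect_true(all(hz$human_change == "H1047R"))
  # genes without ortholog get no_ortholog
  orphans <- geneModels(p)$gene[geneModels(p)$human_ortholog == ""]
  vo <- som[som$gene %in% orphans & !is.na(som$aa_alt) &
              som$variant_class == "SNV", ]
  if (nrow(vo) > 0)
    expect_true(all(humanizeVariants(vo, p)$status == "no_ortholog"))
})

test_that("frequency comparison restricts to shared pairs and subtracts", {
  meta <- mkMeta(sprintf("S%d", 1:20), "MAM")
  v <- do.call(rbind, lapply(sprintf("S%d", 1:10), function(s)
    mkVariant(s, "PIK3CA", "missense", 1047, "H", "R")))
  hf <- data.frame(gene = c("PIK3CA", "ABSENT"), tumor_type = "MAM",
                   fraction = c(0.5, 0.9))
  fc <- frequencyCompare(v, meta, hf)
  expect_equal(nrow(fc), 1L)                  # gene absent from cat dropped
  expect_equal(fc$cat_fraction, 0.5)
  expect_equal(fc$difference, 0.0)
  # hand-built 3-gene table
  v2 <- rbind(v, mkVariant("S1", "TP53", "nonsense", 100, "R", "*"),
              mkVariant(c("S2", "S3"), "KIT", "missense", 560, "V", "D"))
  hf2 <- data.frame(gene = c("PIK3CA", "TP53", "KIT"), tumor_type = "MAM",
                    fraction = c(0.5, 0.3, 0.05))
  fc2 <- frequencyCompare(v2, meta, hf2)
  expect_equal(fc2$cat_fraction[fc2$gene == "TP53"], 0.05)
  expect_equal(fc2$cat_fraction[fc2$gene == "KIT"], 0.10)
  expect_equal(fc2$difference[fc2$gene == "KIT"], 0.05)
})
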