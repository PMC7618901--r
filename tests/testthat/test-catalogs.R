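# Actionability triage and germline predisposition screening.

test_that("germline screen keeps LoF in listed genes only and matches ClinVar-like entries", {
  p <- fullPanel()
  co <- fullCohort()
  germ <- germlineVariants(co)
  cats <- illustrativeCatalogs()
  sc <- screenGermline(germ, predispositionGenes(), p,
                       pathogenic = cats$pathogenic)
  # subset property: every reported row is an input LoF in a listed gene
  expect_true(all(sc$gene %in% predispositionGenes()))
  expect_true(all(sc$lof_class %in% c("nonsense", "frameshift",
                                      "splice_site", "start_loss")))
  key_in <- paste(germ$sample_id, germ$gene, germ$pos)
  expect_true(all(paste(sc$sample_id, sc$gene, sc$pos) %in% key_in))
  # planted CHEK2 Y182* maps to the orthologous pathogenic allele
  chek2 <- sc[sc$gene == "CHEK2" & sc$protein_pos == 182, ]
  expect_gt(nrow(chek2), 0)
  expect_true(all(chek2$pathogenic_match == "orthologous_pathogenic"))
  expect_true(all(chek2$human_change == "Y182*"))
  # missense germline variants in listed genes are excluded
  mis <- germ[germ$consequence == "missense" &
                germ$gene %in% predispositionGenes(), ]
  if (nrow(mis) > 0)
    expect_false(any(paste(mis$sample_id, mis$pos) %in%
                       paste(sc$sample_id, sc$pos)))
  expect_error(screenGermline(germ, character(0), p), "non-empty")
})

test_that("druggability triage reproduces tier logic and percents", {
  meta <- mkMeta(sprintf("S%02d", 1:10), "MAM")
  drg <- data.frame(gene = c("A", "B", "C"),
                    development_level = c("Tclin", "Tbio", "Tchem"))
  v <- rbind(mkVariant("S01", "A", "missense", 1, "M", "V"),
             mkVariant("S02", "B", "missense", 1, "M", "V"),   # Tbio only
             mkVariant("S03", "A", "synonymous", 1, "M", "M")) # not altering
  r <- annotateDruggability(c("A", "B", "C"), v, meta, drg)
  expect_equal(r$per_tumor$tclin_hit,
               c(TRUE, FALSE, FALSE, rep(FALSE, 7)))
  expect_equal(r$summary$gene_percent, roundPercent(1, 3))
  # empty catalog -> nothing flagged
  r0 <- annotateDruggability(c("A", "B"), v, meta, drg[0, ])
  expect_false(any(r0$per_tumor$tclin_hit))
})

test_that("SL triage requires a druggable partner and dedups per tumor", {
  meta <- mkMeta(c("S1", "S2"), "MAM")
  sl <- data.frame(driver_gene = c("A", "B"), partner_gene = c("P1", "P2"),
                   partner_druggable = c(TRUE, FALSE),
                   evidence_id = c("e1", "e2"))
  v <- rbind(mkVariant("S1", "A", "missense", 1, "M", "V"),
             mkVariant("S1", "A", "nonsense", 2, "K", "*"),  # same tumor
             mkVariant("S2", "B", "missense", 1, "M", "V"))  # partner not druggable
  r <- annotateSl(c("A", "B"), v, meta, sl)
  expect_equal(r$per_tumor$sl_hit, c(TRUE, FALSE))
  expect_equal(r$summary$n_hit_tumors, 1L)
})

test_that("actionable triage matches humanized changes and takes the best level", {
  meta <- mkMeta(c("S1", "S2", "S3"), "MAM")
  act <- data.frame(gene = c("PIK3CA", "KIT"),
                    protein_change = c("H1047R", "V560D"),
                    oncogenicity = c("oncogenic", "likely_oncogenic"),
                    level = c(1L, 3L))
  hz <- data.frame(
    sample_id = c("S1", "S1", "S2", "S3"),
    gene = c("PIK3CA", "KIT", "PIK3CA", "PIK3CA"),
    human_gene = c("PIK3CA", "KIT", "PIK3CA", "PIK3CA"),
    cat_change = c("H1047R", "V560D", "H1047L", "H1047R"),
    human_change = c("H1047R", "V560D", "H1047L", ""),
    status = c("mapped", "mapped", "mapped", "ref_mismatch"),
    low_confidence = FALSE)
  r <- annotateActionable(hz, meta, act)
  expect_equal(r$per_tumor$actionable_level, c(1L, NA_integer_, NA_integer_))
  expect_equal(r$summary$n_actionable_tumors, 1L)
  expect_equal(r$summary$level1, 1L)
  # position-only matching rescues H1047L
  r2 <- annotateActionable(hz, meta, act, position_only = TRUE)
  expect_equal(r2$per_tumor$actionable_level[2], 1L)
})

test_that("tumor flags are monotone in the catalogs", {
  meta <- mkMeta(c("S1", "S2"), "MAM")
  v <- rbind(mkVariant("S1", "A", "missense", 1, "M", "V"),
             mkVariant("S2", "B", "missense", 1, "M", "V"))
  drg1 <- data.frame(gene = "A", development_level = "Tclin")
  drg2 <- rbind(drg1, data.frame(gene = "B", development_level = "Tclin"))
  f1 <- annotateDruggability(c("A", "B"), v, meta, drg1)$per_tumor$tclin_hit
  f2 <- annotateDruggability(c("A", "B"), v, meta, drg2)$per_tumor$tclin_hit
  expect_true(all(f2 >= f1))
})

test_that("catalog readers validate their schemas", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeTsvLocal <- function(df, path) utils::write.table(
    df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeTsvLocal(data.frame(gene = c("A", "A"),
                           development_level = c("Tclin", "Tbio")), f)
  expect_error(readDruggability(f), "one row per gene")
  writeTsvLocal(data.frame(gene = "A", development_level = "Tmagic"), f)
  expect_error(readDruggability(f), "development_level")
  writeTsvLocal(data.frame(gene = "A", development_level = "Tclin"), f)
  expect_equal(readDruggability(f)$gene, "A")
})
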