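# End-to-end orchestration: config validation, stage ordering, output
# bundle and manifest. All randomness flows from the single config seed;
# identical config + inputs give byte-identical outputs.

#' Default pipeline configuration
#'
#' @param seed Integer seed.
#' @param output_dir Output directory.
#' @return Config list (see \code{\link{validateConfig}} for the schema).
#' @export
defaultPipelineConfig <- function(seed = 1L, output_dir = "panfelis_out") {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    synthetic = TRUE,
    n_genes = 978L,
    paths = list(),
    stages = list(landscape = TRUE, signatures = TRUE, cna = TRUE,
                  burden = TRUE, drivers = TRUE, cross_species = TRUE,
                  actionability = TRUE, germline = TRUE, viral = TRUE),
    parameters = list(
      gain_threshold = 0.32, loss_threshold = -0.40, focal_max_mb = 10,
      bin_size = 1e6, coverage_min = 0.8,
      hotspot_min_tumors = 2L, hotspot_tolerance = 1L,
      q_max = 0.1, top_k = 5L,
      uv_signature = "SYN_UV", min_fraction = 0.2, min_snvs = 20L,
      viral_k = 31L, read_min_containment = 0.6, sample_min_reads = 5L))
}

#' Validate a pipeline configuration
#'
#' Checks the configuration schema and value ranges; problems are
#' returned as data, not raised.
#'
#' @param config Config list (or path to a YAML file).
#' @return Character vector of problems (empty = valid).
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) return(paste("config file not found:", config))
    config <- yaml::read_yaml(config)
  }
  probs <- character(0)
  add <- function(msg) probs <<- c(probs, msg)
  if (is.null(config$seed) || is.na(suppressWarnings(as.integer(config$seed))))
    add("seed: must be an integer")
  if (is.null(config$output_dir)) add("output_dir: missing")
  p <- config$parameters
  if (!is.null(p$gain_threshold) && p$gain_threshold <= 0)
    add("parameters$gain_threshold: must be > 0")
  if (!is.null(p$loss_threshold) && p$loss_threshold >= 0)
    add("parameters$loss_threshold: must be < 0")
  if (!is.null(p$focal_max_mb) && p$focal_max_mb <= 0)
    add("parameters$focal_max_mb: must be > 0")
  if (!is.null(p$q_max) && (p$q_max <= 0 || p$q_max > 1))
    add("parameters$q_max: must be in (0, 1]")
  if (!is.null(p$viral_k) && (p$viral_k < 15 || p$viral_k %% 2 == 0))
    add("parameters$viral_k: must be odd and >= 15")
  if (!isTRUE(config$synthetic)) {
    need <- c("meta", "variants", "segments", "panel_genes", "panel_cat_fasta",
              "panel_region_fasta")
    for (nm in need) {
      if (is.null(config$paths[[nm]]))
        add(paste0("paths$", nm, ": required when synthetic is FALSE"))
      else if (!file.exists(config$paths[[nm]]))
        add(paste0("paths$", nm, ": file not found: ", config$paths[[nm]]))
    }
  }
  unknown <- setdiff(names(config$stages),
                     c("landscape", "signatures", "cna", "burden", "drivers",
                       "cross_species", "actionability", "germline", "viral"))
  if (length(unknown) > 0)
    add(paste("stages: unknown stage(s):", paste(unknown, collapse = ", ")))
  if (isTRUE(config$stages$actionability) && !isTRUE(config$stages$drivers))
    add("stages$actionability: requires stages$drivers (driver list is its input)")
  if (isTRUE(config$stages$burden) && !isTRUE(config$stages$signatures))
    add("stages$burden: requires stages$signatures (hypermutator flags)")
  if (isTRUE(config$stages$burden) && !isTRUE(config$stages$landscape))
    add("stages$burden: requires stages$landscape (hotspot calls)")
  if (isTRUE(config$stages$burden) && !isTRUE(config$stages$cna))
    add("stages$burden: requires stages$cna (classified segments)")
  probs
}

#' Illustrative actionability and pathogenicity catalogs
#'
#' Small clearly-synthetic catalogs over the marquee panel genes, shaped
#' like the real druggability / synthetic-lethality / actionable-variant /
#' pathogenic-variant databases. For real analyses supply licensed
#' catalogs via the reader functions.
#'
#' @return List: druggability, sl, actionable, pathogenic data.frames.
#' @export
illustrativeCatalogs <- function() {
  druggability <- data.frame(
    gene = c("KIT", "PIK3CA", "MAP2K1", "FGFR2", "CTNNB1", "MYC",
             "TP53", "FBXW7", "PTEN", "APC", "MSH2", "TRAF3", "CHEK2", "NF1"),
    development_level = c("Tclin", "Tclin", "Tclin", "Tclin", "Tchem", "Tbio",
                          "Tchem", "Tbio", "Tchem", "Tbio", "Tbio", "Tdark",
                          "Tchem", "Tbio"),
    stringsAsFactors = FALSE)
  sl <- data.frame(
    driver_gene = c("TP53", "PIK3CA", "APC", "PTEN", "MSH2", "FBXW7"),
    partner_gene = c("CHK1i_target", "PIK3CB", "CTNNB1", "ATR", "WRN", "AURKA"),
    partner_druggable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    evidence_id = paste0("SL", 1:6), stringsAsFactors = FALSE)
  actionable <- data.frame(
    gene = c("PIK3CA", "PIK3CA", "KIT", "MAP2K1", "FGFR2", "FBXW7",
             "PTEN", "NF1"),
    protein_change = c("H1047R", "E545K", "V560D", "Q57E", "S252W", "R465H",
                       "R130Q", "R440*"),
    oncogenicity = c("oncogenic", "oncogenic", "oncogenic", "likely_oncogenic",
                     "oncogenic", "likely_oncogenic", "likely_oncogenic",
                     "likely_oncogenic"),
    level = c(1L, 1L, 2L, 3L, 2L, 4L, 3L, 4L),
    stringsAsFactors = FALSE)
  pathogenic <- data.frame(
    gene = c("CHEK2", "BRIP1", "BRCA1", "BRCA2"),
    protein_change = c("Y182*", "R798*", "Q1756*", "K3326*"),
    stringsAsFactors = FALSE)
  list(druggability = druggability, sl = sl, actionable = actionable,
       pathogenic = pathogenic)
}

#' Run the whole pipeline
#'
#' Runs every enabled stage in dependency order (spectra and hypermutator
#' flags before burden; hotspots before burden; drivers before
#' actionability), writes all stage TSVs plus a JSON manifest with
#' package version, parameters and output checksums to
#' \code{config$output_dir}, and returns the stage results invisibly. A
#' stage failure still writes the manifest, marking the failure point,
#' before propagating the error.
#'
#' @param config Config list from \code{\link{defaultPipelineConfig}} (or
#'   path to a YAML file with the same schema).
#' @param cohort Optional pre-built \linkS4class{CancerCohort} (overrides
#'   synthetic generation / path loading).
#' @param panel Optional \linkS4class{GenePanel}.
#' @return Invisible list of stage results.
#' @export
runPipeline <- function(config, cohort = NULL, panel = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  probs <- validateConfig(config)
  if (length(probs) > 0)
    stop("invalid config:\n  ", paste(probs, collapse = "\n  "))
  p <- config$parameters
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(config$output_dir, name)
  written <- character(0)
  emit <- function(df, name) {
    writeTsv(df, outfile(name))
    written <<- c(written, name)
  }
  res <- list()
  stageDone <- character(0)
  current <- "load"
  on.exit({
    manifest <- list(
      package = "panfelis",
      version = as.character(utils::packageVersion("panfelis")),
      seed = config$seed,
      parameters = p,
      stages_completed = stageDone,
      files = as.list(tools::md5sum(file.path(config$output_dir, written))))
    if (current != "done") manifest$failed_at <- current
    names(manifest$files) <- written
    jsonlite::write_json(manifest, outfile("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })

  catalogs <- illustrativeCatalogs()
  for (nm in c("druggability", "sl", "actionable", "pathogenic")) {
    pth <- config$paths[[paste0("catalog_", nm)]]
    if (!is.null(pth))
      catalogs[[nm]] <- switch(nm,
                               druggability = readDruggability(pth),
                               sl = readSlCatalog(pth),
                               actionable = readActionableCatalog(pth),
                               pathogenic = readPathogenicCatalog(pth))
  }

  if (is.null(cohort)) {
    if (isTRUE(config$synthetic)) {
      if (is.null(panel))
        panel <- syntheticGenePanel(n_genes = config$n_genes %||% 978L,
                                    seed = config$seed)
      cohort <- generateCohort(defaultSyntheticConfig(seed = config$seed),
                               panel = panel)
    } else {
      layout <- syntheticLayout()
      panel <- readGenePanel(config$paths$panel_genes,
                             config$paths$panel_cat_fasta,
                             config$paths$panel_region_fasta, layout,
                             human_fasta_path = config$paths$panel_human_fasta)
      meta <- readTsv(config$paths$meta)
      som <- readVariants(config$paths$variants)
      germ <- if (!is.null(config$paths$germline))
        readVariants(config$paths$germline, compartment = "germline")
      else som[0, ]
      segs <- readSegments(config$paths$segments, layout)
      cohort <- new("CancerCohort", meta = meta, somatic = som,
                    germline = germ, segments = segs, reads = list(),
                    truth = list())
    }
  } else if (is.null(panel)) {
    panel <- syntheticGenePanel(n_genes = config$n_genes %||% 978L,
                                seed = config$seed)
  }
  layout <- panelLayout(panel)
  meta <- sampleMeta(cohort)
  som <- somaticVariants(cohort)
  fpMb <- panelFootprintMb(panel)

  emit(meta, "meta.tsv")
  emit(som, "somatic_variants.tsv")
  emit(germlineVariants(cohort), "germline_variants.tsv")
  emit(cnSegments(cohort), "segments.tsv")

  st <- function(nm) isTRUE(config$stages[[nm]])

  if (st("landscape")) {
    current <- "landscape"
    res$tmb <- cohortTmb(som, meta, fpMb)
    emit(res$tmb, "tmb.tsv")
    res$ranking <- rankGenes(som, meta, top_k = p$top_k)
    emit(res$ranking, "gene_ranking.tsv")
    topGenes <- unique(res$ranking$gene)
    if (length(topGenes) > 0) {
      om <- oncoplotMatrix(som, meta, topGenes)
      emit(data.frame(sample_id = rownames(om), om, check.names = FALSE),
           "oncoplot.tsv")
    }
    res$hotspots <- detectHotspots(som, min_tumors = p$hotspot_min_tumors,
                                   tolerance = p$hotspot_tolerance)
    emit(res$hotspots, "hotspots.tsv")
    stageDone <- c(stageDone, "landscape")
  }

  if (st("signatures")) {
    current <- "signatures"
    catalog <- syntheticSignatureCatalog()
    spectra <- buildSpectra(som, panel, sample_ids = meta$sample_id)
    res$exposures <- flagHypermutators(
      refitExposures(spectra, catalog), p$uv_signature,
      min_fraction = p$min_fraction, min_snvs = p$min_snvs)
    emit(res$exposures, "signature_exposures.tsv")
    stageDone <- c(stageDone, "signatures")
  }

  if (st("cna")) {
    current <- "cna"
    res$classified <- classifySegments(cnSegments(cohort),
                                       gain_threshold = p$gain_threshold,
                                       loss_threshold = p$loss_threshold,
                                       focal_max_mb = p$focal_max_mb)
    emit(res$classified, "classified_segments.tsv")
    res$gfa <- cohortGfa(res$classified, meta, layout)
    emit(res$gfa, "genome_fraction_altered.tsv")
    res$profiles <- binProfiles(res$classified, meta, layout,
                                bin_size = p$bin_size,
                                gain_threshold = p$gain_threshold,
                                loss_threshold = p$loss_threshold)
    emit(res$profiles, "bin_profiles.tsv")
    res$chromCalls <- chromosomeCalls(res$classified, layout,
                                      coverage_min = p$coverage_min)
    emit(res$chromCalls, "chromosome_calls.tsv")
    res$geneCn <- geneCnStatus(res$classified, panel,
                               sample_ids = meta$sample_id,
                               gain_threshold = p$gain_threshold,
                               loss_threshold = p$loss_threshold)
    emit(res$geneCn, "gene_cn_status.tsv")
    if (length(unique(meta$tumor_type)) >= 2) {
      hc <- clusterTumorTypes(res$profiles)
      writeDendrogram(hc, outfile("tumor_type_dendrogram.nwk"))
      written <- c(written, "tumor_type_dendrogram.nwk")
      res$dendrogram <- hc
    }
    stageDone <- c(stageDone, "cna")
  }

  if (st("burden")) {
    current <- "burden"
    res$burden <- burdenPoints(res$classified, som, meta,
                               hypermutators = res$exposures,
                               hotspots = res$hotspots)
    emit(res$burden, "burden_points.tsv")
    res$density <- densityBins(res$burden)
    emit(res$density, "burden_density.tsv")
    stageDone <- c(stageDone, "burden")
  }

  if (st("drivers")) {
    current <- "drivers"
    res$drivers <- driverScreen(som, meta, panel, q_max = p$q_max)
    emit(res$drivers, "drivers.tsv")
    stageDone <- c(stageDone, "drivers")
  }

  if (st("cross_species") || st("actionability")) {
    current <- "cross_species"
    driverGenes <- unique(res$drivers$gene)
    res$humanized <- humanizeVariants(
      som[som$variant_class == "SNV", , drop = FALSE], panel)
    emit(res$humanized, "humanized_mutations.tsv")
    stageDone <- c(stageDone, "cross_species")
  }

  if (st("actionability")) {
    current <- "actionability"
    driverGenes <- unique(res$drivers$gene)
    if (length(driverGenes) == 0) {
      warning("no driver genes called; actionability triage is empty")
      res$triage <- data.frame(sample_id = meta$sample_id,
                               tclin_hit = FALSE, sl_hit = FALSE,
                               actionable_level = NA_integer_)
    } else {
      drg <- annotateDruggability(driverGenes, som, meta,
                                  catalogs$druggability)
      slr <- annotateSl(driverGenes, som, meta, catalogs$sl)
      hz <- res$humanized[res$humanized$gene %in% driverGenes, , drop = FALSE]
      act <- annotateActionable(hz, meta, catalogs$actionable)
      res$triage <- data.frame(
        sample_id = meta$sample_id,
        tclin_hit = drg$per_tumor$tclin_hit,
        sl_hit = slr$per_tumor$sl_hit,
        actionable_level = act$per_tumor$actionable_level)
      res$triage_summary <- list(druggability = drg$summary,
                                 sl = slr$summary, actionable = act$summary)
    }
    emit(res$triage, "actionability_triage.tsv")
    stageDone <- c(stageDone, "actionability")
  }

  if (st("germline")) {
    current <- "germline"
    res$germlineScreen <- screenGermline(germlineVariants(cohort),
                                         predispositionGenes(), panel,
                                         pathogenic = catalogs$pathogenic)
    emit(res$germlineScreen, "germline_screen.tsv")
    stageDone <- c(stageDone, "germline")
  }

  if (st("viral")) {
    current <- "viral"
    viruses <- syntheticViralGenomes(seed = config$seed)
    idx <- buildViralIndex(viruses[c("DyoPV", "TauPV")],
                           exclusions = viruses[c("FIV", "FeLV")],
                           k = p$viral_k)
    res$viralHits <- screenCohortReads(
      offTargetReads(cohort), idx,
      read_min_containment = p$read_min_containment,
      sample_min_reads = p$sample_min_reads)
    emit(res$viralHits, "viral_hits.tsv")
    stageDone <- c(stageDone, "viral")
  }

  current <- "done"
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the committed-size fixture cohort
#'
#' Emits a tiny synthetic cohort (5 tumor types, ~40 samples, 60-gene
#' panel) in the external formats (meta/variants/segments TSV, panel BED,
#' gene table, protein and region FASTA), suitable as a checked-in test
#' fixture or a quick demo input.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Invisible list with the cohort and panel objects.
#' @export
writeFixtureCohort <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- fixtureSyntheticConfig(seed)
  panel <- syntheticGenePanel(n_genes = 60L, seed = seed, mean_protL = 450L)
  cohort <- generateCohort(cfg, panel = panel)
  writeTsv(sampleMeta(cohort), file.path(dir, "meta.tsv"))
  writeVariants(somaticVariants(cohort), file.path(dir, "somatic.tsv"))
  writeVariants(germlineVariants(cohort), file.path(dir, "germline.tsv"))
  writeSegments(cnSegments(cohort), file.path(dir, "segments.tsv"))
  writePanelBed(panelRegions(panel), file.path(dir, "panel.bed"))
  writeTsv(geneModels(panel), file.path(dir, "gene_models.tsv"))
  Biostrings::writeXStringSet(catProteins(panel),
                              file.path(dir, "cat_proteins.fa"))
  Biostrings::writeXStringSet(humanProteins(panel),
                              file.path(dir, "human_proteins.fa"))
  Biostrings::writeXStringSet(panel@regionSeqs,
                              file.path(dir, "region_seqs.fa"))
  writeTsv(truthTable(cohort), file.path(dir, "truth.tsv"))
  invisible(list(cohort = cohort, panel = panel))
}

#' Scaled-down synthetic configuration for fixtures and fast tests
#'
#' Same structure as \code{\link{defaultSyntheticConfig}} with a ~40-sample
#' cohort over 5 tumor types.
#'
#' @param seed Integer seed.
#' @return A \code{panfelis_config}.
#' @export
fixtureSyntheticConfig <- function(seed = 1L) {
  cfg <- defaultSyntheticConfig(seed)
  cfg$per_type_n <- c(cSCC = 10L, MAM = 10L, CRC = 6L, cMCT = 6L, LYM = 8L)
  cfg$viral_background_reads <- 20L
  cfg
}
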