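# Synthetic cohort generator: emulates the statistical structure of a
# 13-tumor-type feline tumor-normal cohort (per-type TMB, UV spectrum in a
# skin type, driver/hotspot spike-ins, type-specific copy-number templates,
# an inverse mutation/CNA relationship, germline LoF variants, planted
# viral reads) so every downstream stage can be tested against known truth.

#' Default synthetic cohort configuration
#'
#' Returns the full configuration of the synthetic cohort generator with
#' defaults emulating a 493-sample, 13-tumor-type feline pan-cancer study:
#' per-type sample counts (BCC 40, CCA 30, CRC 34, cMCT 41, cSCC 62, GLIO
#' 7, LUCA 57, LYM 51, MAM 47, MEN 28, OSA 25, oSCC 42, PANC 29), per-type
#' TMB medians spanning ~0.5-20 mutations/Mb with the skin types highest,
#' a UV-like spectrum in ~55% of cSCC, driver spike-ins loosely modeled on
#' the marquee genes (TP53 widespread, KIT in cMCT, PIK3CA/FBXW7 in MAM,
#' a PIK3CA codon-1047 hotspot), type-specific copy-number templates
#' (whole-chromosome F1/F2 gains and X losses, focal MYC gain and PTEN/FAS
#' and CDKN2A losses, heavy broad events in MAM, almost none in CRC), a
#' negative latent correlation between mutation and CNA propensity,
#' low-prevalence germline LoF variants in 14 predisposition genes (with a
#' planted CHEK2 codon-182 stop), and papillomavirus-like reads planted in
#' the skin types with FIV/FeLV-like reads planted as exclusion controls.
#' These defaults are illustrative of the published cohort structure, not
#' ground truth.
#'
#' @param seed Integer root seed; all randomness of the generator flows
#'   from it.
#' @return A list of class \code{panfelis_config}.
#' @export
defaultSyntheticConfig <- function(seed = 1L) {
  types <- tumorTypes()
  per_type_n <- stats::setNames(
    c(40L, 30L, 34L, 41L, 62L, 7L, 57L, 51L, 47L, 28L, 25L, 42L, 29L), types)
  tmb <- stats::setNames(
    c(2, 1, 1.5, 0.5, 20, 0.8, 2.5, 1.2, 2, 0.6, 1.5, 4, 1), types)

  spikes <- rbind(
    data.frame(tumor_type = types, gene = "TP53",
               frequency = stats::setNames(
                 c(0.20, 0.30, 0.30, 0.10, 0.50, 0.30, 0.30, 0.15, 0.40,
                   0.10, 0.50, 0.50, 0.30), types)[types],
               consequence = "missense", hotspot_residue = NA_integer_,
               aa_alt = NA_character_),
    data.frame(tumor_type = "cMCT", gene = "KIT", frequency = 0.40,
               consequence = "missense", hotspot_residue = 560L,
               aa_alt = NA_character_),
    data.frame(tumor_type = "MAM", gene = "FBXW7", frequency = 0.60,
               consequence = "missense", hotspot_residue = 465L,
               aa_alt = NA_character_),
    data.frame(tumor_type = c("MAM", "BCC", "LUCA", "CRC"), gene = "PIK3CA",
               frequency = c(0.30, 0.02, 0.03, 0.06),
               consequence = "missense", hotspot_residue = 1047L,
               aa_alt = "R"),
    data.frame(tumor_type = c("CRC", "PANC"), gene = "CTNNB1",
               frequency = c(0.15, 0.25), consequence = "missense",
               hotspot_residue = 33L, aa_alt = NA_character_),
    data.frame(tumor_type = c("LYM", "MEN"), gene = "TRAF3",
               frequency = c(0.20, 0.15), consequence = "nonsense",
               hotspot_residue = NA_integer_, aa_alt = NA_character_),
    data.frame(tumor_type = c("GLIO", "MAM"), gene = "PTEN",
               frequency = c(0.25, 0.10), consequence = "frameshift",
               hotspot_residue = NA_integer_, aa_alt = NA_character_),
    data.frame(tumor_type = "CRC", gene = "APC", frequency = 0.25,
               consequence = "nonsense", hotspot_residue = NA_integer_,
               aa_alt = NA_character_))
  rownames(spikes) <- NULL

  cn <- defaultCnTemplates()

  viral <- data.frame(
    tumor_type = c("cSCC", "cSCC", "BCC", "BCC", "oSCC", "LYM"),
    virus = c("DyoPV", "TauPV", "DyoPV", "TauPV", "TauPV", "FeLV"),
    reads_per_sample = c(20L, 20L, 20L, 20L, 20L, 20L),
    positive_fraction = c(0.25, 0.15, 0.20, 0.15, 0.025, 0.10))

  structure(list(
    seed = as.integer(seed),
    per_type_n = per_type_n,
    tmb_log_median = tmb,
    tmb_log_sd = 0.7,
    uv_type = "cSCC",
    uv_fraction = 0.55,
    driver_spikes = spikes,
    mis_multiplier = stats::setNames(numeric(0), character(0)),
    cn_templates = cn,
    cna_noise_rate = stats::setNames(
      c(2, 2, 1.8, 2, 2, 2, 2, 3, 4, 2, 3, 2, 2), types),
    cna_scale = 1.0,
    anticorrelation = -0.8,
    germline_prevalence = 0.04,
    germline_chek2_weight = 0.20,
    germline_noise_per_sample = 2,
    viral_plant = viral,
    viral_background_reads = 50L,
    viral_read_length = 150L,
    viral_error_rate = 0.01,
    indel_fraction = 0.10,
    indel_fs_prob = 2 / 3
  ), class = "panfelis_config")
}

#' Default copy-number event templates
#'
#' Broad/whole-chromosome and focal event templates per tumor type; the
#' MAM template set is sized so its expected genome fraction altered is
#' ~17%, while CRC carries almost no events.
#'
#' @return data.frame (tumor_type, chrom, start, end, log2fc, frequency,
#'   label).
#' @export
defaultCnTemplates <- function() {
  types <- tumorTypes()
  f1f2types <- setdiff(types, c("CRC", "GLIO"))     # eleven tumor types
  xlosstypes <- c("MAM", "LYM", "cSCC", "oSCC", "OSA",
                  "LUCA", "BCC", "MEN", "PANC")     # nine tumor types
  wc <- function(tt, chrom, fc, freq, label) {
    data.frame(tumor_type = tt, chrom = chrom, start = 1,
               end = unname(chromLengths(syntheticLayout())[chrom]),
               log2fc = fc, frequency = freq, label = label)
  }
  rbind(
    wc(f1f2types, "F1", 0.45, 0.12, "wc_gain_F1"),
    wc(f1f2types, "F2", 0.45, 0.12, "wc_gain_F2"),
    wc(xlosstypes, "X", -0.55, 0.12, "wc_loss_X"),
    wc(setdiff(types, c("CRC", "GLIO", "MEN")), "A3", 0.40, 0.08, "broad_gain_A3"),
    wc(setdiff(types, c("CRC", "GLIO", "MEN")), "B4", 0.40, 0.08, "broad_gain_B4"),
    # MAM-heavy broad landscape, frequencies sized so the expected genome
    # fraction altered (including the shared templates above, overlap on a
    # chromosome merged, and the latent-propensity inflation) is ~17%
    wc("MAM", "F1", 0.50, 0.31, "wc_gain_F1_mam"),
    wc("MAM", "F2", 0.50, 0.31, "wc_gain_F2_mam"),
    wc("MAM", "A3", 0.45, 0.21, "broad_gain_A3_mam"),
    wc("MAM", "B4", 0.45, 0.21, "broad_gain_B4_mam"),
    wc("MAM", "X", -0.55, 0.18, "wc_loss_X_mam"),
    wc("MAM", "B1", -0.50, 0.23, "broad_loss_B1_mam"),
    wc("MAM", "C1", 0.45, 0.23, "broad_gain_C1_mam"),
    wc("MAM", "D1", -0.50, 0.23, "broad_loss_D1_mam"),
    wc("MAM", "A2", 0.45, 0.12, "broad_gain_A2_mam"),
    # focal recurrent events; frequencies account for the overlap with the
    # whole-chromosome templates (a sample counts once per gene) and the
    # latent-propensity inflation, targeting ~20% MYC gain (LYM-enriched),
    # ~20% PTEN/FAS loss and ~15% CDKN2A loss cohort-wide
    data.frame(tumor_type = types, chrom = "F2", start = 81.5e6, end = 84.5e6,
               log2fc = 0.60,
               frequency = ifelse(types == "LYM", 0.30, 0.02),
               label = "focal_gain_MYC"),
    data.frame(tumor_type = setdiff(types, "CRC"), chrom = "D2",
               start = 1e6, end = 6e6, log2fc = -0.60, frequency = 0.15,
               label = "focal_loss_PTEN_FAS"),
    data.frame(tumor_type = types, chrom = "D4", start = 9.5e6, end = 10.5e6,
               log2fc = -0.70, frequency = 0.11, label = "focal_loss_CDKN2A"))
}

#' Synthetic viral reference genomes
#'
#' Four random viral genomes: two papillomavirus-like targets (DyoPV,
#' TauPV, ~7.5 kb) and two retrovirus-like exclusion references (FIV ~9.2
#' kb, FeLV ~8.4 kb). Clearly synthetic stand-ins for the real reference
#' genomes, sufficient for k-mer containment screening.
#'
#' @param seed Integer seed.
#' @return A \code{DNAStringSet} named DyoPV, TauPV, FIV, FeLV.
#' @export
syntheticViralGenomes <- function(seed = 1L) {
  set.seed(substreamSeed(seed, "viruses"))
  lens <- c(DyoPV = 7400L, TauPV = 7600L, FIV = 9200L, FeLV = 8400L)
  seqs <- vapply(lens, function(L)
    paste(sample(.BASES, L, replace = TRUE), collapse = ""), character(1))
  Biostrings::DNAStringSet(seqs)
}

## ---- internal helpers -----------------------------------------------------

# Classify SNV hits (site-table row + coding-strand alt) into consequence,
# protein position and amino-acid change; fully vectorized.
classifySiteHits <- function(panel, sites, row, alt) {
  g <- panel@genes
  n <- length(row)
  gi <- sites$geneIdx[row]
  cpos <- sites$cpos[row]
  base <- sites$base[row]
  coding <- cpos > 0L
  consequence <- rep("noncoding", n)
  protein_pos <- rep(NA_integer_, n)
  aa_ref <- aa_alt <- rep(NA_character_, n)
  if (any(coding)) {
    i <- which(coding)
    pic <- (cpos[i] - 1L) %% 3L
    csr <- row[i] - pic
    b1 <- sites$base[csr]; b2 <- sites$base[csr + 1L]; b3 <- sites$base[csr + 2L]
    refCod <- (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3
    mult <- c(16L, 4L, 1L)[pic + 1L]
    mutCod <- refCod + (alt[i] - base[i]) * mult
    aR <- .AA_BY_CODON[refCod]
    aM <- .AA_BY_CODON[mutCod]
    codIdx <- (cpos[i] - 1L) %/% 3L + 1L
    protL <- g$protein_length[gi[i]]
    cls <- ifelse(aM == aR, "synonymous",
                  ifelse(aM == "*", "nonsense", "missense"))
    cls[codIdx == 1L & aM != aR] <- "start_loss"
    isStop <- codIdx == protL + 1L
    cls[isStop & aM != "*"] <- "nonstop"
    cls[isStop & aM == "*"] <- "synonymous"
    consequence[i] <- cls
    protein_pos[i] <- codIdx
    aa_ref[i] <- aR
    aa_alt[i] <- aM
  }
  plus <- g$strand[gi] == "+"
  data.frame(
    chrom = sites$chrom[row],
    pos = sites$gpos[row],
    ref = ifelse(plus, .BASES[base], .BASES[5L - base]),
    alt = ifelse(plus, .BASES[alt], .BASES[5L - alt]),
    variant_class = "SNV",
    gene = g$gene[gi],
    consequence = consequence,
    protein_pos = protein_pos,
    aa_ref = aa_ref,
    aa_alt = aa_alt,
    stringsAsFactors = FALSE)
}

# Cached per-gene site-class table.
geneSiteClassesCached <- function(panel, gene) {
  cache <- panelCache(panel)
  if (is.null(cache$siteClasses)) cache$siteClasses <- list()
  if (is.null(cache$siteClasses[[gene]]))
    cache$siteClasses[[gene]] <- geneSiteClasses(panel, gene)
  cache$siteClasses[[gene]]
}

# Build a variant row from a chosen (site-class row, gene) pair.
.spikeVariantRow <- function(panel, gene, scRow) {
  g <- panel@genes[match(gene, panel@genes$gene), ]
  data.frame(chrom = g$chrom, pos = scRow$gpos, ref = scRow$gref,
             alt = scRow$galt, variant_class = "SNV", gene = gene,
             consequence = scRow$consequence,
             protein_pos = scRow$codon, aa_ref = scRow$aa_ref,
             aa_alt = scRow$aa_alt, stringsAsFactors = FALSE)
}

# Mutate viral read bases at a uniform error rate.
.addReadErrors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  vapply(reads, function(r) {
    b <- strsplit(r, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(b)) < rate)
    if (length(hit) > 0)
      b[hit] <- vapply(b[hit], function(x)
        sample(setdiff(.BASES, x), 1), character(1))
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## ---- generator ------------------------------------------------------------

#' Generate a synthetic cohort
#'
#' Draws a full cohort under the configured study conditions: sample
#' metadata; latent per-sample mutation and CNA propensities with the
#' configured (negative) correlation; passenger SNVs and indels over the
#' panel (Poisson counts at lognormal per-type TMB, flat spectrum, or the
#' UV-like spectrum for the designated fraction of the skin-like type);
#' configured driver/hotspot spike-ins; copy-number segments from the
#' event templates plus focal noise; germline LoF variants in the
#' predisposition genes; and off-target reads with planted viral
#' sequences. A fixed seed produces byte-identical output.
#'
#' @param cfg Configuration from \code{\link{defaultSyntheticConfig}}
#'   (possibly modified).
#' @param panel A \linkS4class{GenePanel} (default: the synthetic panel
#'   built from the same seed).
#' @param viruses \code{DNAStringSet} of viral genomes (default synthetic).
#' @return A \linkS4class{CancerCohort} with ground-truth tables in
#'   \code{cohortTruth()}.
#' @export
generateCohort <- function(cfg, panel = NULL, viruses = NULL) {
  stopifnot(inherits(cfg, "panfelis_config"))
  if (is.null(panel)) panel <- syntheticGenePanel(seed = cfg$seed)
  if (is.null(viruses)) viruses <- syntheticViralGenomes(seed = cfg$seed)
  bad <- setdiff(cfg$driver_spikes$gene, panel@genes$gene)
  if (length(bad) > 0)
    stop("spike gene(s) absent from gene models: ", paste(unique(bad), collapse = ", "))
  if (cfg$uv_fraction > 0 && !(cfg$uv_type %in% names(cfg$per_type_n)))
    stop("uv_type must be present in per_type_n when uv_fraction > 0")

  types <- names(cfg$per_type_n)
  n <- sum(cfg$per_type_n)
  meta <- if (n == 0) {
    data.frame(sample_id = character(0), tumor_type = character(0),
               subtype = character(0), age_years = numeric(0),
               sex = character(0), breed = character(0))
  } else {
    data.frame(sample_id = sprintf("S%04d", seq_len(n)),
               tumor_type = rep(types, cfg$per_type_n),
               subtype = "", age_years = NA_real_, sex = "U", breed = "",
               stringsAsFactors = FALSE)
  }

  emptyVar <- data.frame(sample_id = character(0), chrom = character(0),
                         pos = numeric(0), ref = character(0),
                         alt = character(0), variant_class = character(0),
                         gene = character(0), consequence = character(0),
                         protein_pos = integer(0), aa_ref = character(0),
                         aa_alt = character(0), compartment = character(0))
  emptySeg <- data.frame(sample_id = character(0), chrom = character(0),
                         start = numeric(0), end = numeric(0),
                         log2fc = numeric(0))
  if (n == 0) {
    return(new("CancerCohort", meta = meta, somatic = emptyVar,
               germline = emptyVar, segments = emptySeg, reads = list(),
               truth = list(drivers = data.frame(), cn_events = data.frame(),
                            germline = data.frame(), viral = data.frame())))
  }

  set.seed(substreamSeed(cfg$seed, "meta"))
  meta$age_years <- round(pmin(21, pmax(0.7, stats::rnorm(n, 11, 3.7))), 1)
  meta$sex <- ifelse(meta$tumor_type == "MAM", "F",
                     sample(c("F", "M", "U"), n, replace = TRUE,
                            prob = c(0.53, 0.44, 0.03)))
  meta$breed <- sample(c("DSH", "DLH", "Siamese", "MaineCoon", "Other"),
                       n, replace = TRUE,
                       prob = c(0.731, 0.104, 0.022, 0.018, 0.125))
  meta$subtype[meta$tumor_type == "LYM"] <-
    sample(c("T-cell", "B-cell"), sum(meta$tumor_type == "LYM"), replace = TRUE)
  meta$subtype[meta$tumor_type == "MAM"] <-
    sample(c("ER+", "ER-"), sum(meta$tumor_type == "MAM"), replace = TRUE)
  meta$subtype[meta$tumor_type == "OSA"] <-
    sample(c("appendicular", "axial"), sum(meta$tumor_type == "OSA"),
           replace = TRUE)

  # latent propensities with the configured anticorrelation
  rho <- cfg$anticorrelation
  z_mut <- stats::rnorm(n)
  z_cna <- rho * z_mut + sqrt(1 - rho^2) * stats::rnorm(n)
  tmb_i <- cfg$tmb_log_median[meta$tumor_type] * exp(cfg$tmb_log_sd * z_mut)
  uv_sample <- meta$tumor_type == cfg$uv_type &
    stats::runif(n) < cfg$uv_fraction

  sites <- panelSiteTable(panel)
  S <- length(sites$base)
  fpMb <- panelFootprint(panel) / 1e6
  uvw <- unname(uvSignatureProfile())
  ctxLen <- vapply(sites$byContext, length, 1L)
  cdsRows <- which(sites$cpos > 0L)

  # per-gene missense share for enrichment multipliers
  multGenes <- names(cfg$mis_multiplier)[cfg$mis_multiplier > 1]
  pMis <- stats::setNames(numeric(length(multGenes)), multGenes)
  for (gn in multGenes) {
    sc <- geneSiteClassesCached(panel, gn)
    pMis[gn] <- sum(sc$class == 2L) / (3 * S)
  }

  rowL <- altL <- sampL <- list()
  indelL <- list()
  k <- 0L
  for (si in seq_len(n)) {
    sid <- meta$sample_id[si]
    set.seed(substreamSeed(cfg$seed, paste0("mut:", sid)))
    lambda <- tmb_i[si] * fpMb
    N <- stats::rpois(1, lambda)
    nInd <- stats::rbinom(1, N, cfg$indel_fraction)
    nSNV <- N - nInd
    if (nSNV > 0) {
      if (uv_sample[si]) {
        ch <- sample.int(96L, nSNV, replace = TRUE, prob = uvw)
        ctx <- .CHANNEL_CONTEXT[ch]
        row <- integer(nSNV)
        for (cc in unique(ctx)) {
          w <- which(ctx == cc)
          row[w] <- sites$byContext[[cc]][
            sample.int(ctxLen[cc], length(w), replace = TRUE)]
        }
        pyrAlt <- .CHANNEL_ALT[ch]
        b <- sites$base[row]
        alt <- ifelse(b == 2L | b == 4L, pyrAlt, 5L - pyrAlt)
      } else {
        row <- sample.int(S, nSNV, replace = TRUE)
        b <- sites$base[row]
        alt <- ((b - 1L + sample.int(3L, nSNV, replace = TRUE)) %% 4L) + 1L
      }
      k <- k + 1L
      rowL[[k]] <- row; altL[[k]] <- alt
      sampL[[k]] <- rep(sid, nSNV)
    }
    # missense-enrichment extras (spiked selection pressure)
    for (gn in multGenes) {
      m <- cfg$mis_multiplier[[gn]]
      nEx <- stats::rpois(1, (m - 1) * lambda * pMis[gn])
      if (nEx > 0) {
        sc <- geneSiteClassesCached(panel, gn)
        mis <- which(sc$class == 2L)
        pick <- sc[mis[sample.int(length(mis), nEx, replace = TRUE)], ]
        gi <- match(gn, panel@genes$gene)
        # translate to site-table rows: site row = offset of gene + regOff - 1
        # (use gpos matching instead: emit variant rows directly)
        vr <- .spikeVariantRow(panel, gn, pick)
        vr$sample_id <- sid
        indelL[[length(indelL) + 1L]] <- vr     # reuse accumulator
      }
    }
    if (nInd > 0) {
      row <- cdsRows[sample.int(length(cdsRows), nInd, replace = TRUE)]
      fs <- stats::runif(nInd) < cfg$indel_fs_prob
      len <- ifelse(fs, sample(c(1L, 2L, 4L, 5L, 7L, 8L, 10L), nInd, replace = TRUE),
                    sample(c(3L, 6L, 9L), nInd, replace = TRUE))
      isDel <- stats::runif(nInd) < 0.5
      gi <- sites$geneIdx[row]
      seqs <- as.character(panel@regionSeqs[gi])
      off <- sites$regOff[row]
      len <- pmin(len, nchar(seqs) - off)
      base <- .BASES[sites$base[row]]
      refStr <- ifelse(isDel, substr(seqs, off, off + len), base)
      altStr <- ifelse(isDel, base,
                       paste0(base, vapply(len, function(L)
                         paste(sample(.BASES, L, replace = TRUE), collapse = ""),
                         character(1))))
      indelL[[length(indelL) + 1L]] <- data.frame(
        chrom = sites$chrom[row], pos = sites$gpos[row],
        ref = refStr, alt = altStr,
        variant_class = ifelse(isDel, "DEL", "INS"),
        gene = panel@genes$gene[gi],
        consequence = ifelse(len %% 3L == 0L, "inframe_indel", "frameshift"),
        protein_pos = (sites$cpos[row] - 1L) %/% 3L + 1L,
        aa_ref = NA_character_, aa_alt = NA_character_,
        sample_id = sid, stringsAsFactors = FALSE)
    }
  }

  somatic <- emptyVar
  if (k > 0) {
    row <- unlist(rowL); alt <- unlist(altL)
    snv <- classifySiteHits(panel, sites, row, alt)
    snv$sample_id <- unlist(sampL)
    snv <- snv[!duplicated(snv[, c("sample_id", "chrom", "pos")]), ]
    snv <- snv[snv$ref != snv$alt, ]
    somatic <- snv
  }

  # driver spike-ins
  set.seed(substreamSeed(cfg$seed, "spikes"))
  truth_drivers <- list()
  spikeRows <- list()
  sp <- cfg$driver_spikes
  if (nrow(sp) > 0) for (r in seq_len(nrow(sp))) {
    inType <- which(meta$tumor_type == sp$tumor_type[r])
    if (length(inType) == 0) next
    carrier <- inType[stats::runif(length(inType)) < sp$frequency[r]]
    if (length(carrier) == 0) next
    sc <- geneSiteClassesCached(panel, sp$gene[r])
    for (si in carrier) {
      sid <- meta$sample_id[si]
      v <- NULL
      if (sp$consequence[r] == "missense") {
        cand <- sc[sc$class == 2L, ]
        if (!is.na(sp$hotspot_residue[r]))
          cand <- cand[cand$codon == sp$hotspot_residue[r], ]
        if (!is.na(sp$aa_alt[r]))
          cand <- cand[cand$aa_alt == sp$aa_alt[r], ]
        if (nrow(cand) == 0) stop("no site available for spike in ", sp$gene[r])
        pick <- if (!is.na(sp$hotspot_residue[r])) cand[1L, , drop = FALSE]
                else cand[sample.int(nrow(cand), 1L), , drop = FALSE]
        v <- .spikeVariantRow(panel, sp$gene[r], pick)
      } else if (sp$consequence[r] == "nonsense") {
        cand <- sc[sc$consequence == "nonsense", ]
        pick <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
        v <- .spikeVariantRow(panel, sp$gene[r], pick)
      } else if (sp$consequence[r] == "frameshift") {
        cand <- sc[sc$class == 2L, ]
        pick <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
        g <- panel@genes[match(sp$gene[r], panel@genes$gene), ]
        v <- data.frame(chrom = g$chrom, pos = pick$gpos, ref = pick$gref,
                        alt = paste0(pick$gref, sample(.BASES, 1)),
                        variant_class = "INS", gene = sp$gene[r],
                        consequence = "frameshift", protein_pos = pick$codon,
                        aa_ref = NA_character_, aa_alt = NA_character_,
                        stringsAsFactors = FALSE)
        v$variant_class <- "DEL"
        v$ref <- paste0(pick$gref, sample(.BASES, 1))
        v$alt <- pick$gref
      } else if (sp$consequence[r] == "splice_site") {
        g <- panel@genes[match(sp$gene[r], panel@genes$gene), ]
        v <- data.frame(chrom = g$chrom, pos = g$cds_start - 1L, ref = "G",
                        alt = "A", variant_class = "SNV", gene = sp$gene[r],
                        consequence = "splice_site", protein_pos = NA_integer_,
                        aa_ref = NA_character_, aa_alt = NA_character_,
                        stringsAsFactors = FALSE)
      }
      v$sample_id <- sid
      spikeRows[[length(spikeRows) + 1L]] <- v
      truth_drivers[[length(truth_drivers) + 1L]] <- data.frame(
        sample_id = sid, tumor_type = sp$tumor_type[r], gene = sp$gene[r],
        consequence = sp$consequence[r],
        hotspot_residue = sp$hotspot_residue[r], stringsAsFactors = FALSE)
    }
  }
  extra <- c(spikeRows, indelL)
  if (length(extra) > 0) {
    somatic <- rbind(somatic, do.call(rbind, extra)[, names(somatic)])
  }
  if (nrow(somatic) > 0) {
    somatic$compartment <- "somatic"
    somatic <- somatic[order(somatic$sample_id, somatic$chrom, somatic$pos), ]
    somatic <- somatic[, names(emptyVar)]
    rownames(somatic) <- NULL
  } else somatic <- emptyVar

  # germline variants
  set.seed(substreamSeed(cfg$seed, "germline"))
  pg <- intersect(predispositionGenes(), panel@genes$gene)
  wts <- stats::setNames(rep((1 - cfg$germline_chek2_weight) /
                               max(1, length(pg) - 1), length(pg)), pg)
  if ("CHEK2" %in% pg) wts["CHEK2"] <- cfg$germline_chek2_weight
  germL <- list()
  truth_germ <- list()
  for (si in seq_len(n)) {
    sid <- meta$sample_id[si]
    # benign missense background
    nNoise <- stats::rpois(1, cfg$germline_noise_per_sample)
    if (nNoise > 0) {
      gns <- panel@genes$gene[sample.int(nrow(panel@genes), nNoise, replace = TRUE)]
      for (gn in gns) {
        sc <- geneSiteClassesCached(panel, gn)
        cand <- sc[sc$class == 2L, ]
        pick <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
        v <- .spikeVariantRow(panel, gn, pick)
        v$sample_id <- sid
        germL[[length(germL) + 1L]] <- v
      }
    }
    if (stats::runif(1) < cfg$germline_prevalence && length(pg) > 0) {
      gn <- sample(pg, 1, prob = wts)
      sc <- geneSiteClassesCached(panel, gn)
      if (gn == "CHEK2") {
        pick <- sc[sc$cpos == 546L & sc$aa_alt == "*", ][1L, , drop = FALSE]
      } else {
        cand <- sc[sc$consequence == "nonsense", ]
        pick <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
      }
      v <- .spikeVariantRow(panel, gn, pick)
      v$sample_id <- sid
      germL[[length(germL) + 1L]] <- v
      truth_germ[[length(truth_germ) + 1L]] <- data.frame(
        sample_id = sid, gene = gn, protein_pos = pick$codon,
        aa_ref = pick$aa_ref, stringsAsFactors = FALSE)
    }
  }
  germline <- if (length(germL) > 0) {
    gdf <- do.call(rbind, germL)
    gdf$compartment <- "germline"
    gdf <- gdf[order(gdf$sample_id, gdf$chrom, gdf$pos), names(emptyVar)]
    rownames(gdf) <- NULL
    gdf
  } else emptyVar

  # copy-number segments
  set.seed(substreamSeed(cfg$seed, "cna"))
  cl <- chromLengths(panelLayout(panel))
  segL <- list()
  truth_cn <- list()
  tpl <- cfg$cn_templates
  for (si in seq_len(n)) {
    sid <- meta$sample_id[si]
    tt <- meta$tumor_type[si]
    scale_i <- cfg$cna_scale * z_cna[si]
    rows <- tpl[tpl$tumor_type == tt | tpl$tumor_type == "*", , drop = FALSE]
    p <- stats::plogis(stats::qlogis(pmin(pmax(rows$frequency, 1e-6), 1 - 1e-6)) +
                         scale_i)
    drawn <- rows[stats::runif(nrow(rows)) < p, , drop = FALSE]
    if (nrow(drawn) > 0)
      truth_cn[[length(truth_cn) + 1L]] <- data.frame(
        sample_id = sid, label = drawn$label, chrom = drawn$chrom,
        start = drawn$start, end = drawn$end, log2fc = drawn$log2fc,
        stringsAsFactors = FALSE)
    nNoise <- stats::rpois(1, cfg$cna_noise_rate[[tt]] * exp(scale_i))
    if (nNoise > 0) {
      nch <- sample(names(cl), nNoise, replace = TRUE, prob = cl)
      nlen <- stats::runif(nNoise, 0.5e6, 8e6)
      nst <- floor(stats::runif(nNoise, 1, pmax(2, cl[nch] - nlen)))
      nfc <- sample(c(-1, 1), nNoise, replace = TRUE) *
        stats::runif(nNoise, 0.35, 0.8)
      drawn <- rbind(drawn[, c("chrom", "start", "end", "log2fc")],
                     data.frame(chrom = nch, start = nst, end = nst + nlen,
                                log2fc = nfc))
    } else if (nrow(drawn) > 0) {
      drawn <- drawn[, c("chrom", "start", "end", "log2fc")]
    } else next
    # resolve overlaps: the shortest (most focal) event wins
    for (ch in unique(drawn$chrom)) {
      ev <- drawn[drawn$chrom == ch, , drop = FALSE]
      ev$start <- pmax(1, round(ev$start))
      ev$end <- pmin(cl[[ch]], round(ev$end))
      ev <- ev[ev$start <= ev$end, , drop = FALSE]
      if (nrow(ev) == 0) next
      ev <- ev[order(ev$end - ev$start, decreasing = TRUE), , drop = FALSE]
      ir <- IRanges::IRanges(ev$start, ev$end)
      tiles <- IRanges::disjoin(ir)
      ov <- IRanges::findOverlaps(tiles, ir)
      hitIdx <- tapply(S4Vectors::subjectHits(ov),
                       factor(S4Vectors::queryHits(ov),
                              levels = seq_along(tiles)),
                       max)                              # later = shorter
      fc <- ev$log2fc[hitIdx]
      st <- IRanges::start(tiles); en <- IRanges::end(tiles)
      # merge adjacent tiles with equal value
      keep <- c(TRUE, fc[-1] != fc[-length(fc)] | st[-1] != en[-length(en)] + 1)
      gid <- cumsum(keep)
      st2 <- tapply(st, gid, min); en2 <- tapply(en, gid, max)
      fc2 <- fc[keep]
      fc2 <- fc2 + stats::rnorm(length(fc2), 0, 0.03)
      segL[[length(segL) + 1L]] <- data.frame(
        sample_id = sid, chrom = ch, start = as.numeric(st2),
        end = as.numeric(en2), log2fc = round(fc2, 4),
        stringsAsFactors = FALSE)
    }
  }
  segments <- if (length(segL) > 0) {
    sdf <- do.call(rbind, segL)
    sdf <- sdf[order(sdf$sample_id, sdf$chrom, sdf$start), ]
    rownames(sdf) <- NULL
    sdf
  } else emptySeg

  # off-target reads with planted viral sequences
  set.seed(substreamSeed(cfg$seed, "viral"))
  rl <- cfg$viral_read_length
  reads <- stats::setNames(vector("list", n), meta$sample_id)
  for (si in seq_len(n)) {
    nb <- cfg$viral_background_reads
    reads[[si]] <- if (nb > 0)
      vapply(seq_len(nb), function(i)
        paste(sample(.BASES, rl, replace = TRUE), collapse = ""), character(1))
    else character(0)
  }
  truth_viral <- list()
  vp <- cfg$viral_plant
  if (nrow(vp) > 0) for (r in seq_len(nrow(vp))) {
    if (!vp$virus[r] %in% names(viruses)) next
    vseq <- as.character(viruses[[vp$virus[r]]])
    inType <- which(meta$tumor_type == vp$tumor_type[r])
    pos_samples <- inType[stats::runif(length(inType)) < vp$positive_fraction[r]]
    for (si in pos_samples) {
      nr <- vp$reads_per_sample[r]
      st <- sample.int(nchar(vseq) - rl + 1L, nr, replace = TRUE)
      rd <- substring(vseq, st, st + rl - 1L)
      flip <- stats::runif(nr) < 0.5
      rd[flip] <- revcompStr(rd[flip])
      rd <- .addReadErrors(rd, cfg$viral_error_rate)
      reads[[si]] <- c(reads[[si]], rd)
      truth_viral[[length(truth_viral) + 1L]] <- data.frame(
        sample_id = meta$sample_id[si], tumor_type = vp$tumor_type[r],
        virus = vp$virus[r], n_reads = nr, stringsAsFactors = FALSE)
    }
  }

  bindOrEmpty <- function(L) if (length(L) > 0) do.call(rbind, L) else data.frame()
  new("CancerCohort", meta = meta, somatic = somatic, germline = germline,
      segments = segments, reads = reads,
      truth = list(drivers = bindOrEmpty(truth_drivers),
                   cn_events = bindOrEmpty(truth_cn),
                   germline = bindOrEmpty(truth_germ),
                   viral = bindOrEmpty(truth_viral),
                   latent = data.frame(sample_id = meta$sample_id,
                                       z_mut = z_mut, z_cna = z_cna,
                                       tmb = tmb_i, uv = uv_sample)))
}

#' Planted-event truth table
#'
#' Binds the generator's ground-truth records (driver spike-ins, CN
#' template events, germline LoF plants, viral read plants) into one long
#' table for recovery testing.
#'
#' @param cohort A synthetic \linkS4class{CancerCohort}.
#' @return data.frame with columns event_type, sample_id, detail columns.
#' @export
truthTable <- function(cohort) {
  tr <- cohortTruth(cohort)
  pieces <- list()
  addPiece <- function(df, type, detail_cols) {
    if (is.null(df) || nrow(df) == 0) return()
    detail <- apply(df[, detail_cols, drop = FALSE], 1, function(r)
      paste(paste0(detail_cols, "=", r), collapse = ";"))
    pieces[[length(pieces) + 1L]] <<- data.frame(
      event_type = type, sample_id = df$sample_id, detail = detail,
      stringsAsFactors = FALSE)
  }
  addPiece(tr$drivers, "driver", c("gene", "consequence", "hotspot_residue"))
  addPiece(tr$cn_events, "cn_event", c("label", "chrom", "log2fc"))
  addPiece(tr$germline, "germline", c("gene", "protein_pos"))
  addPiece(tr$viral, "viral", c("virus", "n_reads"))
  if (length(pieces) == 0)
    return(data.frame(event_type = character(0), sample_id = character(0),
                      detail = character(0)))
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
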