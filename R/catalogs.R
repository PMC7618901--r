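# Actionability triage against user-supplied catalogs (druggability tiers,
# synthetic-lethal partners, actionable-variant levels) and germline
# predisposition screening. The real databases (TCRD/Pharos, SL resources,
# OncoKB, ClinVar) are licensed products supplied by the user as TSVs;
# tiny illustrative catalogs ship as test fixtures only.

#' Read a druggability (target-development-level) catalog
#'
#' TSV with columns \code{gene} and \code{development_level} (Tclin =
#' approved drug exists, Tchem, Tbio, Tdark); one row per gene.
#'
#' @param path Path to the TSV.
#' @return data.frame gene, development_level.
#' @export
readDruggability <- function(path) {
  df <- readTsv(path)
  stopifnot(all(c("gene", "development_level") %in% names(df)))
  if (anyDuplicated(df$gene)) stop("druggability catalog: one row per gene")
  bad <- setdiff(df$development_level, c("Tclin", "Tchem", "Tbio", "Tdark"))
  if (length(bad) > 0) stop("unknown development_level: ", paste(bad, collapse = ", "))
  df
}

#' Read a synthetic-lethality catalog
#'
#' TSV with columns \code{driver_gene}, \code{partner_gene},
#' \code{partner_druggable} (TRUE/FALSE), \code{evidence_id}.
#'
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
readSlCatalog <- function(path) {
  df <- readTsv(path)
  stopifnot(all(c("driver_gene", "partner_gene", "partner_druggable") %in% names(df)))
  if (anyDuplicated(df[, c("driver_gene", "partner_gene")]))
    stop("SL catalog: (driver, partner) pairs must be unique")
  df$partner_druggable <- as.logical(df$partner_druggable)
  df
}

#' Read an actionable-variant catalog
#'
#' TSV with columns \code{gene}, \code{protein_change} (normalized
#' RefPosAlt form, e.g. H1047R), \code{oncogenicity} (oncogenic /
#' likely_oncogenic / other) and \code{level} (1-4, therapeutic evidence
#' tier; empty unless oncogenic/likely_oncogenic).
#'
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
readActionableCatalog <- function(path) {
  df <- readTsv(path)
  stopifnot(all(c("gene", "protein_change", "oncogenicity", "level") %in% names(df)))
  onc <- df$oncogenicity %in% c("oncogenic", "likely_oncogenic")
  if (any(!onc & !is.na(df$level) & df$level != ""))
    stop("level must be present only for oncogenic/likely_oncogenic entries")
  df$level <- suppressWarnings(as.integer(df$level))
  df
}

#' Read a pathogenic-variant (ClinVar-like) catalog
#'
#' TSV with columns \code{gene} and \code{protein_change} (e.g. Y182*).
#'
#' @param path Path to the TSV.
#' @return data.frame.
#' @export
readPathogenicCatalog <- function(path) {
  df <- readTsv(path)
  stopifnot(all(c("gene", "protein_change") %in% names(df)))
  df
}

#' Screen germline variants for predisposition candidates
#'
#' Keeps loss-of-function germline variants (nonsense, frameshift,
#' splice-site, start-loss) in the listed predisposition genes, humanizes
#' the affected residue where protein annotation and an ortholog map
#' exist, and matches the humanized change against a pathogenic catalog.
#'
#' @param germline Germline variant data.frame.
#' @param gene_list Non-empty character vector of predisposition genes.
#' @param panel A \linkS4class{GenePanel} (for ortholog residue maps).
#' @param pathogenic Optional pathogenic catalog
#'   (\code{\link{readPathogenicCatalog}}).
#' @return data.frame: sample_id, gene, chrom, pos, lof_class,
#'   protein_pos, human_change, mapping_status, pathogenic_match in
#'   \{orthologous_pathogenic, no_match, unmapped\}.
#' @export
screenGermline <- function(germline, gene_list, panel, pathogenic = NULL) {
  if (length(gene_list) == 0) stop("predisposition gene list must be non-empty")
  lof <- c("nonsense", "frameshift", "splice_site", "start_loss")
  v <- germline[germline$consequence %in% lof &
                  germline$gene %in% gene_list, , drop = FALSE]
  if (nrow(v) == 0)
    return(data.frame(sample_id = character(0), gene = character(0),
                      chrom = character(0), pos = numeric(0),
                      lof_class = character(0), protein_pos = integer(0),
                      human_change = character(0),
                      mapping_status = character(0),
                      pathogenic_match = character(0)))
  out <- data.frame(sample_id = v$sample_id, gene = v$gene, chrom = v$chrom,
                    pos = v$pos, lof_class = v$consequence,
                    protein_pos = v$protein_pos,
                    human_change = "", mapping_status = "unannotated",
                    pathogenic_match = "unmapped", stringsAsFactors = FALSE)
  mappable <- !is.na(v$protein_pos) & !is.na(v$aa_ref) & !is.na(v$aa_alt)
  hz <- humanizeVariants(v[mappable, , drop = FALSE], panel)
  if (nrow(hz) > 0) {
    out$mapping_status[mappable] <- hz$status
    out$human_change[mappable] <- hz$human_change
    mapped <- out$mapping_status == "mapped"
    out$pathogenic_match[mapped] <- "no_match"
    if (!is.null(pathogenic) && any(mapped)) {
      key <- paste(geneModels(panel)$human_ortholog[
        match(out$gene, geneModels(panel)$gene)], out$human_change)
      hit <- mapped & key %in% paste(pathogenic$gene, pathogenic$protein_change)
      out$pathogenic_match[hit] <- "orthologous_pathogenic"
    }
  }
  rownames(out) <- NULL
  out
}

# Distinct protein-altering mutated driver genes per tumor.
.mutatedDriverSets <- function(variants, drivers) {
  altering <- c(truncatingClasses(), "missense", "inframe_indel")
  v <- variants[variants$consequence %in% altering &
                  variants$gene %in% drivers, , drop = FALSE]
  split(v$gene, v$sample_id)
}

#' Druggability triage of mutated driver genes
#'
#' Flags each tumor that carries a protein-altering mutation in at least
#' one driver gene whose human ortholog has development level Tclin
#' (approved drug exists). The summary reports gene-level (drivers that
#' are Tclin) and tumor-level (tumors with a mutated Tclin driver) counts
#' with rounded percents under the cohort percent convention.
#'
#' @param drivers Non-empty character vector of driver genes.
#' @param variants Somatic variant data.frame.
#' @param meta Sample metadata (cohort denominator).
#' @param druggability \code{\link{readDruggability}} catalog.
#' @return List: \code{per_tumor} (sample_id, tclin_hit), \code{summary}
#'   (n_drivers, n_tclin_drivers, gene_percent, n_tumors, n_hit_tumors,
#'   tumor_percent).
#' @export
annotateDruggability <- function(drivers, variants, meta, druggability) {
  if (length(drivers) == 0) stop("driver list must be non-empty")
  tclin <- druggability$gene[druggability$development_level == "Tclin"]
  tclinDrivers <- intersect(drivers, tclin)
  sets <- .mutatedDriverSets(variants, drivers)
  hit <- vapply(meta$sample_id, function(s)
    length(intersect(sets[[s]], tclinDrivers)) > 0, logical(1))
  per_tumor <- data.frame(sample_id = meta$sample_id,
                          tclin_hit = unname(hit), stringsAsFactors = FALSE)
  list(per_tumor = per_tumor,
       summary = data.frame(
         n_drivers = length(drivers),
         n_tclin_drivers = length(tclinDrivers),
         gene_percent = roundPercent(length(tclinDrivers), length(drivers)),
         n_tumors = nrow(meta),
         n_hit_tumors = sum(hit),
         tumor_percent = if (nrow(meta) > 0)
           roundPercent(sum(hit), nrow(meta)) else NA_integer_))
}

#' Synthetic-lethality triage of mutated driver genes
#'
#' Flags each tumor mutated in at least one driver gene that has at least
#' one druggable synthetic-lethal partner.
#'
#' @param drivers Character vector of driver genes.
#' @param variants Somatic variant data.frame.
#' @param meta Sample metadata.
#' @param sl \code{\link{readSlCatalog}} catalog.
#' @return List: \code{per_tumor} (sample_id, sl_hit), \code{summary}.
#' @export
annotateSl <- function(drivers, variants, meta, sl) {
  slDrivers <- intersect(drivers,
                         unique(sl$driver_gene[sl$partner_druggable]))
  sets <- .mutatedDriverSets(variants, drivers)
  hit <- vapply(meta$sample_id, function(s)
    length(intersect(sets[[s]], slDrivers)) > 0, logical(1))
  list(per_tumor = data.frame(sample_id = meta$sample_id,
                              sl_hit = unname(hit), stringsAsFactors = FALSE),
       summary = data.frame(
         n_drivers = length(drivers),
         n_sl_drivers = length(slDrivers),
         n_tumors = nrow(meta),
         n_hit_tumors = sum(hit),
         tumor_percent = if (nrow(meta) > 0)
           roundPercent(sum(hit), nrow(meta)) else NA_integer_))
}

#' Actionable-variant triage of humanized mutations
#'
#' A tumor is actionable iff at least one humanized SNV (status mapped)
#' in a driver gene matches a catalog entry annotated
#' oncogenic/likely_oncogenic; the best (lowest-numbered) therapeutic
#' level is recorded. Matching is exact on the normalized RefPosAlt form;
#' \code{position_only = TRUE} matches any change at the catalog position.
#'
#' @param humanized \code{\link{humanizeVariants}} output restricted to
#'   driver genes.
#' @param meta Sample metadata.
#' @param actionable \code{\link{readActionableCatalog}} catalog.
#' @param position_only Match on position rather than full change.
#' @return List: \code{per_tumor} (sample_id, actionable_level, NA when
#'   none), \code{summary} (counts per level and the tumor percent).
#' @export
annotateActionable <- function(humanized, meta, actionable,
                               position_only = FALSE) {
  onc <- actionable[actionable$oncogenicity %in%
                      c("oncogenic", "likely_oncogenic"), , drop = FALSE]
  h <- humanized[humanized$status == "mapped", , drop = FALSE]
  level <- rep(NA_integer_, nrow(meta))
  if (nrow(h) > 0 && nrow(onc) > 0) {
    if (position_only) {
      hpos <- gsub("[A-Z*]", "", h$human_change)
      cpos <- gsub("[A-Z*]", "", onc$protein_change)
      key_h <- paste(h$human_gene, hpos)
      key_c <- paste(onc$gene, cpos)
    } else {
      key_h <- paste(h$human_gene, h$human_change)
      key_c <- paste(onc$gene, onc$protein_change)
    }
    m <- match(key_h, key_c)
    hit <- !is.na(m)
    if (any(hit)) {
      lv <- stats::aggregate(level ~ sample_id,
                             data = data.frame(sample_id = h$sample_id[hit],
                                               level = onc$level[m[hit]]),
                             FUN = min, na.rm = TRUE)
      level[match(lv$sample_id, meta$sample_id)] <- lv$level
    }
  }
  per_tumor <- data.frame(sample_id = meta$sample_id,
                          actionable_level = level, stringsAsFactors = FALSE)
  nHit <- sum(!is.na(level))
  list(per_tumor = per_tumor,
       summary = data.frame(
         n_tumors = nrow(meta), n_actionable_tumors = nHit,
         tumor_percent = if (nrow(meta) > 0)
           roundPercent(nHit, nrow(meta)) else NA_integer_,
         level1 = sum(level == 1, na.rm = TRUE),
         level2 = sum(level == 2, na.rm = TRUE),
         level3 = sum(level == 3, na.rm = TRUE),
         level4 = sum(level == 4, na.rm = TRUE)))
}
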