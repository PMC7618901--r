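# Driver-gene detection: a simplified context-aware dN/dS positive-
# selection test. A 96-channel background rate is estimated from
# synonymous SNVs (plus a genome-wide frameshift-indel rate); per gene the
# observed missense and truncating counts are compared to their expected
# counts under the background by a 2-df Poisson likelihood-ratio test with
# free omega_mis / omega_trunc, followed by Benjamini-Hochberg correction
# within each tumor-type family. Deliberately simpler than full
# dNdScv-style models: no covariates, no per-gene random effects, and
# 96-channel rather than strand-specific 192-channel rates.

#' Estimate the background mutation model from synonymous variants
#'
#' Channel rate = synonymous SNV count in the channel divided by the
#' panel-wide count of sites where that channel's change is synonymous.
#' With fewer than \code{min_syn} synonymous SNVs the model falls back to
#' a flat per-site rate (total synonymous count over total synonymous
#' opportunity) with a warning. The truncating indel rate is estimated
#' from coding frameshift indels per coding base, matching the indel class
#' counted by the selection test.
#'
#' @param variants Somatic variant data.frame (the family being tested,
#'   e.g. one tumor type).
#' @param panel A \linkS4class{GenePanel}.
#' @param min_syn Minimum synonymous SNVs before falling back to a flat
#'   model (default 50).
#' @return List with \code{context_rates} (96 rates per available site),
#'   \code{indel_rate} (frameshift indels per coding base across the
#'   family), \code{estimated_from} (counts used) and \code{flat_fallback}.
#' @export
estimateBackground <- function(variants, panel, min_syn = 50L) {
  if (nrow(geneModels(panel)) == 0) stop("no gene models in panel")
  opp <- panelOpportunity(panel)
  synOpp <- colSums(opp[, , "syn", drop = FALSE][, , 1])
  syn <- variants[variants$consequence == "synonymous" &
                    variants$variant_class == "SNV", , drop = FALSE]
  nSyn <- nrow(syn)
  flat <- nSyn < min_syn
  if (flat) {
    warning("only ", nSyn, " synonymous SNVs; falling back to a flat rate model")
    total <- nSyn / max(sum(synOpp), 1)
    rates <- rep(total, 96)
  } else {
    # channel of each synonymous SNV from its site-class annotation
    cnt <- synChannelCounts(syn, panel)
    rates <- ifelse(synOpp > 0, cnt / synOpp, 0)
  }
  cds_bases <- sum(geneModels(panel)$cds_end - geneModels(panel)$cds_start + 1)
  fsIndels <- sum(variants$consequence == "frameshift" &
                    variants$variant_class %in% c("INS", "DEL"))
  list(context_rates = stats::setNames(rates, channelLabels()),
       indel_rate = fsIndels / cds_bases,
       estimated_from = c(synonymous_snvs = nSyn, frameshift_indels = fsIndels),
       flat_fallback = flat)
}

# Channel counts of synonymous SNVs via genomic context lookup.
synChannelCounts <- function(syn, panel) {
  ctx <- extractContext(panel, syn$chrom, syn$pos)
  alt <- encodeBase(syn$alt)
  ok <- !is.na(ctx$up) & !is.na(ctx$ref) & !is.na(ctx$dn) & !is.na(alt)
  ch <- channelIndex(ctx$up[ok], ctx$ref[ok], ctx$dn[ok], alt[ok])
  tabulate(ch, nbins = 96L)
}

#' Positive-selection test for one gene
#'
#' Expected missense / truncating counts are obtained by summing the
#' background channel rates over the gene's missense and truncating
#' opportunity sites (plus the family indel rate times CDS length for
#' truncating; the family's sample count is absorbed into the rates). Maximum-likelihood
#' observed/expected ratios (omega) are tested against omega = 1 by a
#' likelihood-ratio statistic referred to a 2-df chi-square upper tail.
#'
#' @param gene Gene symbol.
#' @param variants Somatic variants of the family (e.g. one tumor type).
#' @param background \code{\link{estimateBackground}} output for the same
#'   family.
#' @param panel A \linkS4class{GenePanel}.
#' @return One-row data.frame: gene, n_syn, n_mis, n_trunc, e_mis,
#'   e_trunc, omega_mis, omega_trunc, lrt_stat, p_value.
#' @export
testGene <- function(gene, variants, background, panel) {
  g <- geneModels(panel)
  gi <- match(gene, g$gene)
  if (is.na(gi)) {
    warning("gene not in panel, skipped: ", gene)
    return(NULL)
  }
  opp <- panelOpportunity(panel)
  rates <- background$context_rates
  e_mis <- sum(rates * opp[gi, , "mis"])
  cds_len <- g$cds_end[gi] - g$cds_start[gi] + 1
  e_trunc <- sum(rates * opp[gi, , "trunc"]) +
    background$indel_rate * cds_len
  v <- variants[variants$gene == gene, , drop = FALSE]
  n_syn <- sum(v$consequence == "synonymous" & v$variant_class == "SNV")
  n_mis <- sum(v$consequence == "missense" & v$variant_class == "SNV")
  n_trunc <- sum(v$consequence %in% truncatingClasses())
  # Poisson LRT, omega_mis and omega_trunc free vs both 1
  dev <- function(n, e) {
    if (e <= 0) return(0)
    if (n == 0) return(2 * e)
    2 * (n * log(n / e) - n + e)
  }
  lrt <- dev(n_mis, e_mis) + dev(n_trunc, e_trunc)
  p <- stats::pchisq(lrt, df = 2, lower.tail = FALSE)
  data.frame(gene = gene,
             n_syn = n_syn, n_mis = n_mis, n_trunc = n_trunc,
             e_mis = e_mis, e_trunc = e_trunc,
             omega_mis = if (e_mis > 0) n_mis / e_mis else 0,
             omega_trunc = if (e_trunc > 0) n_trunc / e_trunc else 0,
             lrt_stat = lrt, p_value = p, stringsAsFactors = FALSE)
}

#' Test every panel gene within one family
#'
#' @param variants Somatic variants of the family.
#' @param panel A \linkS4class{GenePanel}.
#' @param background Optional precomputed background (default: estimated
#'   from \code{variants}).
#' @return data.frame of \code{\link{testGene}} rows for all genes.
#' @export
testAllGenes <- function(variants, panel, background = NULL) {
  if (is.null(background))
    background <- suppressWarnings(estimateBackground(variants, panel))
  g <- geneModels(panel)
  opp <- panelOpportunity(panel)
  rates <- background$context_rates
  e_mis <- as.numeric(opp[, , "mis"] %*% rates)
  cds_len <- g$cds_end - g$cds_start + 1
  e_trunc <- as.numeric(opp[, , "trunc"] %*% rates) +
    background$indel_rate * cds_len
  v <- variants
  cnt <- function(sel) {
    t <- table(factor(v$gene[sel], levels = g$gene))
    as.integer(t)
  }
  n_syn <- cnt(v$consequence == "synonymous" & v$variant_class == "SNV")
  n_mis <- cnt(v$consequence == "missense" & v$variant_class == "SNV")
  n_trunc <- cnt(v$consequence %in% truncatingClasses())
  devv <- function(n, e) {
    d <- 2 * e
    pos <- n > 0 & e > 0
    d[pos] <- 2 * (n[pos] * log(n[pos] / e[pos]) - n[pos] + e[pos])
    d[e <= 0] <- 0
    d
  }
  lrt <- devv(n_mis, e_mis) + devv(n_trunc, e_trunc)
  data.frame(gene = g$gene, n_syn = n_syn, n_mis = n_mis, n_trunc = n_trunc,
             e_mis = e_mis, e_trunc = e_trunc,
             omega_mis = ifelse(e_mis > 0, n_mis / e_mis, 0),
             omega_trunc = ifelse(e_trunc > 0, n_trunc / e_trunc, 0),
             lrt_stat = lrt,
             p_value = stats::pchisq(lrt, df = 2, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Call driver genes at a q-value threshold
#'
#' Benjamini-Hochberg correction across all genes tested within the
#' family; genes with q below \code{q_max} and evidence of enrichment
#' (omega_mis > 1 or omega_trunc > 1 — a deficit is never called) are
#' returned sorted by ascending q then gene name.
#'
#' @param results \code{\link{testAllGenes}} output (one family).
#' @param q_max q-value threshold (default 0.1).
#' @return \code{results} with a \code{q_value} column, called rows only.
#' @export
callDrivers <- function(results, q_max = 0.1) {
  if (nrow(results) == 0) stop("need at least one test result")
  results$q_value <- stats::p.adjust(results$p_value, method = "BH")
  called <- results[results$q_value < q_max &
                      (results$omega_mis > 1 | results$omega_trunc > 1), ,
                    drop = FALSE]
  called <- called[order(called$q_value, called$gene), , drop = FALSE]
  rownames(called) <- NULL
  called
}

#' Per-tumor-type driver screen
#'
#' Runs background estimation and gene tests within each tumor type and
#' applies BH within the type ("q-global" interpreted as the within-family
#' correction); with \code{family = "pan"} a single pan-cancer family is
#' used instead.
#'
#' @param variants Somatic variant data.frame (whole cohort).
#' @param meta Sample metadata.
#' @param panel A \linkS4class{GenePanel}.
#' @param q_max q-value threshold.
#' @param family "per_type" (default) or "pan".
#' @return data.frame of called drivers with a tumor_type column
#'   ("pan" for the pan-cancer family).
#' @export
driverScreen <- function(variants, meta, panel, q_max = 0.1,
                         family = c("per_type", "pan")) {
  family <- match.arg(family)
  groups <- if (family == "pan") list(pan = meta$sample_id) else
    split(meta$sample_id, meta$tumor_type)
  out <- list()
  for (tt in names(groups)) {
    sids <- groups[[tt]]
    vt <- variants[variants$sample_id %in% sids, , drop = FALSE]
    if (nrow(vt) == 0) next
    res <- testAllGenes(vt, panel)
    called <- callDrivers(res, q_max)
    if (nrow(called) > 0) {
      called$tumor_type <- tt
      out[[tt]] <- called
    }
  }
  if (length(out) == 0)
    return(data.frame(gene = character(0), tumor_type = character(0),
                      q_value = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
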