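# Somatic landscape summaries: tumor mutational burden, per-type gene
# ranking, oncoplot matrix, and protein hotspot detection.

#' Tumor mutational burden of one sample
#'
#' Somatic mutation count (SNVs, MNVs and indels passing input filters)
#' divided by the deduplicated panel footprint in megabases.
#'
#' @param variants Somatic variant data.frame of one sample.
#' @param footprint_mb Panel footprint in Mb (> 0).
#' @return Mutations per megabase.
#' @export
computeTmb <- function(variants, footprint_mb) {
  if (!is.numeric(footprint_mb) || footprint_mb <= 0)
    stop("footprint_mb must be positive")
  nrow(variants) / footprint_mb
}

#' Per-sample TMB table for a cohort
#'
#' @param variants Somatic variant data.frame.
#' @param meta Sample metadata (all samples appear, including those with 0
#'   mutations).
#' @param footprint_mb Panel footprint in Mb.
#' @return data.frame sample_id, tumor_type, n_mutations, tmb.
#' @export
cohortTmb <- function(variants, meta, footprint_mb) {
  if (footprint_mb <= 0) stop("footprint_mb must be positive")
  cnt <- table(factor(variants$sample_id, levels = meta$sample_id))
  data.frame(sample_id = meta$sample_id, tumor_type = meta$tumor_type,
             n_mutations = as.integer(cnt),
             tmb = as.numeric(cnt) / footprint_mb,
             stringsAsFactors = FALSE)
}

#' Rank genes by mutated-sample fraction per tumor type
#'
#' For each tumor type, the fraction of samples carrying at least one
#' mutation in each gene (a sample counts once per gene however many
#' mutations it carries). Ties are broken lexicographically by gene name.
#'
#' @param variants Somatic variant data.frame.
#' @param meta Sample metadata.
#' @param top_k Number of top genes to keep per type (>= 1).
#' @return data.frame tumor_type, gene, n_mutated, n_type, fraction, rank.
#' @export
rankGenes <- function(variants, meta, top_k = 5L) {
  if (top_k < 1) stop("top_k must be >= 1")
  out <- list()
  v <- variants[variants$gene != "", , drop = FALSE]
  for (tt in unique(meta$tumor_type)) {
    sids <- meta$sample_id[meta$tumor_type == tt]
    vt <- v[v$sample_id %in% sids, , drop = FALSE]
    if (nrow(vt) == 0) next
    pairs <- unique(vt[, c("sample_id", "gene")])
    cnt <- table(pairs$gene)
    df <- data.frame(tumor_type = tt, gene = names(cnt),
                     n_mutated = as.integer(cnt), n_type = length(sids),
                     stringsAsFactors = FALSE)
    df$fraction <- df$n_mutated / df$n_type
    df <- df[order(-df$fraction, df$gene), , drop = FALSE]
    df <- utils::head(df, top_k)
    df$rank <- seq_len(nrow(df))
    out[[tt]] <- df
  }
  if (length(out) == 0)
    return(data.frame(tumor_type = character(0), gene = character(0),
                      n_mutated = integer(0), n_type = integer(0),
                      fraction = numeric(0), rank = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# consequence priority for oncoplot cells: truncating > missense-class >
# synonymous > none
.CONSEQ_PRIORITY <- c(nonsense = 3L, frameshift = 3L, splice_site = 3L,
                      start_loss = 3L, nonstop = 3L,
                      missense = 2L, inframe_indel = 2L,
                      synonymous = 1L, noncoding = 0L)

.PRIORITY_LABEL <- c("none", "synonymous", "missense", "truncating")

#' Oncoplot matrix: best consequence class per sample and gene
#'
#' One cell per sample/gene holding the highest-priority consequence class
#' present (truncating > missense/in-frame > synonymous > none).
#'
#' @param variants Somatic variant data.frame.
#' @param meta Sample metadata.
#' @param genes Non-empty character vector of genes (columns).
#' @return Character matrix samples x genes with values none / synonymous /
#'   missense / truncating.
#' @export
oncoplotMatrix <- function(variants, meta, genes) {
  if (length(genes) == 0) stop("gene list must be non-empty")
  m <- matrix(0L, nrow = nrow(meta), ncol = length(genes),
              dimnames = list(meta$sample_id, genes))
  v <- variants[variants$gene %in% genes &
                  variants$sample_id %in% meta$sample_id, , drop = FALSE]
  if (nrow(v) > 0) {
    pr <- .CONSEQ_PRIORITY[v$consequence]
    i <- match(v$sample_id, meta$sample_id)
    j <- match(v$gene, genes)
    for (r in seq_len(nrow(v)))
      if (pr[r] > m[i[r], j[r]]) m[i[r], j[r]] <- pr[r]
  }
  out <- matrix(.PRIORITY_LABEL[m + 1L], nrow = nrow(m), dimnames = dimnames(m))
  out
}

#' Detect protein hotspots by residue recurrence
#'
#' Clusters the mutated residue positions of each gene by single linkage
#' with gap tolerance (positions at most \code{tolerance} apart chain into
#' one cluster) and reports clusters supported by at least
#' \code{min_tumors} distinct samples. Only missense and in-frame indel
#' residues are clustered: truncating variants are excluded because
#' downstream burden rules always count them, so hotspots exist to rescue
#' missense calls in hypermutators.
#'
#' @param variants Somatic variant data.frame with protein_pos for coding
#'   classes.
#' @param min_tumors Minimum distinct samples supporting a cluster
#'   (default 2).
#' @param tolerance Maximum residue gap joining two positions (default 1,
#'   i.e. the same position with a plus/minus 1-residue tolerance).
#' @return data.frame gene, residue_start, residue_end, n_tumors,
#'   n_mutations, label; label uses the modal reference residue at the
#'   modal position (e.g. "PIK3CA p.H1047").
#' @export
detectHotspots <- function(variants, min_tumors = 2L, tolerance = 1L) {
  v <- variants[variants$consequence %in% c("missense", "inframe_indel") &
                  !is.na(variants$protein_pos) & variants$gene != "", ,
                drop = FALSE]
  empty <- data.frame(gene = character(0), residue_start = integer(0),
                      residue_end = integer(0), n_tumors = integer(0),
                      n_mutations = integer(0), label = character(0))
  if (nrow(v) == 0) return(empty)
  out <- list()
  for (gn in sort(unique(v$gene))) {
    vg <- v[v$gene == gn, , drop = FALSE]
    vg <- vg[order(vg$protein_pos), , drop = FALSE]
    pos <- vg$protein_pos
    newClust <- c(TRUE, diff(pos) > tolerance)
    cid <- cumsum(newClust)
    for (cc in unique(cid)) {
      sel <- cid == cc
      nt <- length(unique(vg$sample_id[sel]))
      if (nt < min_tumors) next
      p <- pos[sel]
      modal <- as.integer(names(which.max(table(p))))
      aa <- vg$aa_ref[sel][p == modal]
      aa <- aa[!is.na(aa)]
      aaLab <- if (length(aa) > 0) names(which.max(table(aa))) else "?"
      out[[length(out) + 1L]] <- data.frame(
        gene = gn, residue_start = min(p), residue_end = max(p),
        n_tumors = nt, n_mutations = sum(sel),
        label = sprintf("%s p.%s%d", gn, aaLab, modal),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(-res$n_tumors, res$gene, res$residue_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
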