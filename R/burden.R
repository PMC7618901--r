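# The cancer-genome "hyperbola": per-sample focal CNA burden versus
# hypermutator-aware recurrent mutation burden, plus the 2-D density table.

#' Focal CNA burden of one sample
#'
#' Count of classified segments that are focal (length <= 10 Mb at the
#' default classification) and non-neutral, i.e. focal gains plus focal
#' losses.
#'
#' @param classified Classified segments of one sample.
#' @return Non-negative integer.
#' @export
focalBurden <- function(classified) {
  sum(classified$scope == "focal" & classified$direction != "neutral")
}

#' Recurrent mutation burden per sample
#'
#' Counts, per sample, somatic protein-altering variants restricted to
#' genes mutated in at least 2 distinct samples across the cohort.
#' Truncating variants (nonsense, frameshift, splice-site, start-loss,
#' nonstop) are always included. Missense and in-frame indels are included
#' for non-hypermutators; for hypermutator samples they count only when
#' the variant residue falls inside a detected hotspot cluster (computed
#' with the same residue tolerance). Synonymous and noncoding variants
#' participate in neither the recurrence test nor the burden.
#'
#' @param variants Somatic variant data.frame (whole cohort).
#' @param hypermutators Character vector of hypermutator sample ids (or a
#'   \code{\link{flagHypermutators}} result).
#' @param hotspots \code{\link{detectHotspots}} output; required whenever
#'   any sample is a hypermutator.
#' @param sample_ids Samples to report (default: all in \code{variants}).
#' @return data.frame sample_id, recurrent_mut_count, hypermutator.
#' @export
recurrentBurden <- function(variants, hypermutators = character(0),
                            hotspots = NULL, sample_ids = NULL) {
  if (is.data.frame(hypermutators))
    hypermutators <- hypermutators$sample_id[hypermutators$hypermutator]
  if (length(hypermutators) > 0 && is.null(hotspots))
    stop("hotspots must be supplied when any sample is a hypermutator")
  if (is.null(sample_ids)) sample_ids <- unique(variants$sample_id)
  altering <- c(truncatingClasses(), "missense", "inframe_indel")
  v <- variants[variants$consequence %in% altering & variants$gene != "", ,
                drop = FALSE]
  # gene-level recurrence: distinct samples with any protein-altering variant
  pairs <- unique(v[, c("sample_id", "gene")])
  recGenes <- names(which(table(pairs$gene) >= 2))
  v <- v[v$gene %in% recGenes, , drop = FALSE]
  trunc <- v$consequence %in% truncatingClasses()
  hyper <- v$sample_id %in% hypermutators
  inHot <- rep(FALSE, nrow(v))
  if (!is.null(hotspots) && nrow(hotspots) > 0 && nrow(v) > 0) {
    for (r in seq_len(nrow(hotspots))) {
      inHot <- inHot | (v$gene == hotspots$gene[r] &
                          !is.na(v$protein_pos) &
                          v$protein_pos >= hotspots$residue_start[r] &
                          v$protein_pos <= hotspots$residue_end[r])
    }
  }
  counts <- trunc | (!hyper) | inHot
  tab <- table(factor(v$sample_id[counts], levels = sample_ids))
  data.frame(sample_id = sample_ids,
             recurrent_mut_count = as.integer(tab),
             hypermutator = sample_ids %in% hypermutators,
             stringsAsFactors = FALSE)
}

#' Assemble per-sample burden points
#'
#' Joins the focal CNA burden and the recurrent mutation burden; only
#' samples present in \code{meta} are reported (samples without segments
#' have focal burden 0).
#'
#' @param classified Classified segments (all samples).
#' @param variants Somatic variant data.frame.
#' @param meta Sample metadata.
#' @param hypermutators Hypermutator sample ids or
#'   \code{\link{flagHypermutators}} result.
#' @param hotspots \code{\link{detectHotspots}} output.
#' @return data.frame sample_id, focal_cna_count, recurrent_mut_count,
#'   hypermutator.
#' @export
burdenPoints <- function(classified, variants, meta,
                         hypermutators = character(0), hotspots = NULL) {
  foc <- classified[classified$scope == "focal" &
                      classified$direction != "neutral", , drop = FALSE]
  fc <- table(factor(foc$sample_id, levels = meta$sample_id))
  rb <- recurrentBurden(variants, hypermutators, hotspots,
                        sample_ids = meta$sample_id)
  data.frame(sample_id = meta$sample_id,
             focal_cna_count = as.integer(fc),
             recurrent_mut_count = rb$recurrent_mut_count,
             hypermutator = rb$hypermutator,
             stringsAsFactors = FALSE)
}

#' 2-D density bins of the burden plane
#'
#' Counts samples over a regular rectangular grid covering the observed
#' range of (focal CNA burden, recurrent mutation burden). Rectangular
#' bins stand in for the hexagonal bins of density displays: the hexagon
#' geometry is presentation, not analysis. Bin totals conserve the number
#' of points.
#'
#' @param points \code{\link{burdenPoints}} output (>= 1 row).
#' @param n_bins_x,n_bins_y Grid resolution.
#' @return data.frame bin_x, bin_y, x_lo, x_hi, y_lo, y_hi, count
#'   (non-empty bins only).
#' @export
densityBins <- function(points, n_bins_x = 25L, n_bins_y = 25L) {
  if (nrow(points) == 0) stop("need at least one burden point")
  x <- points$focal_cna_count
  y <- points$recurrent_mut_count
  binOf <- function(v, k) {
    lo <- min(v); hi <- max(v)
    if (hi == lo) return(list(bin = rep(1L, length(v)),
                              breaks = c(lo - 0.5, hi + 0.5), k = 1L))
    b <- seq(lo, hi, length.out = k + 1)
    bin <- pmin(findInterval(v, b, rightmost.closed = TRUE), k)
    list(bin = bin, breaks = b, k = k)
  }
  bx <- binOf(x, n_bins_x); by <- binOf(y, n_bins_y)
  tab <- table(bx$bin, by$bin)
  idx <- which(tab > 0, arr.ind = TRUE)
  i <- as.integer(rownames(tab)[idx[, 1]])
  j <- as.integer(colnames(tab)[idx[, 2]])
  data.frame(bin_x = i, bin_y = j,
             x_lo = bx$breaks[i], x_hi = bx$breaks[i + 1],
             y_lo = by$breaks[j], y_hi = by$breaks[j + 1],
             count = as.integer(tab[idx]))
}
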