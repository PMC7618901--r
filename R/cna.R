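# Copy-number landscape: threshold classification, focal/broad partition,
# genome fraction altered, 1-Mb bin profiles, whole-chromosome calls,
# gene-level status and tumor-type clustering.

#' Classify copy-number segments
#'
#' Direction: gain iff log2 fold change >= \code{gain_threshold} (+0.32),
#' loss iff <= \code{loss_threshold} (-0.40), else neutral. Scope: focal
#' iff segment length <= \code{focal_max_mb} megabases (boundary
#' included), else broad.
#'
#' @param segments Segment data.frame (sample_id, chrom, start, end, log2fc).
#' @param gain_threshold Gain threshold on log2fc (default +0.32).
#' @param loss_threshold Loss threshold on log2fc (default -0.40).
#' @param focal_max_mb Focal/broad boundary in Mb (default 10; lengths
#'   exactly at the boundary are focal).
#' @return Input with added columns direction, scope, length_bases.
#' @export
classifySegments <- function(segments, gain_threshold = 0.32,
                             loss_threshold = -0.40, focal_max_mb = 10) {
  if (!(loss_threshold < 0 && 0 < gain_threshold))
    stop("thresholds must satisfy loss_threshold < 0 < gain_threshold")
  s <- segments
  s$direction <- ifelse(s$log2fc >= gain_threshold, "gain",
                        ifelse(s$log2fc <= loss_threshold, "loss", "neutral"))
  s$length_bases <- s$end - s$start + 1
  s$scope <- ifelse(s$length_bases <= focal_max_mb * 1e6, "focal", "broad")
  s
}

#' Genome fraction altered of one sample
#'
#' 100 x (deduplicated bases covered by gained or lost segments) / total
#' assayable genome length.
#'
#' @param classified Classified segments of one sample
#'   (\code{\link{classifySegments}} output).
#' @param layout A \linkS4class{GenomeLayout}.
#' @return Percent in [0, 100].
#' @export
genomeFractionAltered <- function(classified, layout) {
  alt <- classified[classified$direction != "neutral", , drop = FALSE]
  if (nrow(alt) == 0) return(0)
  gr <- GenomicRanges::GRanges(alt$chrom, IRanges::IRanges(alt$start, alt$end))
  100 * sum(GenomicRanges::width(GenomicRanges::reduce(gr))) /
    assayableLength(layout)
}

#' Per-sample genome fraction altered for a cohort
#'
#' @param classified Classified segments (all samples).
#' @param meta Sample metadata.
#' @param layout A \linkS4class{GenomeLayout}.
#' @return data.frame sample_id, tumor_type, gfa_percent.
#' @export
cohortGfa <- function(classified, meta, layout) {
  gfa <- vapply(meta$sample_id, function(s)
    genomeFractionAltered(classified[classified$sample_id == s, , drop = FALSE],
                          layout), numeric(1))
  data.frame(sample_id = meta$sample_id, tumor_type = meta$tumor_type,
             gfa_percent = unname(gfa), stringsAsFactors = FALSE)
}

# Length-weighted mean log2fc of segments over target windows; samples
# absent contribute nothing. Returns a samples x windows matrix of means
# (NA where no overlap).
.weightedMeanByWindow <- function(segments, windows, sample_ids) {
  segGr <- GenomicRanges::GRanges(segments$chrom,
                                  IRanges::IRanges(segments$start, segments$end))
  ov <- GenomicRanges::findOverlaps(segGr, windows, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov); wi <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(GenomicRanges::pintersect(segGr[qi], windows[wi]))
  si <- match(segments$sample_id[qi], sample_ids)
  key <- (si - 1) * length(windows) + wi
  num <- rowsum(w * segments$log2fc[qi], key)
  den <- rowsum(w, key)
  m <- matrix(NA_real_, nrow = length(sample_ids), ncol = length(windows),
              dimnames = list(sample_ids, NULL))
  keys <- as.numeric(rownames(num))
  m[cbind(((keys - 1) %/% length(windows)) + 1,
          ((keys - 1) %% length(windows)) + 1)] <- num / den
  m
}

#' 1-Mb bin gain/loss profiles per tumor type
#'
#' Tiles the genome into fixed-size bins; a sample contributes gain
#' (resp. loss) to a bin iff the length-weighted mean log2fc of its
#' segments overlapping the bin reaches the gain (resp. loss) threshold.
#' Fractions are proportions of each tumor type's samples, so every bin
#' fraction is a rational with the per-type cohort size as denominator.
#' With \code{any_overlap = TRUE}, a bin counts as gained/lost when any
#' overlapping classified segment has that direction (legacy behavior; the
#' weighted mean prevents a 1-bp overlap from flagging a 1-Mb bin).
#'
#' @param classified Classified segments (all samples).
#' @param meta Sample metadata (defines per-type denominators).
#' @param layout A \linkS4class{GenomeLayout}.
#' @param bin_size Bin width in bases (default 1e6).
#' @param gain_threshold,loss_threshold Thresholds on the per-bin weighted
#'   mean log2fc.
#' @param any_overlap Use any-overlap instead of the weighted mean.
#' @return data.frame tumor_type, chrom, start, end, gain_fraction,
#'   loss_fraction, net.
#' @export
binProfiles <- function(classified, meta, layout, bin_size = 1e6,
                        gain_threshold = 0.32, loss_threshold = -0.40,
                        any_overlap = FALSE) {
  cl <- chromLengths(layout)
  tiles <- GenomicRanges::tileGenome(cl, tilewidth = bin_size,
                                     cut.last.tile.in.chrom = TRUE)
  base <- data.frame(chrom = as.character(GenomicRanges::seqnames(tiles)),
                     start = GenomicRanges::start(tiles),
                     end = GenomicRanges::end(tiles))
  out <- list()
  for (tt in unique(meta$tumor_type)) {
    sids <- meta$sample_id[meta$tumor_type == tt]
    segs <- classified[classified$sample_id %in% sids, , drop = FALSE]
    gm <- matrix(0, nrow = length(sids), ncol = length(tiles))
    lm <- matrix(0, nrow = length(sids), ncol = length(tiles))
    if (nrow(segs) > 0) {
      if (any_overlap) {
        for (dir in c("gain", "loss")) {
          sd <- segs[segs$direction == dir, , drop = FALSE]
          if (nrow(sd) == 0) next
          gr <- GenomicRanges::GRanges(sd$chrom,
                                       IRanges::IRanges(sd$start, sd$end))
          ov <- GenomicRanges::findOverlaps(gr, tiles)
          si <- match(sd$sample_id[S4Vectors::queryHits(ov)], sids)
          idx <- cbind(si, S4Vectors::subjectHits(ov))
          if (dir == "gain") gm[idx] <- 1 else lm[idx] <- 1
        }
      } else {
        wm <- .weightedMeanByWindow(segs, tiles, sids)
        gm[] <- !is.na(wm) & wm >= gain_threshold
        lm[] <- !is.na(wm) & wm <= loss_threshold
      }
    }
    df <- base
    df$tumor_type <- tt
    df$gain_fraction <- colSums(gm) / length(sids)
    df$loss_fraction <- colSums(lm) / length(sids)
    df$net <- df$gain_fraction - df$loss_fraction
    out[[tt]] <- df[, c("tumor_type", "chrom", "start", "end",
                        "gain_fraction", "loss_fraction", "net")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Whole-chromosome gain/loss calls
#'
#' A chromosome is called gained (lost) for a sample iff its gained (lost)
#' segments cover at least \code{coverage_min} of the chromosome length.
#'
#' @param classified Classified segments (all samples).
#' @param layout A \linkS4class{GenomeLayout}.
#' @param coverage_min Minimum covered fraction (default 0.8).
#' @return data.frame sample_id, chrom, call in \{gain, loss, none\}.
#' @export
chromosomeCalls <- function(classified, layout, coverage_min = 0.8) {
  cl <- chromLengths(layout)
  sids <- unique(classified$sample_id)
  out <- expand.grid(sample_id = sids, chrom = names(cl),
                     stringsAsFactors = FALSE)
  out$call <- "none"
  for (dir in c("gain", "loss")) {
    sd <- classified[classified$direction == dir, , drop = FALSE]
    if (nrow(sd) == 0) next
    cov <- stats::aggregate(
      width ~ sample_id + chrom,
      data = data.frame(sample_id = sd$sample_id, chrom = sd$chrom,
                        width = sd$end - sd$start + 1),
      FUN = sum)
    cov$frac <- cov$width / cl[cov$chrom]
    hit <- cov[cov$frac >= coverage_min, , drop = FALSE]
    if (nrow(hit) > 0) {
      i <- match(paste(hit$sample_id, hit$chrom),
                 paste(out$sample_id, out$chrom))
      out$call[i] <- dir
    }
  }
  out
}

#' Gene-level copy-number status
#'
#' Status per sample and gene from the length-weighted mean log2fc over
#' the gene's CDS span, using the same thresholds as segment
#' classification. Genes without coordinates are skipped with a warning.
#'
#' @param classified Classified segments (all samples).
#' @param panel A \linkS4class{GenePanel} (or a gene-model data.frame with
#'   gene, chrom, cds_start, cds_end).
#' @param sample_ids Samples to report (default: all in \code{classified}).
#' @param gain_threshold,loss_threshold Classification thresholds.
#' @return data.frame sample_id, gene, status in \{gain, loss, neutral\}.
#' @export
geneCnStatus <- function(classified, panel, sample_ids = NULL,
                         gain_threshold = 0.32, loss_threshold = -0.40) {
  g <- if (is(panel, "GenePanel")) geneModels(panel) else panel
  ok <- !is.na(g$chrom) & !is.na(g$cds_start) & !is.na(g$cds_end)
  if (any(!ok)) {
    warning(sum(!ok), " gene(s) without coordinates skipped")
    g <- g[ok, , drop = FALSE]
  }
  if (is.null(sample_ids)) sample_ids <- unique(classified$sample_id)
  windows <- GenomicRanges::GRanges(g$chrom,
                                    IRanges::IRanges(g$cds_start, g$cds_end))
  wm <- .weightedMeanByWindow(classified, windows, sample_ids)
  status <- matrix("neutral", nrow = nrow(wm), ncol = ncol(wm))
  status[!is.na(wm) & wm >= gain_threshold] <- "gain"
  status[!is.na(wm) & wm <= loss_threshold] <- "loss"
  data.frame(sample_id = rep(sample_ids, times = nrow(g)),
             gene = rep(g$gene, each = length(sample_ids)),
             status = as.vector(status), stringsAsFactors = FALSE)
}

#' Cluster tumor types on their net bin profiles
#'
#' Agglomerative clustering of per-type net (gain minus loss) bin vectors
#' with Euclidean distance and average linkage, as used for copy-number
#' landscape dendrograms. \code{stats::hclust} resolves distance ties by
#' lowest merge index, making the tree deterministic; the input order is
#' canonicalized (types sorted) so the topology does not depend on profile
#' order.
#'
#' @param profiles \code{\link{binProfiles}} output (>= 2 tumor types).
#' @return An \code{hclust} object (convert with \code{ape::as.phylo};
#'   write Newick with \code{\link{writeDendrogram}}).
#' @export
clusterTumorTypes <- function(profiles) {
  types <- sort(unique(profiles$tumor_type))
  if (length(types) < 2) stop("need at least 2 profiles to cluster")
  m <- do.call(rbind, lapply(types, function(tt) {
    p <- profiles[profiles$tumor_type == tt, , drop = FALSE]
    p <- p[order(p$chrom, p$start), , drop = FALSE]
    p$net
  }))
  rownames(m) <- types
  stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
}

#' Write a dendrogram as Newick
#'
#' @param hc An \code{hclust} object.
#' @param path Output path.
#' @export
writeDendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
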