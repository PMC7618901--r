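# Readers/writers for the external table formats: MAF-like variant TSV,
# SEG-style copy-number TSV, BED panel definitions, and cohort metadata.
# Internal coordinates are 1-based inclusive everywhere; BED (0-based
# half-open) is converted at the boundary.

.VARIANT_COLS <- c("sample_id", "chrom", "pos", "ref", "alt", "variant_class",
                   "gene", "consequence", "protein_pos", "aa_ref", "aa_alt",
                   "compartment")

# Infer SNV/MNV/INS/DEL from allele lengths.
inferVariantClass <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  out <- character(length(ref))
  out[lr == 1 & la == 1] <- "SNV"
  out[lr > 1 & la == lr] <- "MNV"
  out[la > lr] <- "INS"
  out[la < lr] <- "DEL"
  out
}

#' Read a MAF-like variant table
#'
#' Reads a tab-separated variant table with a header naming at least
#' \code{sample_id} (or \code{sample}), \code{chrom}, \code{pos},
#' \code{ref}, \code{alt} and \code{consequence}. Optional columns
#' \code{variant_class}, \code{gene}, \code{protein_pos}, \code{aa_ref},
#' \code{aa_alt}, \code{compartment} are carried through;
#' \code{variant_class} is inferred from allele lengths when absent.
#' Consequence strings are canonicalized through the documented alias table
#' (\code{\link{consequenceAliases}}); unknown strings are rejected.
#'
#' @param path Path to the TSV file.
#' @param compartment Default compartment ("somatic" or "germline") for
#'   rows without a compartment column.
#' @return data.frame of variant records.
#' @export
readVariants <- function(path, compartment = "somatic") {
  df <- readTsv(path, colClasses = "character")
  names(df)[names(df) == "sample"] <- "sample_id"
  need <- c("sample_id", "chrom", "pos", "ref", "alt", "consequence")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("variant file missing mandatory column(s): ", paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.numeric(df$pos))
  bad <- which(is.na(pos) | pos != floor(pos) | pos < 1)
  if (length(bad) > 0)
    stop("non-integer pos at line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for header line
  df$pos <- pos
  if (any(df$ref == df$alt)) stop("ref must differ from alt")
  if (!"variant_class" %in% names(df) || all(is.na(df$variant_class)))
    df$variant_class <- inferVariantClass(df$ref, df$alt)
  df$consequence <- normalizeConsequence(df$consequence)
  if (!"gene" %in% names(df)) df$gene <- ""
  if (!"protein_pos" %in% names(df)) df$protein_pos <- NA
  df$protein_pos <- suppressWarnings(as.integer(df$protein_pos))
  if (!"aa_ref" %in% names(df)) df$aa_ref <- NA_character_
  if (!"aa_alt" %in% names(df)) df$aa_alt <- NA_character_
  if (!"compartment" %in% names(df)) df$compartment <- compartment
  df$gene[is.na(df$gene)] <- ""
  df[, .VARIANT_COLS]
}

#' Write a variant table
#'
#' Writes the canonical MAF-like TSV (UTF-8, tab-separated, header,
#' deterministic column order). \code{readVariants(writeVariants(x))}
#' round-trips all fields.
#'
#' @param variants Variant data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeVariants <- function(variants, path) {
  writeTsv(variants[, .VARIANT_COLS], path)
}

#' Read a SEG-style copy-number segment table
#'
#' Columns \code{sample_id} (or \code{sample}), \code{chrom}, \code{start},
#' \code{end}, \code{log2fc} (1-based inclusive). Segments are clipped to
#' chromosome bounds from \code{layout}; segments empty after clipping are
#' dropped with a warning. Overlap between two segments of one sample on
#' one chromosome is a validation error listing both.
#'
#' @param path Path to the TSV file.
#' @param layout A \linkS4class{GenomeLayout}.
#' @return data.frame of segments.
#' @export
readSegments <- function(path, layout) {
  df <- readTsv(path)
  names(df)[names(df) == "sample"] <- "sample_id"
  need <- c("sample_id", "chrom", "start", "end", "log2fc")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("segment file missing mandatory column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  validateSegments(df, layout)
}

#' Validate, clip and order a segment table against a genome layout
#'
#' @param df Segment data.frame (sample_id, chrom, start, end, log2fc).
#' @param layout A \linkS4class{GenomeLayout}.
#' @return The clipped, validated data.frame.
#' @export
validateSegments <- function(df, layout) {
  if (nrow(df) == 0) return(df)
  if (any(df$start > df$end)) stop("segment start > end")
  cl <- chromLengths(layout)
  unknown <- setdiff(unique(df$chrom), names(cl))
  if (length(unknown) > 0)
    stop("segment chromosome(s) not in layout: ", paste(unknown, collapse = ", "))
  maxlen <- cl[df$chrom]
  df$start <- pmax(df$start, 1)
  over <- df$start > maxlen
  df$end <- pmin(df$end, maxlen)
  if (any(over)) {
    warning(sum(over), " segment(s) empty after clipping to chromosome bounds; dropped")
    df <- df[!over, , drop = FALSE]
  }
  # per-sample, per-chromosome overlap check
  o <- order(df$sample_id, df$chrom, df$start)
  d <- df[o, ]
  same <- d$sample_id[-1] == d$sample_id[-nrow(d)] &
    d$chrom[-1] == d$chrom[-nrow(d)]
  ovl <- which(same & d$start[-1] <= d$end[-nrow(d)])
  if (length(ovl) > 0) {
    i <- ovl[1]
    stop(sprintf("overlapping segments for sample %s on %s: [%d,%d] and [%d,%d]",
                 d$sample_id[i], d$chrom[i],
                 as.integer(d$start[i]), as.integer(d$end[i]),
                 as.integer(d$start[i + 1]), as.integer(d$end[i + 1])))
  }
  rownames(d) <- NULL
  d
}

#' Write a segment table
#' @param segments Segment data.frame.
#' @param path Output path.
#' @export
writeSegments <- function(segments, path) {
  writeTsv(segments[, c("sample_id", "chrom", "start", "end", "log2fc")], path)
}

#' Read a panel BED file
#'
#' BED input is 0-based half-open; regions are converted to the internal
#' 1-based inclusive convention and returned as a \code{GRanges} with a
#' \code{gene} metadata column.
#'
#' @param path Path to the BED file (chrom, start, end, gene).
#' @return \code{GRanges} of panel regions.
#' @export
readPanelBed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "gene")[1:4])
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges(gene = character(0)))
  }
  bad <- which(df$start >= df$end)
  if (length(bad) > 0)
    stop("BED start >= end at row(s): ", paste(bad, collapse = ", "))
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  S4Vectors::mcols(gr)$gene <- df$gene
  gr
}

#' Write panel regions as BED
#'
#' Inverse of \code{\link{readPanelBed}} (back to 0-based half-open).
#' @param regions \code{GRanges} with a \code{gene} metadata column.
#' @param path Output path.
#' @export
writePanelBed <- function(regions, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                   start = GenomicRanges::start(regions) - 1L,
                   end = GenomicRanges::end(regions),
                   gene = S4Vectors::mcols(regions)$gene)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Deduplicated base footprint of panel regions
#'
#' Overlapping regions are unioned before counting bases, so the footprint
#' is invariant under region order and under splitting a region in two.
#'
#' @param regions \code{GRanges} of panel regions.
#' @param by_gene If TRUE, return a named vector of per-gene footprints
#'   (deduplicated within gene).
#' @return Total base count, or a named vector per gene.
#' @export
regionFootprint <- function(regions, by_gene = FALSE) {
  if (length(regions) == 0) {
    if (by_gene) return(stats::setNames(numeric(0), character(0)))
    return(0)
  }
  if (!by_gene)
    return(sum(GenomicRanges::width(GenomicRanges::reduce(regions))))
  genes <- S4Vectors::mcols(regions)$gene
  vapply(split(regions, genes), function(g)
    sum(GenomicRanges::width(GenomicRanges::reduce(g))), numeric(1))
}

#' Cohort demographic summary
#'
#' Counts by tumor type, sex and breed, plus the age quartiles of the
#' cohort — the standard demographic overview of a pan-cancer study group.
#'
#' @param meta Sample metadata data.frame.
#' @return List with data.frames \code{tumor_type}, \code{sex},
#'   \code{breed} (count + integer percent under the cohort percent
#'   convention) and \code{age} (quartiles).
#' @export
cohortSummary <- function(meta) {
  countTab <- function(x) {
    if (length(x) == 0)
      return(data.frame(level = character(0), n = integer(0),
                        percent = integer(0)))
    t <- table(x)
    data.frame(level = names(t), n = as.integer(t),
               percent = roundPercent(as.integer(t), length(x)),
               row.names = NULL)
  }
  age <- if (nrow(meta) == 0) {
    data.frame(stat = character(0), value = numeric(0))
  } else {
    q <- stats::quantile(meta$age_years, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE)
    data.frame(stat = c("min", "q1", "median", "q3", "max"),
               value = unname(q))
  }
  list(tumor_type = countTab(meta$tumor_type),
       sex = countTab(meta$sex),
       breed = countTab(meta$breed),
       age = age)
}
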