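# Central S4 containers: genome layout, gene panel, cohort, signature
# catalog and viral k-mer index.

#' @import methods
#' @importClassesFrom Biostrings AAStringSet DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

setClassUnion("df_OR_NULL", c("data.frame", "NULL"))

## ---- GenomeLayout ---------------------------------------------------------

#' Genome layout: ordered chromosomes with lengths
#'
#' Minimal description of the assayable genome: an ordered set of
#' chromosome names with lengths in bases. Used for coordinate clipping,
#' 1-Mb binning, whole-chromosome calls and the genome-fraction-altered
#' denominator.
#'
#' @slot chrom Character vector of unique chromosome names (ordered).
#' @slot lengths Numeric vector of positive chromosome lengths (bases).
#' @export
setClass("GenomeLayout",
         representation(chrom = "character", lengths = "numeric"))

setValidity("GenomeLayout", function(object) {
  if (length(object@chrom) != length(object@lengths))
    return("chrom and lengths must have equal length")
  if (anyDuplicated(object@chrom)) return("chromosome names must be unique")
  if (any(object@lengths <= 0)) return("chromosome lengths must be positive")
  TRUE
})

#' Construct a GenomeLayout
#'
#' @param chrom Character vector of chromosome names.
#' @param lengths Numeric vector of chromosome lengths in bases.
#' @return A \linkS4class{GenomeLayout}.
#' @export
GenomeLayout <- function(chrom, lengths) {
  new("GenomeLayout", chrom = as.character(chrom), lengths = as.numeric(lengths))
}

#' @describeIn GenomeLayout-class Named vector of chromosome lengths.
#' @param x,object A \code{GenomeLayout}.
#' @export
chromLengths <- function(x) stats::setNames(x@lengths, x@chrom)

#' @describeIn GenomeLayout-class Total assayable genome length in bases.
#' @export
assayableLength <- function(x) sum(x@lengths)

setMethod("show", "GenomeLayout", function(object) {
  cat("GenomeLayout:", length(object@chrom), "chromosomes,",
      sprintf("%.1f Mb total\n", sum(object@lengths) / 1e6))
})

## ---- GenePanel ------------------------------------------------------------

#' Targeted gene panel with gene models and sequence
#'
#' Holds the gene models of a targeted sequencing panel: per-gene CDS
#' coordinates (single ordered interval per gene here), strand, protein
#' sequences for cat and (where an ortholog exists) human, the targeted
#' regions as a \code{GRanges}, and the coding-strand nucleotide sequence of
#' each targeted region (CDS plus a short flank), which serves as the
#' reference sequence source for trinucleotide context lookups.
#'
#' @slot genes data.frame with columns gene, chrom, strand, cds_start,
#'   cds_end, protein_length, human_ortholog (empty string when none).
#' @slot catProteins \code{AAStringSet} named by gene.
#' @slot humanProteins \code{AAStringSet} named by gene (subset with orthologs).
#' @slot regions \code{GRanges} of targeted regions (1-based inclusive),
#'   with metadata column \code{gene}.
#' @slot regionSeqs \code{DNAStringSet} named by gene: coding-strand
#'   sequence of flank + CDS + flank.
#' @slot flank Integer flank width included around each CDS.
#' @slot layout \linkS4class{GenomeLayout}.
#' @export
setClass("GenePanel",
         representation(genes = "data.frame",
                        catProteins = "AAStringSet",
                        humanProteins = "AAStringSet",
                        regions = "GRanges",
                        regionSeqs = "DNAStringSet",
                        flank = "integer",
                        layout = "GenomeLayout"))

setValidity("GenePanel", function(object) {
  g <- object@genes
  need <- c("gene", "chrom", "strand", "cds_start", "cds_end",
            "protein_length", "human_ortholog")
  if (!all(need %in% names(g))) return("genes table missing required columns")
  if (anyDuplicated(g$gene)) return("gene names must be unique")
  if (!all(g$strand %in% c("+", "-"))) return("strand must be + or -")
  pl <- Biostrings::width(object@catProteins)[match(g$gene, names(object@catProteins))]
  if (any(pl != g$protein_length))
    return("protein_length must equal length of cat protein sequence")
  cdslen <- g$cds_end - g$cds_start + 1
  if (any((cdslen %% 3) != 0)) return("CDS length must be divisible by 3")
  TRUE
})

setMethod("show", "GenePanel", function(object) {
  cat("GenePanel:", nrow(object@genes), "genes,",
      sprintf("%.2f Mb footprint\n", panelFootprint(object) / 1e6))
})

#' @describeIn GenePanel-class Gene model table.
#' @param x A \code{GenePanel}.
#' @export
geneModels <- function(x) x@genes

#' @describeIn GenePanel-class Targeted regions as a \code{GRanges}.
#' @export
panelRegions <- function(x) x@regions

#' @describeIn GenePanel-class Cat protein sequences (\code{AAStringSet}).
#' @export
catProteins <- function(x) x@catProteins

#' @describeIn GenePanel-class Human ortholog protein sequences.
#' @export
humanProteins <- function(x) x@humanProteins

#' @describeIn GenePanel-class Genome layout the panel is placed on.
#' @export
panelLayout <- function(x) x@layout

## ---- CancerCohort ---------------------------------------------------------

#' A tumor-normal cohort: metadata, variants, copy-number segments, reads
#'
#' The central data object of the pipeline. Variant tables are MAF-like
#' data.frames with columns sample_id, chrom, pos, ref, alt, variant_class,
#' gene, consequence, protein_pos, aa_ref, aa_alt, compartment. Segments
#' carry sample_id, chrom, start, end, log2fc. Off-target reads are a named
#' list (sample_id -> character vector of read sequences). When produced by
#' the synthetic generator, \code{truth} holds the planted ground-truth
#' event tables.
#'
#' @slot meta data.frame: sample_id, tumor_type, subtype, age_years, sex, breed.
#' @slot somatic data.frame of somatic variants.
#' @slot germline data.frame of germline variants.
#' @slot segments data.frame of copy-number segments.
#' @slot reads Named list of off-target read sequence vectors.
#' @slot truth List of planted-event tables (empty for real cohorts).
#' @export
setClass("CancerCohort",
         representation(meta = "data.frame",
                        somatic = "data.frame",
                        germline = "data.frame",
                        segments = "data.frame",
                        reads = "list",
                        truth = "list"))

setValidity("CancerCohort", function(object) {
  m <- object@meta
  if (nrow(m) > 0) {
    if (anyDuplicated(m$sample_id)) return("sample_id must be unique")
    if (!all(m$tumor_type %in% tumorTypes()))
      return("tumor_type must be one of the 13 cohort codes")
    if (!all(m$sex %in% c("F", "M", "U"))) return("sex must be F, M or U")
    if (any(m$age_years < 0, na.rm = TRUE)) return("age_years must be >= 0")
  }
  for (sl in c("somatic", "germline")) {
    v <- slot(object, sl)
    if (nrow(v) > 0 && !all(v$sample_id %in% m$sample_id))
      return(paste(sl, "variants reference unknown sample_id"))
  }
  TRUE
})

setMethod("show", "CancerCohort", function(object) {
  cat("CancerCohort:", nrow(object@meta), "samples,",
      length(unique(object@meta$tumor_type)), "tumor types\n")
  cat("  somatic variants:", nrow(object@somatic),
      "| germline variants:", nrow(object@germline),
      "| CN segments:", nrow(object@segments), "\n")
})

#' @describeIn CancerCohort-class Sample metadata table.
#' @param x A \code{CancerCohort}.
#' @export
sampleMeta <- function(x) x@meta

#' @describeIn CancerCohort-class Somatic variant table.
#' @export
somaticVariants <- function(x) x@somatic

#' @describeIn CancerCohort-class Germline variant table.
#' @export
germlineVariants <- function(x) x@germline

#' @describeIn CancerCohort-class Copy-number segment table.
#' @export
cnSegments <- function(x) x@segments

#' @describeIn CancerCohort-class Off-target reads per sample.
#' @export
offTargetReads <- function(x) x@reads

#' @describeIn CancerCohort-class Planted ground-truth tables (synthetic cohorts).
#' @export
cohortTruth <- function(x) x@truth

## ---- SignatureCatalog -----------------------------------------------------

#' Reference mutational-signature catalog (96-channel)
#'
#' @slot profiles Numeric matrix 96 x K; each column a signature profile
#'   summing to 1; rownames are the standard channel labels.
#' @export
setClass("SignatureCatalog", representation(profiles = "matrix"))

setValidity("SignatureCatalog", function(object) {
  p <- object@profiles
  if (nrow(p) != 96) return("profiles must have 96 rows")
  if (is.null(colnames(p))) return("profiles must have signature names")
  if (any(p < 0)) return("profile entries must be non-negative")
  if (any(abs(colSums(p) - 1) > 1e-6)) return("each column must sum to 1")
  TRUE
})

#' Construct a SignatureCatalog
#'
#' @param profiles 96 x K non-negative matrix with named columns; columns
#'   are normalized to sum to 1.
#' @return A \linkS4class{SignatureCatalog}.
#' @export
SignatureCatalog <- function(profiles) {
  profiles <- as.matrix(profiles)
  profiles <- sweep(profiles, 2, colSums(profiles), "/")
  rownames(profiles) <- channelLabels()
  new("SignatureCatalog", profiles = profiles)
}

#' @describeIn SignatureCatalog-class Signature names.
#' @param x,object A \code{SignatureCatalog}.
#' @export
signatureNames <- function(x) colnames(x@profiles)

#' @describeIn SignatureCatalog-class The 96 x K profile matrix.
#' @export
signatureProfiles <- function(x) x@profiles

setMethod("show", "SignatureCatalog", function(object) {
  cat("SignatureCatalog:", ncol(object@profiles), "signatures:",
      paste(colnames(object@profiles), collapse = ", "), "\n")
})

## ---- ViralIndex -----------------------------------------------------------

#' Canonical k-mer index over viral reference genomes
#'
#' Per-virus sets of canonical k-mers (lexicographically smaller of a k-mer
#' and its reverse complement), with any k-mer present in the exclusion
#' references (e.g. FIV/FeLV) removed.
#'
#' @slot k Odd integer k-mer size.
#' @slot sets Named list of character vectors (canonical k-mers per virus).
#' @slot n_excluded Integer count of k-mers removed by the exclusion set.
#' @export
setClass("ViralIndex",
         representation(k = "integer", sets = "list", n_excluded = "integer"))

setValidity("ViralIndex", function(object) {
  if (object@k < 15L) return("k must be >= 15")
  if (object@k %% 2L == 0L) return("k must be odd")
  TRUE
})

setMethod("show", "ViralIndex", function(object) {
  cat("ViralIndex: k =", object@k, "|",
      length(object@sets), "viruses:",
      paste(sprintf("%s (%d kmers)", names(object@sets),
                    vapply(object@sets, length, 1L)), collapse = ", "), "\n")
})
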