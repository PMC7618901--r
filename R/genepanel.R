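# GenePanel construction (user-supplied or synthetic), per-site codon
# classification, 96-channel mutational-opportunity tables, and
# trinucleotide context extraction used by the signatures module.

.CODON_STR <- local({
  out <- character(64)
  k <- 0L
  for (b1 in 1:4) for (b2 in 1:4) for (b3 in 1:4) {
    k <- k + 1L
    out[k] <- paste0(.BASES[b1], .BASES[b2], .BASES[b3])
  }
  out
})

.STOP_CODONS <- which(.AA_BY_CODON == "*")

#' Construct a GenePanel
#'
#' @param genes data.frame with columns gene, chrom, strand, cds_start,
#'   cds_end, protein_length, human_ortholog.
#' @param catProteins \code{AAStringSet} of cat protein sequences named by gene.
#' @param humanProteins \code{AAStringSet} of human ortholog proteins named
#'   by (cat) gene; genes without ortholog are absent.
#' @param regionSeqs \code{DNAStringSet} named by gene holding the
#'   coding-strand sequence of flank + CDS + flank.
#' @param flank Integer flank width around each CDS.
#' @param layout \linkS4class{GenomeLayout}.
#' @return A \linkS4class{GenePanel}.
#' @export
GenePanel <- function(genes, catProteins, humanProteins, regionSeqs,
                      flank, layout) {
  rs <- genes$cds_start - flank
  re <- genes$cds_end + flank
  regions <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(rs, re),
                                    strand = genes$strand)
  S4Vectors::mcols(regions)$gene <- genes$gene
  obj <- new("GenePanel", genes = genes, catProteins = catProteins,
             humanProteins = humanProteins, regions = regions,
             regionSeqs = regionSeqs, flank = as.integer(flank),
             layout = layout)
  obj
}

#' Read a gene panel from a gene-model table and protein/region FASTAs
#'
#' @param gene_table_path TSV with the gene-model columns (see
#'   \code{\link{GenePanel}}).
#' @param cat_fasta_path FASTA of cat protein sequences named by gene.
#' @param region_fasta_path FASTA of coding-strand region sequences
#'   (flank + CDS + flank) named by gene.
#' @param layout \linkS4class{GenomeLayout}.
#' @param human_fasta_path Optional FASTA of human ortholog proteins named
#'   by cat gene.
#' @param flank Flank width used in the region sequences.
#' @return A \linkS4class{GenePanel}.
#' @export
readGenePanel <- function(gene_table_path, cat_fasta_path, region_fasta_path,
                          layout, human_fasta_path = NULL, flank = 10L) {
  genes <- readTsv(gene_table_path)
  cat_aa <- Biostrings::readAAStringSet(cat_fasta_path)
  names(cat_aa) <- sub("\\s.*$", "", names(cat_aa))
  hum_aa <- if (is.null(human_fasta_path)) Biostrings::AAStringSet() else {
    h <- Biostrings::readAAStringSet(human_fasta_path)
    names(h) <- sub("\\s.*$", "", names(h))
    h
  }
  seqs <- Biostrings::readDNAStringSet(region_fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  GenePanel(genes, cat_aa[genes$gene], hum_aa,
            seqs[genes$gene], flank, layout)
}

#' Total deduplicated panel footprint in bases
#'
#' @param panel A \linkS4class{GenePanel}.
#' @return Footprint in bases (deduplicated across overlapping regions).
#' @export
panelFootprint <- function(panel) {
  regionFootprint(panel@regions)
}

#' Panel footprint in megabases (TMB denominator)
#' @param panel A \linkS4class{GenePanel}.
#' @export
panelFootprintMb <- function(panel) panelFootprint(panel) / 1e6

## ---- synthetic layout and panel -------------------------------------------

#' Cat-like genome layout
#'
#' The 18 autosomes plus X of the domestic cat karyotype with approximate
#' assembly lengths (rounded to the Mb), totalling ~2.44 Gb.
#'
#' @return A \linkS4class{GenomeLayout}.
#' @export
syntheticLayout <- function() {
  GenomeLayout(
    chrom = c("A1", "A2", "A3", "B1", "B2", "B3", "B4", "C1", "C2",
              "D1", "D2", "D3", "D4", "E1", "E2", "E3", "F1", "F2", "X"),
    lengths = c(240, 169, 142, 206, 155, 149, 144, 222, 159,
                117, 90, 96, 96, 63, 64, 43, 71, 85, 131) * 1e6)
}

# Marquee genes: placed deliberately so that the default copy-number
# templates and driver/hotspot spike-ins land on them, with specific codons
# planted so that spiked protein changes carry realistic amino-acid labels
# (e.g. PIK3CA codon 1047 = His, CHEK2 codon 182 = Tyr).
.MARQUEE <- data.frame(
  gene   = c("TP53", "PIK3CA", "KIT", "FBXW7", "CTNNB1", "PTEN", "FAS",
             "CDKN2A", "MYC", "CHEK2", "BRIP1", "BRCA1", "BRCA2", "TRAF3",
             "APC", "MSH2", "NF1", "MAP2K1", "FGFR2", "MLH1", "PMS2",
             "ATM", "PALB2", "RAD51C", "NBN", "MUTYH"),
  chrom  = c("E1", "C2", "B1", "B1", "C2", "D2", "D2",
             "D4", "F2", "B4", "E1", "E1", "A1", "B3",
             "B1", "A3", "E2", "B3", "D2", "C2", "A2",
             "D3", "E3", "E1", "D1", "C1"),
  pos_mb = c(8, 120, 60, 90, 40, 2, 5,
             10, 83, 50, 40, 20, 100, 30,
             30, 50, 10, 60, 40, 80, 30,
             60, 20, 55, 40, 70),
  protL  = c(393, 1068, 976, 707, 781, 403, 335,
             156, 439, 543, 1249, 1863, 3418, 568,
             2843, 934, 2839, 393, 821, 756, 862,
             3056, 1186, 376, 754, 546),
  stringsAsFactors = FALSE)

# Planted codons per marquee gene: residue index -> codon string.
.PLANTED <- list(
  TP53   = c("175" = "CGC", "248" = "CGG"),
  PIK3CA = c("1047" = "CAT", "545" = "GAA"),
  KIT    = c("816" = "GAC", "560" = "GTT"),
  FBXW7  = c("465" = "CGT", "505" = "CGC"),
  CTNNB1 = c("33" = "TCT", "37" = "TCT", "41" = "ACC", "45" = "TCT"),
  CHEK2  = c("182" = "TAC"),
  MAP2K1 = c("57" = "CAA"),
  FGFR2  = c("252" = "TCT"),
  PTEN   = c("130" = "CGA"),
  NF1    = c("440" = "CGA")
)

#' The 14 cancer-predisposition genes screened in the germline module
#'
#' Human cancer predisposition genes whose feline orthologs are on the
#' panel; the default gene list for \code{\link{screenGermline}}.
#' @return Character vector of 14 gene symbols.
#' @export
predispositionGenes <- function() {
  c("CHEK2", "BRIP1", "BRCA1", "BRCA2", "TP53", "PTEN", "MSH2",
    "MLH1", "PMS2", "ATM", "PALB2", "RAD51C", "NBN", "MUTYH")
}

# Sample a CDS as codon integers: ATG start, no internal stops, planted
# codons overwritten, terminal stop codon.
.sampleCDS <- function(protL, planted = NULL) {
  ok <- setdiff(1:64, .STOP_CODONS)
  cod <- c(15L,                                  # ATG
           sample(ok, protL - 1L, replace = TRUE),
           sample(.STOP_CODONS, 1L))
  if (!is.null(planted)) {
    idx <- as.integer(names(planted))
    cod[idx] <- match(planted, .CODON_STR)
  }
  cod
}

#' Generate a synthetic targeted gene panel
#'
#' Builds a panel of single-exon gene models placed on a cat-like genome
#' layout: random coding sequences (ATG start, no internal stop, terminal
#' stop), cat proteins as their translations, and human ortholog proteins
#' derived from the cat proteins by random substitution at a configurable
#' divergence. A set of marquee cancer genes (TP53, PIK3CA, KIT, FBXW7,
#' CTNNB1, PTEN, FAS, CDKN2A, MYC, CHEK2, ...) is placed at fixed loci with
#' specific codons planted so spike-in protein changes carry their familiar
#' labels; remaining genes are fillers with synthetic names.
#'
#' @param n_genes Total number of genes (default 978, the panel size of a
#'   targeted feline pan-cancer design).
#' @param seed Integer seed; fixed seed gives a byte-identical panel.
#' @param layout \linkS4class{GenomeLayout} (default \code{syntheticLayout()}).
#' @param flank Flank width (bases) around each CDS in the targeted regions.
#' @param divergence Fraction of residues substituted in the human ortholog.
#' @param orphan_fraction Fraction of filler genes without a human ortholog.
#' @param mean_protL Mean filler protein length (residues); lengths are
#'   uniform between 0.5x and 1.5x this value.
#' @return A \linkS4class{GenePanel}.
#' @export
syntheticGenePanel <- function(n_genes = 978L, seed = 1L,
                               layout = syntheticLayout(), flank = 10L,
                               divergence = 0.05, orphan_fraction = 0.03,
                               mean_protL = 700L) {
  stopifnot(n_genes >= nrow(.MARQUEE))
  set.seed(substreamSeed(seed, "genepanel"))
  n_fill <- n_genes - nrow(.MARQUEE)
  cl <- chromLengths(layout)

  fill <- data.frame(
    gene = sprintf("FCG%04d", seq_len(n_fill)),
    chrom = sample(names(cl), n_fill, replace = TRUE, prob = cl),
    pos_mb = NA_real_,
    protL = as.integer(round(stats::runif(n_fill, 0.5 * mean_protL,
                                          1.5 * mean_protL))),
    stringsAsFactors = FALSE)
  fill$pos_mb <- stats::runif(n_fill, 1, cl[fill$chrom] / 1e6 - 2)

  g <- rbind(.MARQUEE, fill)
  g$strand <- sample(c("+", "-"), nrow(g), replace = TRUE)
  g$cds_len <- (g$protL + 1L) * 3L
  g$cds_start <- round(g$pos_mb * 1e6)
  # resolve same-chromosome collisions by pushing genes apart
  for (ch in unique(g$chrom)) {
    i <- which(g$chrom == ch)
    i <- i[order(g$cds_start[i])]
    for (k in seq_along(i)[-1]) {
      lo <- g$cds_start[i[k - 1]] + g$cds_len[i[k - 1]] + 2L * flank + 1000L
      if (g$cds_start[i[k]] < lo) g$cds_start[i[k]] <- lo
    }
  }
  g$cds_end <- g$cds_start + g$cds_len - 1L
  g$human_ortholog <- g$gene
  orphan <- g$gene %in% sample(fill$gene, round(orphan_fraction * n_fill))
  g$human_ortholog[orphan] <- ""
  g$protein_length <- g$protL

  codons <- lapply(seq_len(nrow(g)), function(i) {
    .sampleCDS(g$protL[i], .PLANTED[[g$gene[i]]])
  })
  catP <- vapply(codons, function(cd)
    paste(.AA_BY_CODON[cd[-length(cd)]], collapse = ""), character(1))
  regionSeqs <- vapply(seq_len(nrow(g)), function(i) {
    paste0(paste(sample(.BASES, flank, replace = TRUE), collapse = ""),
           paste(.CODON_STR[codons[[i]]], collapse = ""),
           paste(sample(.BASES, flank, replace = TRUE), collapse = ""))
  }, character(1))

  aa20 <- setdiff(unique(.AA_BY_CODON), "*")
  humP <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    if (g$human_ortholog[i] == "") { humP[i] <- NA_character_; next }
    p <- strsplit(catP[i], "")[[1]]
    guard <- as.integer(names(.PLANTED[[g$gene[i]]]))
    nmut <- stats::rbinom(1, length(p), divergence)
    cand <- setdiff(seq_along(p), guard)
    if (nmut > 0 && length(cand) > 0) {
      at <- sample(cand, min(nmut, length(cand)))
      p[at] <- vapply(p[at], function(a) sample(setdiff(aa20, a), 1), character(1))
    }
    humP[i] <- paste(p, collapse = "")
  }

  genes <- g[, c("gene", "chrom", "strand", "cds_start", "cds_end",
                 "protein_length", "human_ortholog")]
  rownames(genes) <- NULL
  catAA <- Biostrings::AAStringSet(stats::setNames(catP, g$gene))
  has_h <- !is.na(humP)
  humAA <- Biostrings::AAStringSet(stats::setNames(humP[has_h], g$gene[has_h]))
  seqs <- Biostrings::DNAStringSet(stats::setNames(regionSeqs, g$gene))
  GenePanel(genes, catAA, humAA, seqs, flank, layout)
}

## ---- per-site classification and opportunity ------------------------------

# Per-gene table of every (CDS position, alternate base) pair with its
# consequence class and 96-channel assignment, on the coding strand.
# class codes: 1 = synonymous, 2 = missense, 3 = truncating
# (nonsense / start-loss / nonstop).
geneSiteClasses <- function(panel, gene) {
  gi <- match(gene, panel@genes$gene)
  if (is.na(gi)) stop("gene not in panel: ", gene)
  grow <- panel@genes[gi, ]
  f <- panel@flank
  b <- encodeDNA(as.character(panel@regionSeqs[[gi]]))
  L3 <- grow$cds_end - grow$cds_start + 1L
  cpos <- seq_len(L3)
  i <- f + cpos
  bc <- b[i]
  cod0 <- (cpos - 1L) %/% 3L
  pic <- (cpos - 1L) %% 3L + 1L
  b1 <- bc[3L * cod0 + 1L]; b2 <- bc[3L * cod0 + 2L]; b3 <- bc[3L * cod0 + 3L]
  refCod <- (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3
  up <- b[i - 1L]; dn <- b[i + 1L]
  mult <- c(16L, 4L, 1L)[pic]
  nC <- grow$protein_length + 1L  # codon count incl. stop
  out <- vector("list", 3L)
  for (k in 1:3) {
    alt <- ((bc - 1L + k) %% 4L) + 1L     # the k-th other base, cyclic
    mutCod <- refCod + (alt - bc) * mult
    aaRef <- .AA_BY_CODON[refCod]
    aaMut <- .AA_BY_CODON[mutCod]
    cls <- ifelse(aaMut == aaRef, 1L, ifelse(aaMut == "*", 3L, 2L))
    cls[cod0 == 0L & aaMut != aaRef] <- 3L          # start-loss
    isStop <- cod0 == (nC - 1L)
    cls[isStop] <- ifelse(aaMut[isStop] == "*", 1L, 3L)
    csq <- character(L3)
    csq[cls == 1L] <- "synonymous"
    csq[cls == 2L] <- "missense"
    csq[cls == 3L] <- "nonsense"
    csq[cls == 3L & cod0 == 0L] <- "start_loss"
    csq[cls == 3L & isStop] <- "nonstop"
    out[[k]] <- data.frame(
      cpos = cpos, codon = cod0 + 1L, ref = bc, alt = alt,
      channel = channelIndex(up, bc, dn, alt),
      class = cls, consequence = csq,
      aa_ref = aaRef, aa_alt = aaMut, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (grow$strand == "+") {
    res$gpos <- grow$cds_start + res$cpos - 1L
  } else {
    res$gpos <- grow$cds_end - res$cpos + 1L
  }
  res$gref <- if (grow$strand == "+") .BASES[res$ref] else .BASES[5L - res$ref]
  res$galt <- if (grow$strand == "+") .BASES[res$alt] else .BASES[5L - res$alt]
  res
}

#' Mutational opportunity of every gene over the 96 channels
#'
#' For each gene, the count of (site, alternate base) pairs in each
#' substitution channel that would produce a synonymous, missense or
#' truncating (nonsense / start-loss / nonstop) change. This is the
#' context-aware opportunity table behind the driver-selection background
#' model. Cached on the panel after first computation.
#'
#' @param panel A \linkS4class{GenePanel}.
#' @return Numeric array gene x 96 x class with dimnames
#'   (gene, channel label, c("syn","mis","trunc")).
#' @export
panelOpportunity <- function(panel) {
  cache <- panelCache(panel)
  if (!is.null(cache$opportunity)) return(cache$opportunity)
  genes <- panel@genes$gene
  arr <- array(0, dim = c(length(genes), 96L, 3L),
               dimnames = list(genes, channelLabels(), c("syn", "mis", "trunc")))
  for (gi in seq_along(genes)) {
    sc <- geneSiteClasses(panel, genes[gi])
    t <- tabulate(sc$channel + 96L * (sc$class - 1L), nbins = 288L)
    arr[gi, , ] <- t
  }
  cache$opportunity <- arr
  arr
}

# Per-panel cache environment (reference semantics keyed by the panel's
# region sequences so equal panels share derived tables within a session).
.panelCaches <- new.env(parent = emptyenv())

panelCache <- function(panel) {
  key <- paste0(nrow(panel@genes), ":",
                sum(Biostrings::width(panel@regionSeqs)), ":",
                as.character(panel@regionSeqs[[1L]]))
  key <- substr(key, 1, 200)
  if (is.null(.panelCaches[[key]]))
    .panelCaches[[key]] <- new.env(parent = emptyenv())
  .panelCaches[[key]]
}

#' Site table of the whole panel
#'
#' One row per region base (excluding the outermost base on each side of a
#' region, where no trinucleotide context exists): gene index, region
#' offset, coding position (0 for flank bases), base, trinucleotide context
#' class, chromosome and genomic position. Includes the per-context site
#' index used by the synthetic generator to place passenger mutations.
#'
#' @param panel A \linkS4class{GenePanel}.
#' @return List of parallel vectors plus \code{byContext}, a list of 32
#'   integer vectors of row indices per pyrimidine-centered context class.
#' @export
panelSiteTable <- function(panel) {
  cache <- panelCache(panel)
  if (!is.null(cache$sites)) return(cache$sites)
  g <- panel@genes
  f <- panel@flank
  nG <- nrow(g)
  widths <- Biostrings::width(panel@regionSeqs)
  seqcat <- paste(as.character(panel@regionSeqs), collapse = "")
  ball <- encodeBase(strsplit(seqcat, "", fixed = TRUE)[[1]])
  offs <- cumsum(c(0L, widths))[seq_len(nG)]
  # usable positions: region offsets 2..w-1
  nuse <- widths - 2L
  geneIdx <- rep.int(seq_len(nG), nuse)
  regOff <- unlist(lapply(nuse, function(n) seq_len(n) + 1L), use.names = FALSE)
  glob <- offs[geneIdx] + regOff
  base <- ball[glob]
  ctx <- contextIndex(ball[glob - 1L], base, ball[glob + 1L])
  cdslen <- g$cds_end - g$cds_start + 1L
  cpos <- regOff - f
  cpos[cpos < 1L | cpos > cdslen[geneIdx]] <- 0L
  plus <- g$strand[geneIdx] == "+"
  gpos <- ifelse(plus,
                 g$cds_start[geneIdx] - f + regOff - 1L,
                 g$cds_end[geneIdx] + f - regOff + 1L)
  sites <- list(geneIdx = geneIdx, regOff = regOff, cpos = cpos,
                base = base, ctx = ctx, gpos = gpos,
                chrom = g$chrom[geneIdx],
                byContext = split(seq_along(ctx), factor(ctx, levels = 1:32)))
  cache$sites <- sites
  sites
}

## ---- trinucleotide context extraction -------------------------------------

#' Extract genomic trinucleotide context at positions
#'
#' Returns the genomic-orientation (upstream, reference, downstream) bases
#' at 1-based positions, integer-encoded A=1..T=4 (NA where no context is
#' available). Methods exist for a \code{DNAStringSet} of whole chromosomes
#' (named by chromosome) and for a \linkS4class{GenePanel}, whose stored
#' region sequences back the lookup for positions inside targeted regions.
#'
#' @param x Reference sequence source.
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions.
#' @return List with integer vectors \code{up}, \code{ref}, \code{dn}.
#' @export
setGeneric("extractContext", function(x, chrom, pos)
  standardGeneric("extractContext"))

#' @rdname extractContext
setMethod("extractContext", "DNAStringSet", function(x, chrom, pos) {
  n <- length(pos)
  up <- ref <- dn <- rep(NA_integer_, n)
  cl <- stats::setNames(Biostrings::width(x), names(x))
  ok <- which(chrom %in% names(x) & pos >= 1 &
                pos <= ifelse(chrom %in% names(x), cl[chrom], 0))
  for (ch in unique(chrom[ok])) {
    i <- ok[chrom[ok] == ch]
    s <- as.character(x[[ch]])
    p <- pos[i]
    ref[i] <- encodeBase(substring(s, p, p))
    inner <- p > 1 & p < nchar(s)
    up[i[inner]] <- encodeBase(substring(s, p[inner] - 1, p[inner] - 1))
    dn[i[inner]] <- encodeBase(substring(s, p[inner] + 1, p[inner] + 1))
  }
  list(up = up, ref = ref, dn = dn)
})

#' @rdname extractContext
setMethod("extractContext", "GenePanel", function(x, chrom, pos) {
  g <- x@genes
  f <- x@flank
  n <- length(pos)
  up <- ref <- dn <- rep(NA_integer_, n)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hit <- GenomicRanges::findOverlaps(q, x@regions, select = "first",
                                     ignore.strand = TRUE)
  ok <- which(!is.na(hit))
  if (length(ok) == 0) return(list(up = up, ref = ref, dn = dn))
  gi <- hit[ok]
  rs <- g$cds_start[gi] - f
  re <- g$cds_end[gi] + f
  plus <- g$strand[gi] == "+"
  i <- ifelse(plus, pos[ok] - rs + 1L, re - pos[ok] + 1L)
  w <- re - rs + 1L
  for (u in unique(gi)) {
    sel <- gi == u
    b <- encodeDNA(as.character(x@regionSeqs[[u]]))
    ii <- i[sel]
    # coding-strand triple around offset ii
    cu <- ifelse(ii > 1L, b[pmax(ii - 1L, 1L)], NA_integer_)
    cr <- b[ii]
    cd <- ifelse(ii < length(b), b[pmin(ii + 1L, length(b))], NA_integer_)
    if (g$strand[u] == "+") {
      up[ok][sel] <- cu; ref[ok][sel] <- cr; dn[ok][sel] <- cd
    } else {
      up[ok][sel] <- 5L - cd; ref[ok][sel] <- 5L - cr; dn[ok][sel] <- 5L - cu
    }
  }
  list(up = up, ref = ref, dn = dn)
})
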