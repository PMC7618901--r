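# Shared vocabularies, the 96-channel substitution encoding, and small
# numeric conventions used by every stage of the pipeline.

#' Tumor-type codes of the feline pan-cancer cohort
#'
#' The closed set of 13 histologically defined tumor types: basal cell
#' carcinoma (BCC), cholangiocarcinoma (CCA), colorectal adenocarcinoma
#' (CRC), cutaneous mast cell tumor (cMCT), cutaneous squamous cell
#' carcinoma (cSCC), glioma (GLIO), lung adenocarcinoma (LUCA), lymphoma
#' (LYM), mammary carcinoma (MAM), meningioma (MEN), osteosarcoma (OSA),
#' oral squamous cell carcinoma (oSCC) and pancreatic adenocarcinoma (PANC).
#'
#' @return Character vector of the 13 codes.
#' @export
tumorTypes <- function() {
  c("BCC", "CCA", "CRC", "cMCT", "cSCC", "GLIO", "LUCA",
    "LYM", "MAM", "MEN", "OSA", "oSCC", "PANC")
}

#' Consequence vocabulary and groupings
#'
#' `consequenceClasses()` returns the closed consequence vocabulary;
#' `truncatingClasses()` the subset always counted as protein-truncating
#' (nonsense, frameshift, splice-site, start-loss, nonstop);
#' `consequenceAliases()` the documented alias table mapping common
#' synonyms (e.g. Sequence Ontology terms) onto the canonical set.
#'
#' @return Character vector (named, for the alias table).
#' @export
consequenceClasses <- function() {
  c("missense", "nonsense", "synonymous", "frameshift", "inframe_indel",
    "splice_site", "start_loss", "nonstop", "noncoding")
}

#' @rdname consequenceClasses
#' @export
truncatingClasses <- function() {
  c("nonsense", "frameshift", "splice_site", "start_loss", "nonstop")
}

#' @rdname consequenceClasses
#' @export
consequenceAliases <- function() {
  c(stop_gained            = "nonsense",
    stop_lost              = "nonstop",
    stop_retained_variant  = "synonymous",
    start_lost             = "start_loss",
    missense_variant       = "missense",
    synonymous_variant     = "synonymous",
    frameshift_variant     = "frameshift",
    frameshift_indel       = "frameshift",
    inframe_insertion      = "inframe_indel",
    inframe_deletion       = "inframe_indel",
    splice_acceptor_variant = "splice_site",
    splice_donor_variant   = "splice_site",
    splice_region_variant  = "splice_site",
    intron_variant         = "noncoding",
    intergenic_variant     = "noncoding",
    "5_prime_UTR_variant"  = "noncoding",
    "3_prime_UTR_variant"  = "noncoding")
}

# Canonicalize a vector of consequence strings via the alias table;
# unknown strings raise an error naming the offenders.
normalizeConsequence <- function(x) {
  x <- as.character(x)
  ali <- consequenceAliases()
  hit <- x %in% names(ali)
  x[hit] <- unname(ali[x[hit]])
  bad <- setdiff(unique(x), consequenceClasses())
  if (length(bad) > 0L)
    stop("unknown consequence value(s): ", paste(bad, collapse = ", "))
  x
}

#' Cohort percent convention
#'
#' Percentages reported by all cohort summaries: 100 * n / d rounded half
#' away from zero to the nearest integer (so 19/493 -> 4, 102/493 -> 21,
#' 181/493 -> 37, 67/493 -> 14, 6/31 -> 19).
#'
#' @param n Numerator count(s).
#' @param d Denominator count(s); must be > 0.
#' @return Integer percent(s).
#' @export
roundPercent <- function(n, d) {
  if (any(d <= 0)) stop("denominator must be positive")
  x <- 100 * n / d
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

## ---- base / codon / channel integer encodings -----------------------------

# bases encoded A=1 C=2 G=3 T=4; complement is 5 - code
.BASES <- c("A", "C", "G", "T")

encodeBase <- function(x) {
  m <- match(x, .BASES)
  m
}

decodeBase <- function(i) .BASES[i]

.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Standard 96-channel labels
#'
#' Channel labels in the standard pyrimidine-centered order: the six
#' substitution classes C>A, C>G, C>T, T>A, T>C, T>G, each across the 16
#' flanking-base contexts ordered A,C,G,T upstream (outer) and downstream
#' (inner), e.g. `"A[C>A]A"`, `"A[C>A]C"`, ...
#'
#' @return Character vector of length 96.
#' @export
channelLabels <- function() {
  out <- character(96)
  k <- 0L
  for (s in .SUBS) for (up in .BASES) for (dn in .BASES) {
    k <- k + 1L
    out[k] <- paste0(up, "[", s, "]", dn)
  }
  out
}

# Vectorized channel index (1..96) from integer-encoded genomic context
# (upstream, ref, downstream) and alternate base. Purine-reference records
# are reverse-complemented into the pyrimidine-centered frame.
channelIndex <- function(up, ref, dn, alt) {
  pur <- ref == 1L | ref == 3L
  u <- ifelse(pur, 5L - dn, up)
  r <- ifelse(pur, 5L - ref, ref)
  d <- ifelse(pur, 5L - up, dn)
  a <- ifelse(pur, 5L - alt, alt)
  # substitution index within .SUBS
  sub <- integer(length(r))
  isC <- r == 2L
  # C ref: A->1 G->2 T->3 ; T ref: A->4 C->5 G->6
  sub[isC] <- match(a[isC], c(1L, 3L, 4L))
  sub[!isC] <- match(a[!isC], c(1L, 2L, 3L)) + 3L
  (sub - 1L) * 16L + (u - 1L) * 4L + d
}

# 32 trinucleotide context classes (pyrimidine-centered): index from
# integer-encoded genomic (up, center, dn).
contextIndex <- function(up, ctr, dn) {
  pur <- ctr == 1L | ctr == 3L
  u <- ifelse(pur, 5L - dn, up)
  c2 <- ifelse(pur, 5L - ctr, ctr)
  d <- ifelse(pur, 5L - up, dn)
  pyr <- ifelse(c2 == 2L, 1L, 2L)        # C -> 1, T -> 2
  (pyr - 1L) * 16L + (u - 1L) * 4L + d
}

# channel -> context class, and the three channels served by each context
.CHANNEL_CONTEXT <- local({
  sub <- rep(1:6, each = 16)
  pyr <- ifelse(sub <= 3, 1L, 2L)
  flank <- rep(1:16, times = 6)
  (pyr - 1L) * 16L + flank
})

# channel -> pyrimidine-frame alt base code
.CHANNEL_ALT <- local({
  sub <- rep(1:6, each = 16)
  alt <- integer(96)
  alt[sub == 1] <- 1L; alt[sub == 2] <- 3L; alt[sub == 3] <- 4L
  alt[sub == 4] <- 1L; alt[sub == 5] <- 2L; alt[sub == 6] <- 3L
  alt
})

# context class -> is the pyrimidine-frame center C (TRUE) or T
.CONTEXT_IS_C <- rep(c(TRUE, FALSE), each = 16L)

## ---- genetic code ---------------------------------------------------------

# codon integer = (b1-1)*16 + (b2-1)*4 + b3, bases A=1..T=4
.AA_BY_CODON <- local({
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  idx <- (encodeBase(substr(codons, 1, 1)) - 1L) * 16L +
    (encodeBase(substr(codons, 2, 2)) - 1L) * 4L +
    encodeBase(substr(codons, 3, 3))
  out <- character(64)
  out[idx] <- unname(gc)
  out
})

codonToAA <- function(codonInt) .AA_BY_CODON[codonInt]

# Encode a DNA string into an integer base vector (A=1..T=4, NA otherwise).
encodeDNA <- function(seq) {
  encodeBase(strsplit(seq, "", fixed = TRUE)[[1]])
}

revcompInt <- function(b) rev(5L - b)

# Reverse complement of character DNA strings (vectorized).
revcompStr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## ---- misc -----------------------------------------------------------------

# Deterministic 31-bit integer substream seed from a root seed and a label;
# keeps per-sample randomness independent of sample order.
substreamSeed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(paste0(label, ":", seed))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Write a tab-separated table with header, UTF-8, deterministic order.
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

readTsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
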