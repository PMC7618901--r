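# 96-channel mutational spectra, non-negative least-squares signature
# refitting against a reference catalog, and UV/hypermutator flagging.

#' Build the 96-channel spectrum of one sample
#'
#' Counts single-nucleotide variants into the standard pyrimidine-centered
#' trinucleotide channels. Purine-reference substitutions are
#' reverse-complemented into the pyrimidine frame. Records whose genomic
#' context contains a non-ACGT base, or whose reference allele disagrees
#' with the reference sequence, are dropped with a warning; a position
#' outside the reference sequence source is an error.
#'
#' @param variants Variant data.frame (one sample); non-SNV records are
#'   ignored.
#' @param genome Reference sequence source: a \code{DNAStringSet} named by
#'   chromosome or a \linkS4class{GenePanel}.
#' @return Named integer vector of length 96 (channel labels).
#' @export
buildSpectrum <- function(variants, genome) {
  v <- variants[variants$variant_class == "SNV", , drop = FALSE]
  counts <- stats::setNames(integer(96), channelLabels())
  if (nrow(v) == 0) return(counts)
  ctx <- extractContext(genome, v$chrom, v$pos)
  if (anyNA(ctx$ref))
    stop(sum(is.na(ctx$ref)), " SNV position(s) outside the reference sequence")
  alt <- encodeBase(v$alt)
  refv <- encodeBase(v$ref)
  drop <- is.na(ctx$up) | is.na(ctx$dn) | is.na(alt) | is.na(refv) |
    refv != ctx$ref
  if (any(drop)) {
    warning(sum(drop), " SNV(s) dropped: ambiguous context or reference mismatch")
    v <- v[!drop, , drop = FALSE]
    for (nm in c("up", "ref", "dn")) ctx[[nm]] <- ctx[[nm]][!drop]
    alt <- alt[!drop]
  }
  if (nrow(v) == 0) return(counts)
  ch <- channelIndex(ctx$up, ctx$ref, ctx$dn, alt)
  tab <- tabulate(ch, nbins = 96L)
  counts[] <- tab
  counts
}

#' Build spectra for every sample of a cohort
#'
#' @param variants Somatic variant data.frame (multiple samples).
#' @param genome Reference sequence source (see \code{\link{buildSpectrum}}).
#' @param sample_ids Samples to include (default: all in \code{variants}).
#' @return Integer matrix 96 x n_samples.
#' @export
buildSpectra <- function(variants, genome, sample_ids = NULL) {
  if (is.null(sample_ids)) sample_ids <- unique(variants$sample_id)
  m <- vapply(sample_ids, function(s)
    buildSpectrum(variants[variants$sample_id == s, , drop = FALSE], genome),
    integer(96))
  m <- matrix(m, nrow = 96, dimnames = list(channelLabels(), sample_ids))
  m
}

#' Read / write a 96-row signature catalog TSV
#'
#' First column holds channel labels in \code{"A[C>T]G"} notation; the
#' remaining columns are signature profiles. Rows are reordered into the
#' standard channel order; columns are normalized to sum to 1.
#'
#' @param path Path to the TSV.
#' @return A \linkS4class{SignatureCatalog}.
#' @export
readSignatureCatalog <- function(path) {
  df <- readTsv(path)
  lab <- df[[1]]
  if (!setequal(lab, channelLabels()))
    stop("catalog must contain exactly the 96 standard channel labels")
  m <- as.matrix(df[, -1, drop = FALSE])
  m <- m[match(channelLabels(), lab), , drop = FALSE]
  SignatureCatalog(m)
}

#' @rdname readSignatureCatalog
#' @param catalog A \linkS4class{SignatureCatalog} to write.
#' @export
writeSignatureCatalog <- function(catalog, path) {
  df <- data.frame(channel = channelLabels(),
                   signatureProfiles(catalog), check.names = FALSE)
  writeTsv(df, path)
}

#' UV-like substitution profile
#'
#' A synthetic ultraviolet-damage-like 96-channel profile: mass
#' concentrated on C>T substitutions at dipyrimidines (pyrimidine 5' of the
#' mutated cytosine), the hallmark of UV mutagenesis.
#'
#' @param dipyrimidine_mass Total probability on the eight C>T
#'   dipyrimidine channels.
#' @return Named numeric vector of length 96 summing to 1.
#' @export
uvSignatureProfile <- function(dipyrimidine_mass = 0.92) {
  w <- rep((1 - dipyrimidine_mass) / 88, 96)
  # C>T block is channels 33..48; upstream C -> flanks 5..8, upstream T -> 13..16
  uvch <- c(32L + 5:8, 32L + 13:16)
  w[uvch] <- dipyrimidine_mass / 8
  stats::setNames(w, channelLabels())
}

#' Illustrative synthetic signature catalog
#'
#' A small clearly-synthetic five-signature catalog used by examples and
#' the synthetic cohort: a flat profile, the UV-like profile of
#' \code{\link{uvSignatureProfile}}, a CpG-deamination-like profile (C>T at
#' NpCpG), an APOBEC-like profile (C>T / C>G at TpCpW) and a
#' transition-rich profile (T>C). It is not the COSMIC catalog; real
#' analyses should supply a reference catalog via
#' \code{\link{readSignatureCatalog}}.
#'
#' @return A \linkS4class{SignatureCatalog} with 5 signatures.
#' @export
syntheticSignatureCatalog <- function() {
  flat <- rep(1 / 96, 96)
  uv <- unname(uvSignatureProfile())
  cpg <- rep(0.2 / 92, 96)
  cpg[32L + c(3L, 7L, 11L, 15L)] <- 0.8 / 4      # C>T with downstream G
  apo <- rep(0.12 / 92, 96)
  apo[c(16L + 13L, 16L + 16L, 32L + 13L, 32L + 16L)] <- 0.88 / 4  # TpCpA/T
  tra <- rep(0.2 / 80, 96)
  tra[64L + 1:16] <- 0.8 / 16                    # T>C block
  m <- cbind(SYN_FLAT = flat, SYN_UV = uv, SYN_CPG = cpg,
             SYN_APOBEC = apo, SYN_TC = tra)
  SignatureCatalog(m)
}

#' Refit signature exposures by non-negative least squares
#'
#' Finds non-negative exposures minimizing the Euclidean distance between
#' an observed 96-channel spectrum and \code{catalog %*% exposures}
#' (active-set NNLS; deterministic). Fractions are exposures normalized to
#' sum 1 (all-zero spectra give all-zero fractions).
#'
#' @param spectra Named 96-vector or 96 x n matrix of channel counts.
#' @param catalog A \linkS4class{SignatureCatalog}.
#' @return data.frame with one row per sample: \code{sample_id},
#'   \code{n_snvs}, \code{residual}, one \code{exposure_<sig>} and one
#'   \code{fraction_<sig>} column per signature.
#' @export
refitExposures <- function(spectra, catalog) {
  if (is.null(dim(spectra)))
    spectra <- matrix(spectra, ncol = 1, dimnames = list(names(spectra), "sample"))
  P <- signatureProfiles(catalog)
  K <- ncol(P)
  out <- lapply(seq_len(ncol(spectra)), function(j) {
    d <- as.numeric(spectra[, j])
    if (sum(d) == 0) {
      x <- rep(0, K)
    } else {
      x <- pracma::lsqnonneg(P, d)$x
    }
    res <- sqrt(sum((d - as.numeric(P %*% x))^2))
    tot <- sum(x)
    fr <- if (tot > 0) x / tot else rep(0, K)
    c(n_snvs = sum(d), residual = res,
      stats::setNames(x, paste0("exposure_", colnames(P))),
      stats::setNames(fr, paste0("fraction_", colnames(P))))
  })
  df <- as.data.frame(do.call(rbind, out))
  df <- cbind(sample_id = colnames(spectra), df)
  rownames(df) <- NULL
  df
}

#' Flag hypermutator (UV-signature) samples
#'
#' A sample is flagged as a hypermutator when the refitted fraction of the
#' UV signature reaches \code{min_fraction} and the sample has at least
#' \code{min_snvs} SNVs. Both knobs are exposed because signature
#' "presence" criteria vary between studies.
#'
#' @param exposures Result of \code{\link{refitExposures}}.
#' @param uv_signature Name of the UV-like signature in the catalog.
#' @param min_fraction Minimum UV fraction (default 0.2).
#' @param min_snvs Minimum SNV count (default 20).
#' @return \code{exposures} with a logical \code{hypermutator} column.
#' @export
flagHypermutators <- function(exposures, uv_signature,
                              min_fraction = 0.2, min_snvs = 20L) {
  col <- paste0("fraction_", uv_signature)
  if (!col %in% names(exposures))
    stop("unknown signature name: ", uv_signature)
  exposures$hypermutator <- exposures[[col]] >= min_fraction &
    exposures$n_snvs >= min_snvs
  exposures
}
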