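# Viral screening of off-target reads by canonical k-mer containment,
# with retroviral (FIV/FeLV) exclusion.

# All canonical k-mers of a DNA string (ambiguous bases excluded).
canonicalKmers <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  km <- substring(seq, 1:(L - k + 1), k:L)
  km <- km[!grepl("[^ACGT]", km)]
  if (length(km) == 0) return(character(0))
  rc <- revcompStr(km)
  unique(pmin(km, rc))
}

#' Build a viral k-mer index
#'
#' Extracts canonical k-mers (the lexicographically smaller of a k-mer and
#' its reverse complement) from each viral reference and removes any k-mer
#' present in the exclusion references, so reads from excluded
#' retroviruses can never be assigned.
#'
#' @param viruses \code{DNAStringSet} of target viral genomes (named).
#' @param exclusions \code{DNAStringSet} of excluded references (e.g.
#'   FIV/FeLV), or NULL.
#' @param k Odd k-mer size >= 15 (default 31).
#' @return A \linkS4class{ViralIndex}.
#' @export
buildViralIndex <- function(viruses, exclusions = NULL, k = 31L) {
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("k must be odd")
  if (k < 15L) stop("k must be >= 15")
  excl <- character(0)
  if (!is.null(exclusions) && length(exclusions) > 0)
    excl <- unique(unlist(lapply(as.character(exclusions), canonicalKmers, k = k)))
  sets <- lapply(as.character(viruses), canonicalKmers, k = k)
  names(sets) <- names(viruses)
  n_ex <- 0L
  for (i in seq_along(sets)) {
    before <- length(sets[[i]])
    sets[[i]] <- setdiff(sets[[i]], excl)
    n_ex <- n_ex + before - length(sets[[i]])
  }
  new("ViralIndex", k = k, sets = sets, n_excluded = n_ex)
}

#' Screen reads of one sample against a viral index
#'
#' Each read is assigned to the virus with the highest containment (the
#' fraction of the read's canonical k-mers found in that virus's set) if
#' it reaches \code{read_min_containment}; ties leave the read
#' unassigned. A sample-virus hit is emitted iff at least
#' \code{sample_min_reads} reads are assigned. Reads shorter than k are
#' skipped and counted.
#'
#' @param reads Character vector of read sequences.
#' @param index A \linkS4class{ViralIndex}.
#' @param read_min_containment Minimum containment to assign a read
#'   (default 0.6).
#' @param sample_min_reads Minimum assigned reads to emit a hit (default 5).
#' @return List: \code{hits} (data.frame virus, supporting_reads,
#'   mean_containment), \code{n_reads}, \code{n_too_short}.
#' @export
screenReads <- function(reads, index, read_min_containment = 0.6,
                        sample_min_reads = 5L) {
  k <- index@k
  tooShort <- nchar(reads) < k
  use <- reads[!tooShort]
  emptyHits <- data.frame(virus = character(0), supporting_reads = integer(0),
                          mean_containment = numeric(0))
  if (length(use) == 0)
    return(list(hits = emptyHits, n_reads = length(reads),
                n_too_short = sum(tooShort)))
  nv <- length(index@sets)
  kmL <- lapply(use, canonicalKmers, k = k)
  nk <- lengths(kmL)
  rid <- rep.int(seq_along(use), nk)
  kmAll <- unlist(kmL, use.names = FALSE)
  cont <- matrix(0, nrow = length(use), ncol = nv,
                 dimnames = list(NULL, names(index@sets)))
  if (length(kmAll) > 0) {
    for (vi in seq_len(nv)) {
      inSet <- kmAll %in% index@sets[[vi]]
      hitN <- rowsum(as.numeric(inSet), rid)
      cont[as.integer(rownames(hitN)), vi] <-
        hitN[, 1] / nk[as.integer(rownames(hitN))]
    }
  }
  best <- max.col(cont, ties.method = "first")
  bestVal <- cont[cbind(seq_len(nrow(cont)), best)]
  # ties leave the read unassigned
  tied <- rowSums(cont == bestVal) > 1 & bestVal > 0
  assigned <- bestVal >= read_min_containment & !tied
  hits <- emptyHits
  if (any(assigned)) {
    df <- data.frame(virus = names(index@sets)[best[assigned]],
                     containment = bestVal[assigned])
    agg <- stats::aggregate(containment ~ virus, data = df,
                            FUN = function(x) c(n = length(x), m = mean(x)))
    hits <- data.frame(virus = agg$virus,
                       supporting_reads = as.integer(agg$containment[, "n"]),
                       mean_containment = as.numeric(agg$containment[, "m"]),
                       stringsAsFactors = FALSE)
    hits <- hits[hits$supporting_reads >= sample_min_reads, , drop = FALSE]
    rownames(hits) <- NULL
  }
  list(hits = hits, n_reads = length(reads), n_too_short = sum(tooShort))
}

#' Screen every sample of a cohort
#'
#' @param reads Named list of read vectors (sample_id -> reads), e.g.
#'   \code{\link{offTargetReads}} output.
#' @param index A \linkS4class{ViralIndex}.
#' @param ... Passed to \code{\link{screenReads}}.
#' @return data.frame sample_id, virus, supporting_reads, mean_containment.
#' @export
screenCohortReads <- function(reads, index, ...) {
  out <- list()
  for (sid in names(reads)) {
    res <- screenReads(reads[[sid]], index, ...)
    if (nrow(res$hits) > 0) {
      res$hits$sample_id <- sid
      out[[sid]] <- res$hits
    }
  }
  if (length(out) == 0)
    return(data.frame(sample_id = character(0), virus = character(0),
                      supporting_reads = integer(0),
                      mean_containment = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[, c("sample_id", "virus", "supporting_reads", "mean_containment")]
  rownames(res) <- NULL
  res
}

#' Read FASTA/FASTQ reads as a character vector
#'
#' @param path FASTA or FASTQ file (gzip allowed).
#' @param format "fasta" or "fastq" (guessed from the extension by default).
#' @return Character vector of read sequences.
#' @export
readSequencingReads <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path)) "fastq" else "fasta"
  x <- if (format == "fastq") Biostrings::readDNAStringSet(path, format = "fastq")
  else Biostrings::readDNAStringSet(path)
  as.character(x)
}
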