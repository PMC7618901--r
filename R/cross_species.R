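# Cross-species comparison: global ortholog protein alignment, residue
# maps, "humanization" of cat protein changes, and per-gene mutation
# frequency comparison against human cohort tables.

#' Align a cat/human ortholog protein pair
#'
#' Global (end-gap penalized) pairwise alignment with BLOSUM62 scoring and
#' affine gaps (open 10, extend 0.5). Aligned non-gap columns become the
#' residue map; its pairs are strictly monotone in both coordinates by
#' construction. Maps with identity below \code{low_identity} are flagged
#' low-confidence but still usable.
#'
#' @param cat_protein,human_protein Amino-acid strings (non-empty; X
#'   allowed but X columns are never mapped).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @param low_identity Identity fraction below which the map is flagged.
#' @return List: \code{pairs} (data.frame cat_pos, human_pos, cat_aa,
#'   human_aa), \code{identity_fraction}, \code{low_confidence},
#'   \code{cat_length}, \code{human_length}.
#' @export
alignOrthologs <- function(cat_protein, human_protein,
                           gap_opening = 10, gap_extension = 0.5,
                           low_identity = 0.5) {
  cat_protein <- as.character(cat_protein)
  human_protein <- as.character(human_protein)
  if (nchar(cat_protein) == 0 || nchar(human_protein) == 0)
    stop("protein sequences must be non-empty")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(cat_protein), Biostrings::AAString(human_protein),
    substitutionMatrix = "BLOSUM62", type = "global",
    gapOpening = gap_opening, gapExtension = gap_extension)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  cpos <- cumsum(pa != "-")
  hpos <- cumsum(sa != "-")
  keep <- pa != "-" & sa != "-" & pa != "X" & sa != "X"
  pairs <- data.frame(cat_pos = cpos[keep], human_pos = hpos[keep],
                      cat_aa = pa[keep], human_aa = sa[keep],
                      stringsAsFactors = FALSE)
  ident <- if (nrow(pairs) > 0)
    sum(pairs$cat_aa == pairs$human_aa) / length(pa) else 0
  list(pairs = pairs, identity_fraction = ident,
       low_confidence = ident < low_identity,
       cat_length = nchar(cat_protein), human_length = nchar(human_protein))
}

#' Humanize one cat protein change
#'
#' Maps a cat protein change onto the human ortholog's coordinates:
#' status \code{mapped} iff the cat residue is an aligned non-gap column
#' AND the human residue letter equals the cat reference amino acid
#' (strict reference match prevents nonsensical humanized annotations;
#' relax with \code{require_ref_match = FALSE} for lollipop aggregation).
#'
#' @param variant One variant row with protein_pos, aa_ref, aa_alt.
#' @param map \code{\link{alignOrthologs}} output.
#' @param require_ref_match Require the aligned human residue to equal
#'   aa_ref (default TRUE).
#' @return One-row data.frame: cat_gene, cat_change, human_gene (caller
#'   fills names), human_pos, human_change, status in \{mapped,
#'   ref_mismatch, gap, no_ortholog\}.
#' @export
humanize <- function(variant, map, require_ref_match = TRUE) {
  if (is.na(variant$protein_pos) || is.na(variant$aa_ref) ||
      is.na(variant$aa_alt))
    stop("variant must carry protein_pos, aa_ref and aa_alt")
  cat_change <- paste0(variant$aa_ref, variant$protein_pos, variant$aa_alt)
  i <- match(variant$protein_pos, map$pairs$cat_pos)
  if (is.na(i)) {
    return(data.frame(cat_change = cat_change, human_pos = NA_integer_,
                      human_change = "", status = "gap",
                      stringsAsFactors = FALSE))
  }
  hres <- map$pairs$human_aa[i]
  hpos <- map$pairs$human_pos[i]
  if (require_ref_match && hres != variant$aa_ref) {
    return(data.frame(cat_change = cat_change, human_pos = hpos,
                      human_change = "", status = "ref_mismatch",
                      stringsAsFactors = FALSE))
  }
  data.frame(cat_change = cat_change, human_pos = hpos,
             human_change = paste0(variant$aa_ref, hpos, variant$aa_alt),
             status = "mapped", stringsAsFactors = FALSE)
}

#' Humanize all eligible variants of a cohort
#'
#' Aligns each mutated gene's cat/human ortholog pair once, then maps
#' every missense/nonsense SNV carrying full protein annotation. Variants
#' in genes without a human ortholog get status \code{no_ortholog}.
#'
#' @param variants Somatic variant data.frame.
#' @param panel A \linkS4class{GenePanel}.
#' @param genes Genes to humanize (default: all mutated genes with
#'   protein-annotated variants).
#' @param require_ref_match See \code{\link{humanize}}.
#' @return data.frame: sample_id, gene, human_gene, cat_change,
#'   human_change, status, low_confidence.
#' @export
humanizeVariants <- function(variants, panel, genes = NULL,
                             require_ref_match = TRUE) {
  v <- variants[!is.na(variants$protein_pos) & !is.na(variants$aa_ref) &
                  !is.na(variants$aa_alt) & variants$gene != "", ,
                drop = FALSE]
  if (!is.null(genes)) v <- v[v$gene %in% genes, , drop = FALSE]
  v$.row <- seq_len(nrow(v))
  g <- geneModels(panel)
  out <- list()
  for (gn in unique(v$gene)) {
    vg <- v[v$gene == gn, , drop = FALSE]
    gi <- match(gn, g$gene)
    hg <- if (is.na(gi)) "" else g$human_ortholog[gi]
    if (is.na(gi) || hg == "" || !gn %in% names(humanProteins(panel))) {
      out[[gn]] <- data.frame(
        .row = vg$.row,
        sample_id = vg$sample_id, gene = gn, human_gene = "",
        cat_change = paste0(vg$aa_ref, vg$protein_pos, vg$aa_alt),
        human_change = "", status = "no_ortholog", low_confidence = NA,
        stringsAsFactors = FALSE)
      next
    }
    map <- alignOrthologs(as.character(catProteins(panel)[[gn]]),
                          as.character(humanProteins(panel)[[gn]]))
    hz <- do.call(rbind, lapply(seq_len(nrow(vg)), function(r)
      humanize(vg[r, ], map, require_ref_match)))
    out[[gn]] <- data.frame(
      .row = vg$.row,
      sample_id = vg$sample_id, gene = gn, human_gene = hg,
      cat_change = hz$cat_change, human_change = hz$human_change,
      status = hz$status, low_confidence = map$low_confidence,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(sample_id = character(0), gene = character(0),
                      human_gene = character(0), cat_change = character(0),
                      human_change = character(0), status = character(0),
                      low_confidence = logical(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$.row), setdiff(names(res), ".row"), drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Compare per-gene mutation frequencies between species
#'
#' Cat fraction = distinct mutated samples / tumor-type cohort size, for
#' protein-altering variants; human fractions are supplied as input (from
#' published pan-cancer cohorts). Only gene x tumor-type pairs present in
#' both tables are reported.
#'
#' @param variants Somatic variant data.frame (cat cohort).
#' @param meta Sample metadata.
#' @param human_freq data.frame gene, tumor_type, fraction.
#' @return data.frame gene, tumor_type, cat_fraction, human_fraction,
#'   difference (cat minus human).
#' @export
frequencyCompare <- function(variants, meta, human_freq) {
  altering <- c(truncatingClasses(), "missense", "inframe_indel")
  v <- variants[variants$consequence %in% altering & variants$gene != "", ,
                drop = FALSE]
  v$tumor_type <- meta$tumor_type[match(v$sample_id, meta$sample_id)]
  pairs <- unique(v[, c("sample_id", "gene", "tumor_type")])
  cnt <- stats::aggregate(sample_id ~ gene + tumor_type, data = pairs,
                          FUN = length)
  names(cnt)[3] <- "n_mutated"
  tsize <- table(meta$tumor_type)
  cnt$cat_fraction <- cnt$n_mutated / as.integer(tsize[cnt$tumor_type])
  m <- merge(cnt[, c("gene", "tumor_type", "cat_fraction")], human_freq,
             by = c("gene", "tumor_type"))
  names(m)[names(m) == "fraction"] <- "human_fraction"
  m$difference <- m$cat_fraction - m$human_fraction
  m[order(m$gene, m$tumor_type), , drop = FALSE]
}
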