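# Independent oracles used by unit and acceptance tests. These
# deliberately re-derive the results by different means (exhaustive
# closure, rule-by-rule filtering, grid search) than the implementation.

# Exhaustive hotspot oracle: transitive closure over all position pairs
# within tolerance, then support filtering.
bruteHotspots <- function(variants, min_tumors = 2L, tolerance = 1L) {
  v <- variants[variants$consequence %in% c("missense", "inframe_indel") &
                  !is.na(variants$protein_pos), , drop = FALSE]
  out <- list()
  for (gn in sort(unique(v$gene))) {
    vg <- v[v$gene == gn, ]
    pos <- sort(unique(vg$protein_pos))
    n <- length(pos)
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (abs(pos[i] - pos[j]) <= tolerance && comp[i] != comp[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cc in unique(comp)) {
      pc <- pos[comp == cc]
      sel <- vg$protein_pos %in% pc
      nt <- length(unique(vg$sample_id[sel]))
      if (nt >= min_tumors)
        out[[length(out) + 1L]] <- data.frame(
          gene = gn, residue_start = min(pc), residue_end = max(pc),
          n_tumors = nt, n_mutations = sum(sel))
    }
  }
  if (length(out) == 0)
    return(data.frame(gene = character(0), residue_start = integer(0),
                      residue_end = integer(0), n_tumors = integer(0),
                      n_mutations = integer(0)))
  do.call(rbind, out)
}

# Rule-by-rule burden oracle: literal per-variant evaluation of the
# recurrence / truncating-always / hypermutator-hotspot rules.
bruteRecurrentBurden <- function(variants, hypermutators, hotspots,
                                 sample_ids) {
  altering <- c("nonsense", "frameshift", "splice_site", "start_loss",
                "nonstop", "missense", "inframe_indel")
  counts <- stats::setNames(integer(length(sample_ids)), sample_ids)
  v <- variants[variants$gene != "", , drop = FALSE]
  for (r in seq_len(nrow(v))) {
    row <- v[r, ]
    if (!row$consequence %in% altering) next
    carriers <- unique(v$sample_id[v$gene == row$gene &
                                     v$consequence %in% altering])
    if (length(carriers) < 2) next
    truncating <- row$consequence %in% c("nonsense", "frameshift",
                                         "splice_site", "start_loss",
                                         "nonstop")
    ok <- FALSE
    if (truncating) {
      ok <- TRUE
    } else if (!(row$sample_id %in% hypermutators)) {
      ok <- TRUE
    } else if (!is.null(hotspots) && nrow(hotspots) > 0 &&
               !is.na(row$protein_pos)) {
      for (h in seq_len(nrow(hotspots))) {
        if (hotspots$gene[h] == row$gene &&
            row$protein_pos >= hotspots$residue_start[h] &&
            row$protein_pos <= hotspots$residue_end[h]) { ok <- TRUE; break }
      }
    }
    if (ok && row$sample_id %in% sample_ids)
      counts[row$sample_id] <- counts[row$sample_id] + 1L
  }
  counts
}

# Random variant set spanning all consequence classes, for oracle checks.
randomVariantSet <- function(n_samples = 8, n_genes = 4, n_var = 25) {
  cons <- c("missense", "nonsense", "synonymous", "frameshift",
            "inframe_indel", "splice_site", "start_loss", "nonstop",
            "noncoding")
  mkVariant(sprintf("S%d", sample(seq_len(n_samples), n_var, replace = TRUE)),
            sprintf("G%d", sample(seq_len(n_genes), n_var, replace = TRUE)),
            sample(cons, n_var, replace = TRUE),
            protein_pos = sample(1:25, n_var, replace = TRUE),
            aa_ref = "A", aa_alt = "V")
}
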