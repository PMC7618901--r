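# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small panel / cohort for unit tests
fixPanel <- function() memo("panel", syntheticGenePanel(
  n_genes = 60L, seed = 42L, mean_protL = 450L))

fixCohort <- function() memo("cohort", suppressWarnings(
  generateCohort(fixtureSyntheticConfig(42L), panel = fixPanel())))

# full-size panel and default cohort for acceptance-scale checks
fullPanel <- function() memo("fullPanel", syntheticGenePanel(seed = 11L))

fullCohort <- function() memo("fullCohort", suppressWarnings(
  generateCohort(defaultSyntheticConfig(11L), panel = fullPanel())))

# a null (spike-free, flat-spectrum, CNA-free) single-type configuration
nullConfig <- function(seed, n = 100L, tmb = 20) {
  cfg <- defaultSyntheticConfig(seed)
  cfg$per_type_n <- c(LUCA = as.integer(n))
  cfg$tmb_log_median["LUCA"] <- tmb
  cfg$tmb_log_sd <- 0.5
  cfg$uv_fraction <- 0
  cfg$driver_spikes <- cfg$driver_spikes[0, ]
  cfg$viral_plant <- cfg$viral_plant[0, ]
  cfg$viral_background_reads <- 0L
  cfg$cn_templates <- cfg$cn_templates[0, ]
  cfg$cna_noise_rate[] <- 0
  cfg$germline_prevalence <- 0
  cfg$germline_noise_per_sample <- 0
  cfg
}

# hand-built variant table rows
mkVariant <- function(sample_id, gene, consequence, protein_pos = NA,
                      aa_ref = NA, aa_alt = NA, chrom = "A1",
                      pos = 1000, ref = "C", alt = "T",
                      variant_class = "SNV", compartment = "somatic") {
  n <- length(sample_id)
  r <- function(x) rep_len(x, n)
  data.frame(sample_id = r(sample_id), chrom = r(chrom), pos = r(pos),
             ref = r(ref), alt = r(alt), variant_class = r(variant_class),
             gene = r(gene), consequence = r(consequence),
             protein_pos = as.integer(r(protein_pos)),
             aa_ref = as.character(r(aa_ref)),
             aa_alt = as.character(r(aa_alt)),
             compartment = r(compartment), stringsAsFactors = FALSE)
}

mkMeta <- function(sample_ids, tumor_type = "MAM") {
  data.frame(sample_id = sample_ids,
             tumor_type = rep(tumor_type, length.out = length(sample_ids)),
             subtype = "", age_years = 10, sex = "F", breed = "DSH",
             stringsAsFactors = FALSE)
}

cosineSim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
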