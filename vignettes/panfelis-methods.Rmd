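---
title: "Models and methods behind panfelis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind panfelis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

panfelis analyses targeted tumor–normal sequencing of domestic-cat tumors
at cohort scale: tumor mutational burden, recurrently mutated genes and
hotspots, mutational-signature attribution, the somatic copy-number
landscape, the mutation/copy-number burden trade-off, driver-gene
selection, cross-species mutation mapping, actionability and germline
triage, and viral read screening. This vignette explains each model, its
assumptions, the tunable parameters, and the design choices made where
the methodology was genuinely open. It states no empirical result that
the package's tests and acceptance script do not themselves compute.

## Data model and conventions

All coordinates are 1-based inclusive; BED input (0-based half-open) is
converted at the boundary, so internal arithmetic matches HGVS and
SEG-style conventions throughout. The consequence vocabulary is closed
(missense, nonsense, synonymous, frameshift, inframe_indel, splice_site,
start_loss, nonstop, noncoding); common synonyms such as Sequence
Ontology terms are mapped through the documented alias table
(`consequenceAliases()`), and unknown strings are rejected rather than
silently retained. Cohort percentages are rounded half away from zero to
the nearest integer (`roundPercent()`), the convention that reproduces
the usual "k/n (p%)" renderings of cohort papers.

Variants arrive annotated: the pipeline never re-derives protein effects
from genomic context, except in the signatures module where the
trinucleotide context of each SNV is read from the reference sequence
source (either whole chromosomes as a `DNAStringSet` or the targeted
regions stored in a `GenePanel`).

## Tumor mutational burden

TMB is the somatic mutation count (SNVs, MNVs and indels that passed
input filtering) divided by the deduplicated panel footprint in
megabases. The denominator is the union of the targeted regions, so
overlapping regions are not double-counted; TMB is therefore linear in
the variant count and invariant to region bookkeeping. Panel footprints
of targeted designs in this domain are a few megabases; the synthetic
panel's ~978 genes give ≈2.1 Mb, which makes per-sample counts small
integers at low TMB — per-type medians are consequently quantized at
roughly 1/footprint resolution, which matters when interpreting medians
below ~1 mutation/Mb.

## Hotspots

A hotspot is a protein position mutated in at least `min_tumors = 2`
distinct samples with a ±1-residue tolerance. Positions are merged by
single linkage with gap ≤ `tolerance`: residues 100, 101, 102 chain into
one cluster even though 100 and 102 differ by 2. The tolerance rule does
not itself address chains, so the chaining behavior is an explicit
choice, checked against an exhaustive transitive-closure oracle in the
tests. Only missense and in-frame indel residues are clustered:
truncating variants are excluded because the burden rules below always
count them, so hotspots exist precisely to rescue missense calls in
hypermutators. Hotspot labels use the modal reference residue at the
modal position (e.g. `PIK3CA p.H1047`).

## Mutational signatures

Spectra use the standard 96 pyrimidine-centered trinucleotide channels;
purine-reference records are reverse-complemented into the pyrimidine
frame, which makes the construction strand-symmetric. Records with
ambiguous context or a reference-allele mismatch against the sequence
source are dropped with a warning; a position outside the reference is
an error, since it indicates corrupted input rather than noise.

Exposures are refitted against a user-supplied catalog by non-negative
least squares (active-set NNLS; deterministic, no tuning parameters).
There is no de-novo extraction: the attribution question here is whether
a known (UV-like) signature is present, not what novel signatures exist.
The package ships a clearly synthetic five-signature illustrative
catalog (`syntheticSignatureCatalog()`); the COSMIC catalog is licensed
and must be supplied by the user for real analyses.

A sample is flagged a hypermutator when the UV-signature fraction is at
least `min_fraction = 0.2` and the sample has at least `min_snvs = 20`
SNVs. Published studies state only that UV-signature samples were
treated as hypermutators; both knobs are exposed because "presence" of a
signature is not well-defined below a handful of mutations — with fewer
than ~20 SNVs the NNLS fraction is dominated by sampling noise.

## Copy-number landscape

Segments are classified as gain at log2 fold change ≥ +0.32 and loss at
≤ −0.40 (boundary values included), focal at length ≤ 10 Mb and broad
above. The published text uses "<10 Mb" in one place and "≤ 10 Mb" in
the legend stating the computational rule; the package uses ≤ 10 Mb and
documents the discrepancy. Genome fraction altered is the deduplicated
base count of gained or lost segments over the total assayable genome
length, in percent.

Bin profiles tile the genome at 1 Mb. A sample contributes gain or loss
to a bin iff the length-weighted mean log2fc of its overlapping segments
crosses the threshold — not any-overlap, which would let a 1-bp overlap
flag a 1-Mb bin (an `any_overlap` switch restores the cruder rule).
Per-type fractions therefore always have the per-type sample count as
denominator. Whole-chromosome calls use a coverage threshold of 0.8 of
the chromosome length in gained (lost) segments; the operational
definition of "gain of a chromosome" is not stated in the source
material, so 0.8 is this package's documented choice. Gene-level status
applies the same weighted-mean rule over the CDS span. Tumor types are
clustered on their net (gain − loss) bin vectors with Euclidean distance
and average linkage; input order is canonicalized and `hclust`'s
lowest-index merge rule makes the tree deterministic.

## Burden "hyperbola"

Per sample, the focal CNA burden is the count of non-neutral focal
segments, and the recurrent mutation burden counts somatic
protein-altering variants in genes mutated in ≥ 2 samples cohort-wide.
Truncating variants (nonsense, frameshift, splice-site, start-loss,
nonstop) always count. Missense and in-frame indels count for
non-hypermutators, and for hypermutators only inside a hotspot cluster
computed with the same ±1 tolerance. Synonymous and noncoding variants
enter neither the recurrence test nor the burden: the variant classes
the rule enumerates are all protein-altering, and admitting synonymous
recurrence would make the gene filter depend on panel composition. MNVs
are treated as missense-class unless annotated truncating. In-frame
indels participate in hotspot rescue exactly as missense (a flag can
separate them). The 2-D density summary uses rectangular bins —
hexagonal binning is presentation geometry, not analysis — and bin
counts conserve the number of samples with both data types.

## Driver selection

The selection test is an intentionally simplified, desk-scale analogue
of dNdScv-style inference with the same inferential shape: a neutral
background predicts missense and truncating counts per gene, and excess
is tested by likelihood ratio.

* Background: for each of the 96 channels, rate = (synonymous SNVs in
  the channel) / (panel sites where that channel's change is
  synonymous). Synonymous sites are neutral to protein sequence, so
  their rate estimates the local mutation process. With < 50 synonymous
  SNVs a flat per-site rate is used, with a warning. The truncating
  indel rate is frameshift coding indels per coding base — frameshift
  only, because in-frame indels are excluded from the test, and using
  all indels in the rate while counting only frameshift in the observed
  class would mis-calibrate the null.
* Test: expected counts come from summing channel rates over each
  gene's missense and truncating opportunity sites (every possible
  single-base change classified by codon arithmetic). Observed counts
  are Poisson with free ratios omega_mis and omega_trunc; the LRT
  against both fixed at 1 is referred to a 2-df chi-square. Only
  enrichment (omega > 1) can be called a driver; a deficit is reported
  but never called.
* Correction: Benjamini–Hochberg within each tumor-type family
  ("q-global" interpreted as the within-family correction; a pan-cancer
  family is available behind a flag), threshold q < 0.1.

Simplifications relative to full dNdScv: no covariates, no per-gene
random effects, 96 rather than 192 strand-specific channels, and a
single genome-wide indel rate. Consequences: genes with atypical local
mutation rates can drift from the null, and power at per-gene expected
counts below ~1 is limited by the discreteness of the Poisson
distribution — the chi-square reference is then conservative. The
calibration suite measures the realized type-I error on null cohorts
sized so per-gene expected counts are a few (100 samples, 100 genes of
~2.3 kb CDS at 20 mutations/Mb), where the approximation is usable.

## Cross-species humanization

Cat and human ortholog proteins are aligned globally (end gaps
penalized) with BLOSUM62, gap open 10, gap extend 0.5 — the source
material does not state its mapping method, so these standard protein
alignment defaults are the package's documented choice, and all are
configurable. Aligned non-gap, non-X columns form the residue map,
strictly monotone in both coordinates by construction. A cat change maps
iff its residue is in the map and the aligned human residue equals the
cat reference amino acid; the strict reference match prevents
nonsensical humanized annotations and can be relaxed for lollipop-style
aggregation. Maps under 50% identity are flagged low-confidence but
still usable. Frequency comparison restricts to gene × tumor-type pairs
present in both species' tables; human fractions are inputs, not
recomputed.

## Actionability and germline triage

The druggability, synthetic-lethality, actionable-variant and pathogenic
catalogs are user-supplied TSVs with documented schemas; the real
databases are licensed and versioned products, so only tiny clearly
synthetic illustrative catalogs ship with the package. A tumor is
Tclin-flagged iff it carries a protein-altering mutation in a driver
whose entry is Tclin; SL-flagged iff mutated in a driver with a
druggable partner; actionable iff a humanized SNV (strict mapped status)
exactly matches an oncogenic/likely-oncogenic entry in normalized
RefPosAlt form (position-only matching is a flag), recording the best
(lowest) therapeutic level. Flags are monotone in the catalogs: adding
rows never unflags a tumor. Germline screening keeps loss-of-function
classes (nonsense, frameshift, splice-site as annotated, start-loss) in
the 14 predisposition genes, humanizes the residue where possible, and
marks matches against the pathogenic catalog as orthologous_pathogenic.

## Viral screening

Off-target reads are screened by canonical k-mer containment (k = 31,
odd so a k-mer is never its own reverse complement). Each virus
contributes the set of canonical k-mers of its genome minus any k-mer in
the exclusion references (FIV/FeLV-like retroviruses), so excluded-virus
reads can never be assigned. A read is assigned to the virus with the
highest containment if ≥ 0.6, ties unassigned; a sample–virus hit
requires ≥ 5 assigned reads. Both thresholds are exposed: at 1%
sequencing error the expected per-k-mer survival is 0.99^31 ≈ 0.73, so
0.6 tolerates realistic error while rejecting chance matches, and the
5-read floor suppresses single-read artifacts. Reporting is by input
FASTA label; no taxonomy inference is attempted.

## The synthetic cohort generator

The generator exists so every stage can be tested against known truth
without controlled-access data. Its defaults emulate the structure of a
493-sample, 13-tumor-type feline cohort; they are illustrative of that
structure, not a re-creation of any real cohort.

* Gene panel: 978 single-exon gene models (one CDS interval each) on a
  cat-like 19-chromosome layout (~2.44 Gb), random coding sequence with
  ATG start, no internal stops, terminal stop; cat proteins are the
  translations, human orthologs differ by ~5% random substitution.
  Marquee cancer genes are placed at fixed loci with specific codons
  planted (PIK3CA codon 1047 His, CHEK2 codon 182 Tyr, KIT 560/816,
  FBXW7 465, CTNNB1 N-terminal cluster...) so spiked changes carry their
  familiar labels. Single-exon models keep codon arithmetic exact;
  splice-site consequences enter only through configured events.
* Mutations: per sample, a Poisson count at TMB × footprint with
  lognormal per-type TMB (medians spanning ~0.5–20 mutations/Mb, log-sd
  0.7); sites uniform over the panel (flat samples) or drawn
  channel-first from the UV-like profile for the designated fraction
  (0.55) of the skin-like type; consequences derived from codon
  arithmetic. Indels are 10% of passenger events, length 1–10,
  frameshift with probability 2/3 — unspecified by the source material,
  chosen to exercise the burden rules. Driver spike-ins are Bernoulli
  per sample at configured frequencies, optionally at a fixed hotspot
  residue and target amino acid.
* Copy number: per-type event templates (whole-chromosome F1/F2 gains
  across eleven types, X losses across nine, broad gains on A3/B4, a
  MAM-heavy broad landscape, focal MYC gain, PTEN/FAS and CDKN2A
  losses) plus Poisson focal noise. Overlaps resolve most-focal-wins,
  adjacent equal segments merge, and a small N(0, 0.03) log2fc jitter is
  added. Template frequencies were sized analytically — accounting for
  template overlap on a chromosome and the inflation from the latent
  propensity scaling — so the expected MAM genome fraction altered is
  ~17%, CRC ~0.6%, and cohort-level MYC gain / PTEN–FAS loss / CDKN2A
  loss rates are ~20/20/15%: these are the study conditions the
  generator emulates.
* Inverse burden relationship: latent per-sample propensities (z_mut,
  z_cna) are bivariate normal with correlation −0.8; z_mut scales TMB
  multiplicatively and z_cna shifts template log-odds and the focal
  noise rate, producing the negative association between mutation and
  CNA burden.
* Germline: carrier probability 0.04 per sample across the 14
  predisposition genes (≈20 carriers in 493), CHEK2 weighted at 0.2 so
  the planted codon-182 stop appears in ~4 cats; plus benign missense
  background so the screen has something to exclude.
* Viral: papillomavirus-like reads (150 bp, 1% uniform error, either
  strand) planted in configured fractions of the skin types and one
  FeLV-like plant as an exclusion control; background reads are random
  sequence.
* Determinism: a single root seed drives one generator per stage, with
  per-sample substreams derived by hashing sample identifiers, so output
  is byte-identical for a fixed seed and independent of sample order.

What passing tests on this cohort do **not** show about real data: the
generator has no purity or subclonality, no FFPE artifact spectrum, no
germline contamination of somatic calls, flat (not gene-specific)
passenger rates outside the UV signal, single-exon gene models, and
random rather than homologous sequence. Recovery results on it validate
the bookkeeping and the statistics under their stated assumptions, not
robustness to those real-data complications.

## Problem sizes and numerical choices

The shipped analyses run at the scales used by the test and acceptance
suites: the full synthetic cohort (493 samples, 978 genes) for
end-to-end checks; 100-gene, 100-sample cohorts for driver calibration
(10 null cohorts → ≥1000 gene-tests) and power (50 seeded cohorts with
5× missense enrichment in 5 genes); 100 seeded spectra of 1000 mutations
for exposure recovery; 200 random genes for the hotspot oracle and 1000
random variant sets for the burden oracle. NNLS is exact (active-set);
the refit residual is reported as the Euclidean distance. Ties are
resolved deterministically everywhere (lexicographic gene order in
rankings, lowest-index merges in clustering, first-best virus
assignment with true ties unassigned). Degenerate inputs — empty
cohorts, zero spectra, genes without coordinates, reads shorter than k —
return empty results or documented warnings rather than errors, except
where the input is unambiguously corrupt (negative footprint, positions
outside the reference, overlapping segments of one sample).

## Known limitations

The driver background ignores gene-level covariates (expression,
replication timing) that full dNdScv uses, so real-data calls should be
treated as a screen, not a verdict. Humanization is protein-level only;
codon-level (nucleotide) mapping and genomic liftover are out of scope.
The viral screen is presence/absence on containment, without assembly or
integration-site analysis. The actionability triage is only as good as
the supplied catalogs, and the shipped ones are deliberately tiny and
synthetic.
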