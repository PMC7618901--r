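Package: panfelis
Title: Feline Pan-Cancer Oncogenome Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pan-cancer analysis of targeted tumor-normal
    sequencing in the domestic cat: tumor mutational burden, recurrently
    mutated gene ranking and oncoplot matrices, protein hotspot detection,
    96-channel mutational-signature refitting with UV/hypermutator flagging,
    copy-number landscape classification (focal/broad gains and losses,
    1-Mb bin profiles, genome fraction altered, whole-chromosome calls,
    tumor-type clustering), the mutation/copy-number burden "hyperbola",
    a simplified context-aware dN/dS driver-gene selection test with BH
    correction, cross-species "humanization" of cat protein changes onto
    human ortholog coordinates, actionability and germline-predisposition
    triage against user-supplied catalogs, and k-mer containment screening
    of off-target reads for viral sequences. A synthetic cohort generator
    emulates the statistical structure of a 13-tumor-type feline cohort so
    that every stage is testable without access to controlled raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    pracma,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
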