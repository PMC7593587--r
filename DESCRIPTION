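Package: gcescan
Title: Detection of Genetic Code Expansion in Bacterial Genomes and
    Metatranscriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects stop-codon reassignment (genetic code expansion) in
    bacterial genome assemblies: two-pass gene prediction with a custom
    translation table in which the TAG amber codon is read through as
    pyrrolysine (O), conservation scoring of the sequence following the
    repurposed codon, cloverleaf scanning for pyrrolysine and
    selenocysteine tRNAs, detection of bacterial SECIS-like stem-loops
    downstream of in-frame TGA codons, and a translated homology screen
    of transcripts against the trimethylamine-metabolism pathway at a
    98 percent amino-acid identity threshold. Ships a synthetic-data
    generator that emits genomes and transcripts with a ground-truth
    manifest so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
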