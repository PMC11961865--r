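Package: tagtis
Title: T-DNA Integration Site Discovery from Tagmentation Bridge-PCR Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, types and reports T-DNA integration sites (TISs) in
    transgenic plant genomes from paired-end sequencing of Tn5
    tagmentation / bridge-primer enrichment libraries. Reads are aligned to a
    merged reference (plant genome plus a "tDNA" contig spanning the region
    between the left and right border repeats) either with a built-in
    seed-and-extend aligner or by parsing externally produced SAM/BAM; read
    pairs are classified as split, discordant or invalid, junction evidence is
    typed into the eight RefSide/border/direction insertion types, deduplicated
    by tagmentation fragment signature, clustered into supported calls,
    control-subtracted, and paired into full integration sites. Includes a
    library simulator with ground truth for end-to-end validation, PCR primer
    window recommendation, gene-context annotation of integration sites, and
    genomic safe harbor prediction by buffered interval exclusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    data.table,
    methods,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
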