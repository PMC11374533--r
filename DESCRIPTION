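Package: centromap
Title: Centromere Landscape Analysis from CENH3 ChIP Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to map functional centromeres and characterise their
    repeat landscape on telomere-to-telomere plant genome assemblies.
    Computes windowed CENH3 ChIP/input enrichment tracks and calls
    CENH3-enriched centromere domains; counts telomeric repeat copies at
    chromosome ends; discovers tandem satellite arrays de novo, builds
    monomer consensus sequences and groups them into CentFs-style
    families; scores repeat clusters for centromere association from
    ChIP versus input read alignment; analyses nucleosome phasing from
    fragment midpoints on satellite trimer consensus sequences; detects
    full-length LTR retrotransposons and dates insertions from LTR-LTR
    divergence (T = K / (2 r)). A synthetic-genome generator with full
    ground-truth annotation makes every stage testable without external
    data, and a pipeline driver produces per-chromosome summary reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    graphics,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
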