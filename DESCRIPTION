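Package: rlgl
Title: Design and In Silico Cloning of Dual-Reporter Enhancer Constructs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Construct-design computations for divergent dual-reporter
    ("red light/green light") enhancer assays: generation of
    regulatory-neutral spacer DNA by non-complementary transversion
    patterns, composition scrambling and tandem duplication; detection and
    certified elimination of forbidden motifs (IUPAC-degenerate
    transcription-factor binding sites) and restriction-enzyme recognition
    sites, with a codon-aware synonymous mode for coding sequences;
    scanning-block mutagenesis series for mapping remote-control elements;
    and an in silico cloning engine (restriction digestion with overhang
    chemistry, ligation with junction-scar tracking, PCR with tailed and
    degenerate primers, homology-arm assembly) that assembles and verifies
    annotated dual-reporter vector maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
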