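Package: plalign
Title: Partially Local Three-Way Alignment of Rearrangement Breakpoint
    Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Aligns a reference breakpoint region F against the two
    fragments L and R produced by a genome rearrangement, using a
    partially local three-way dynamic programming algorithm: global at
    the outer sequence ends, local toward the breakpoint, with an
    unscored suffix of L, an unscored prefix of R, and optionally an
    unpenalized internal interval of F.  The measured overlap of L and
    R on F (duplication remnant) or gap between them (deleted sequence)
    discriminates rearrangement mechanisms such as tandem duplication
    random loss.  Includes a synthetic-data generator and scoring
    parameter scan, breakpoint detection from signed gene orders,
    breakpoint-region extraction from annotated (circular) genomes with
    inversion handling, Stockholm and plain-text alignment writers, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Alignment, Genetics, SequenceMatching, Software
RoxygenNote: 7.3.3
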