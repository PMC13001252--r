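Package: tnsudoku
Title: Ordered Transposon Mutant Libraries from Combinatorially Pooled
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and decoding ordered transposon mutant
    libraries built by Knockout-Sudoku-style combinatorial pooling. Provides
    the four-axis plate/well pooling geometry, Monte Carlo estimation of
    mutagenesis saturation as a function of colonies picked, deconvolution of
    pooled sequencing read counts into plate/well coordinates by absolute-count
    and signal-to-noise thresholding followed by iterative triangulation,
    assembly of redundant and consolidated ordered collections with coverage
    and expected-accuracy statistics, and hit calling for crystal-violet
    microtiter biofilm screens. A fully parameterised synthetic-data module
    (genome, annotation, colony picking, pooled counts with a noise model)
    makes the whole pipeline exercisable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
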