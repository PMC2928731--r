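Package: virophase
Title: Haplotype Phasing and Molecular Evolution of Mixed Viral Sanger Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing short viral amplicons sequenced by the Sanger
    method, aimed at RNA viruses such as Drosophila C virus. Phases two
    co-infecting haplotypes from strand-consistent double peaks in
    chromatogram peak tables, fits nucleotide substitution models up to
    GTR+G+I with discrete-gamma rate heterogeneity by maximum likelihood
    (Felsenstein pruning, NNI hill-climbing search), compares nested models
    by likelihood ratio test and AIC, profiles per-site minimum mutational
    steps by Fitch parsimony with amino-acid-change flagging, tests for
    recombination with the pairwise homoplasy index (PHI) permutation test,
    bounds the synonymous mutation rate, and counts distinct haplotypes.
    Includes a coalescent-style simulator of trees, GTR+G+I alignments,
    two-haplotype mixture peak signals and missing-data patterns for
    validation, and a deterministic end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
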