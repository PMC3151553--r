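Package: phylodapp
Title: Directional Analysis of Phylogeographical Patterns and Haplotype
    Diversity on Distributional Islands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mitochondrial phylogeography of patchily distributed
    taxa: collapsing aligned multi-gene sequences into unique composite
    haplotypes, classifying private versus shared haplotypes, axial circular
    statistics on inter-locality bearings of haplotype sharing (Rayleigh,
    Rao spacing, Kuiper uniformity tests; Mardia-Watson-Wheeler and Watson
    U2 two-sample tests), haplotype-area curves over distributional islands,
    an equal-frequency urn estimator of haplotype sampling completeness,
    pairwise p and Kimura two-parameter divergence summaries, the
    McDonald-Kreitman neutrality test, and a synthetic-data generator that
    emulates clade-structured sequence data with controlled orientation
    patterns for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    geosphere,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
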