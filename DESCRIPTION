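Package: retroburst
Title: Annotation and Evolutionary Dynamics of LTR Retrotransposon Families
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for delimiting full-unit LTR retrotransposons around seed
    loci (terminal-repeat pair detection, TGT...ACA termini, 4-bp target site
    duplications), building family consensus elements (ORF prediction, 70%
    identity family clustering, tRNA primer-binding-site matching), and
    quantifying the evolutionary dynamics of retrotransposon copy sets:
    transition/transversion saturation (entropy-based Iss index with
    simulated critical values), F84 and p-distances, Tajima's D and Fu & Li's
    D/F neutrality tests, uncorrected codon-counting dN/dS with Mann-Whitney
    group comparisons, sliding-window divergence screens, and neighbor-joining
    trees with bootstrap support and monophyly classification. Includes a
    retrotransposon burst simulator with full ground truth so every stage of
    the pipeline is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
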