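Package: entsat
Title: Entropy-Based Test of Substitution Saturation in Nucleotide Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tests nucleotide sequence alignments for substitution saturation by
    comparing the per-site information content of observed site patterns against
    the entropy expected under a fully saturated multinomial model, either on all
    alignment sites or on parsimony-informative sites only. Includes a sequence
    evolution simulator (Jukes-Cantor and GTR+Gamma with invariant sites), a
    distance-based tree inference engine with Robinson-Foulds scoring, simulation
    machinery that calibrates critical values for the test statistic via ROC
    analysis, a regression model predicting critical values from the number of
    taxa and sequence length, and a batch screening tool for phylogenomic loci.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    phangorn,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
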