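Package: chronocompare
Title: Comparison of Divergence-Time Estimates Across Chronogram Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing panels of time-calibrated phylogenies
    (chronograms) produced under different relaxed molecular clock models
    and fossil calibration sets. Reads dated trees from Newick or NEXUS,
    extracts node ages, matches internal nodes shared across topologies,
    and computes per-source percentage deviations from group-mean node
    ages (D) together with pairwise mean age differences in absolute (P)
    and symmetric percentage (P%) form. Includes paired Wilcoxon
    signed-rank testing with Benjamini-Hochberg correction, classical
    multidimensional scaling of pairwise dissimilarities, validation of
    chronograms against min/max fossil calibration constraints, and a
    synthetic chronogram generator (Yule trees with lognormal age noise
    and controlled per-source bias) for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
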