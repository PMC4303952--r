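Package: probepair
Title: Concordance Analysis of Same-Gene Microarray Probeset Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reannotates Affymetrix-style probeset annotations into gene
    groups, selects genes measured by exactly two probesets, and classifies
    each pair by the joint behaviour of Pearson and Spearman correlations of
    tissue expression profiles into reliable, tissue-specific,
    isoform-specific, discordant and intermediate categories. Includes
    probe-level quality classification (green/yellow/red/black
    cross-hybridisation classes), group-level nonparametric comparisons
    (Kruskal-Wallis, Mann-Whitney with Bonferroni correction, Friedman test,
    Kendall's coefficient of concordance), mean and coefficient-of-variation
    concordance regressions by correlation-strength bin, and a synthetic
    tissue-expression generator with known ground-truth archetypes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
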