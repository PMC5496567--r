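Package: lakeweb
Title: Seasonal Food-Web Assembly and Analysis for Lake Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds monthly binary food webs for an idealized averaged year
    from incomplete multi-year community records, and analyses their seasonal
    structure. Provides a synthetic community generator with configurable
    two-season structure, a panel of qualitative network descriptors
    (connectance, link density, trophic-level statistics, generality and
    vulnerability, path length and clustering), nonmetric multidimensional
    scaling with Wisconsin double standardization and Bray-Curtis distances,
    permutation-tested environmental vector fitting, Sorensen link-pattern
    similarity with two-season partitioning of links, Bayesian
    (Dirichlet-multinomial) Shannon diversity with credible intervals, and
    Kruskal-Wallis seasonal contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
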