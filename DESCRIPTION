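Package: autumnsig
Title: Climate and Phylogenetic Drivers of Autumn Leaf Phenology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Attribution of variation in autumn leaf phenology (leaf
    coloring dates) to climatic and biological drivers. At the
    interannual scale the package determines, for each species and
    site, the optimal preseason window over which each of five daily
    climate variables (maximum and minimum temperature, precipitation,
    insolation, wind speed) best correlates with leaf coloring date,
    and then estimates partial correlations of each driver (plus spring
    first-leaf date) with the effects of the remaining drivers removed.
    At the species level it quantifies phylogenetic signal in mean leaf
    coloring date with Blomberg's K and a permutation test, and
    partitions interspecific variance into exclusive phylogenetic,
    exclusive native-climate, and shared components via phylogenetic
    eigenvector regression with adjusted R-squared decomposition.
    Includes synthetic-data generators (seasonal AR(1) climate, linear
    phenological responses, Yule trees, Brownian-motion traits,
    occurrence-climate samples) with known ground truth for validation,
    quality-control filters for observational series, linear trend
    estimation, and an end-to-end pipeline with CSV/Newick input and
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    phytools,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
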