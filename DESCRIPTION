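Package: culmforce
Title: Multiscale Analysis of Cereal Culm Lodging Resistance
Version: 0.1.0
Authors@R:
    person("Jan", "Keller", email = "jan.keller@posteo.net", role = c("aut", "cre"))
Description: Tools for studying the mechanical basis of lodging resistance in
    cereal stems (culms). Generates synthetic MRI-like label volumes of hollow
    culms with two helically inclined vascular-bundle rings, extracts bundle
    centerlines, counts and incline angles from such volumes, runs a
    cylindrical-voxel force-redistribution model with per-fibre axial/bending
    partitioning over 360 attack angles, performs FTIR cell-wall chemotyping by
    EMSC-style least-squares decomposition and PCA, and provides the trait
    statistics used in lodging studies (Welch and Mann-Whitney tests, Cohen's D
    with effect classes, moment-based normality checks, Pearson correlation,
    Mahmud-Kramer broad-sense heritability, fold changes and linkage-map
    summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
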