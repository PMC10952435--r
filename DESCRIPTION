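Package: granulofit
Title: Decomposition of Bimodal Starch Granule Size Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing binned particle size distributions of
    cereal endosperm starch, as measured on a Coulter counter. Decomposes
    volume-weighted bimodal distributions into a normal component (large
    discoid A-type granules) and a log-normal component (small spherical
    B-type granules) by constrained least squares on bin-integrated
    densities, derives phenotype metrics (mean A- and B-type granule
    diameters, B-type granule volume content, granule number per mg
    starch), aggregates biological replicates, and compares genotype
    groups with one-way ANOVA/Tukey, Kruskal-Wallis/Nemenyi or Welch
    t-tests summarised as compact letter displays. Includes a seeded
    synthetic granule-population generator emulating Coulter-counter
    measurements so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    grDevices,
    yaml
Suggests:
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
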