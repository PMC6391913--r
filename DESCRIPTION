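Package: qsep
Title: Quantifying Sub-Cellular Resolution in Spatial Proteomics
Version: 0.1.0
Authors@R: person("Maintainer", "Dev", email = "dev@example.org", role = c("aut", "cre"))
Description: Tools to assess how well a spatial proteomics experiment
    (LOPIT, hyperLOPIT, protein correlation profiling, dynamic organellar
    maps and related fractionation designs) resolves sub-cellular niches.
    The central statistic is QSep, the matrix of average between-cluster
    Euclidean distances of protein occupancy profiles normalised by the
    reference cluster's average within-cluster distance. The package
    provides a lightweight profile-matrix container with delimited-text
    input and output, marker-set hygiene (minimum cluster size filtering,
    cross-dataset marker transfer), raw and normalised cluster distance
    matrices with missing-value aware distances, experiment-wide summaries
    and comparisons, a class-removal robustness scan, PCA and profile
    visualisations, and a synthetic data generator with known ground
    truth. A command line interface wires these together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
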