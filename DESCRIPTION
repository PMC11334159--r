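Package: hypopack
Title: Spatial Packing Efficiency Analysis of Brain Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Models brain regions as packed spheres carrying a directed,
    weighted connectome and asks whether their spatial arrangement is
    efficient. Provides the neural efficiency metric (projection volume
    over distance, summed over ordered region pairs) and the wiring cost
    (summed pairwise distance); a constrained optimizer that repacks the
    spheres to maximize efficiency or minimize wiring cost under
    non-overlap constraints with random restarts; a rejection sampler
    that builds a geometry-matched random-packing null ensemble; ensemble
    statistics (percentile, z-score, shared-bin histograms) to locate an
    observed configuration on those distributions; small-world graph
    diagnostics; readers and writers for region tables, adjacency
    matrices and viral-tracing experiment records; and a synthetic-data
    generator producing hypothalamus-like instances for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
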