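Package: methanoflux
Title: Flux Balance Analysis and 13C Isotopomer Algebra for Methylotroph Central Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constraint-based flux balance analysis (FBA) with 13C-derived
    flux-ratio constraints for methylotroph central carbon metabolism, and the
    mass-isotopomer algebra that partitions de novo acetyl-CoA synthesis between
    pyruvate dehydrogenase (PDH) and malyl-CoA lyase (MCL) from citrate,
    threonine (oxaloacetate proxy) and malate labeling. Includes a bounded-variable
    simplex LP solver, metabolic-model I/O (JSON and delimited reaction tables),
    robustness and ratio-sensitivity scans, ATP-maintenance grids, scenario
    ladders, targeted-metabolomics volcano analysis, growth-rate and yield
    computations, and seeded synthetic-data generators for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
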