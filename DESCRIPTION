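Package: bonescreen
Title: Rapid-Throughput Multi-Parameter Skeletal Phenotype Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for rapid-throughput skeletal phenotyping of knockout
    mouse cohorts. Decomposes destructive 3-point bend load-displacement
    curves into stiffness, yield, maximum and fracture loads and an
    elastic/dissipated energy partition; calibrates radiographic grey-level
    histograms against phantom standards and compares bone mineral content
    distributions with the two-sample Kolmogorov-Smirnov statistic; builds
    wild-type reference ranges and standard-deviation distance screens;
    detects multivariate outlier strains with robust Mahalanobis distances
    from a minimum volume ellipsoid estimator; and assigns each strain to a
    four-category functional classification of bone strength. A synthetic
    cohort generator emulates the wild-type reference population and
    knockout strains with planted phenotypes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
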