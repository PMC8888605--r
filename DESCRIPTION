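Package: rgensi
Title: Correlation in Genetic Signals Between Partners, Siblings and In-Laws
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structural-equation modelling of assortative mating from
    polygenic scores and phenotypes of linked family members. Quantifies
    measurement-error-free genetic and phenotypic resemblance between
    partners, siblings, siblings-in-law and co-siblings-in-law by path
    tracing with co-paths, discriminates direct from indirect assortment,
    fits model variants to raw family data by full-information maximum
    likelihood with profile-likelihood confidence intervals, and tests
    intergenerational genetic equilibrium. Includes an agent-based
    mate-matching simulator for model validation and a forward-in-time
    mating simulator for additive-variance dynamics under assortment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
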