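Package: InterCriteria
Title: InterCriteria Analysis for Pairwise Performance Comparison of Criteria
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements InterCriteria analysis (ICrA), a multi-criterion
    decision-making method that evaluates the relation between every pair of
    criteria over a common set of objects as an intuitionistic fuzzy pair
    <mu, nu> of agreement and disagreement degrees, computed from concordant
    and discordant comparisons across all object pairs. Provides consonance/
    dissonance classification under configurable threshold schemes (the
    classical quarters scale and a thirds scale with an explicit uncertainty
    class), systematic threshold sweeps, juxtaposition with Pearson
    correlation, and a Gaussian-copula generator of docking-output-like
    evaluation matrices with controllable pairwise concordance. Ships the
    published agreement degrees for five molecular-docking scoring functions
    across four docking outputs as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'InterCriteria-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'indexMatrix.R'
    'icra.R'
    'consonance.R'
    'sweep.R'
    'correlation.R'
    'synthetic.R'
    'fixtures.R'
    'cli.R'
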