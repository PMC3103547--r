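Package: satmut
Title: Structure-Based Saturation Mutagenesis and Site-Mutability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: In-silico mutability analysis of protein mutation sites:
    backbone-preserving computational saturation mutagenesis, folding and
    binding free-energy change estimation with a simplified molecular-mechanics
    potential (Lennard-Jones, Coulomb, Still-type Generalized-Born solvation)
    under several named parameter sets, Monte-Carlo protein titration with
    pKa-shift bookkeeping, and Z-score/half-standard-deviation classification
    of sites into tolerance and specificity categories. Includes a synthetic
    structure generator (homodimer with loop, interface and buried site
    archetypes) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
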