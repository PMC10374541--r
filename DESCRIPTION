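Package: diallelGS
Title: Genomic Selection for Hybrid Performance in Half-Diallel Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluation of hybrid performance in plant breeding via genomic
    selection. Fits a GBLUP model with additive plus dominance effects to a
    training population of hybrids using a Bayesian Gibbs sampler for the
    variance components, predicts genomic estimated breeding values (GEBVs)
    for every hybrid combination of a half diallel mating design, and derives
    GEBV-based general and specific combining abilities, mid-parent heterosis
    and better-parent heterosis to rank candidate hybrids and parental lines.
    Includes marker quality control for inbred parental panels, genomic
    relationship matrices with numerically safe inversion, a synthetic-data
    generator, a variance-component simulation harness and a k-fold
    cross-validation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), vcfR, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
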