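Package: diallelkit
Title: Frequentist and Bayesian Analysis of Full Diallel Mating Designs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for multi-environment full diallel experiments: Griffing's
    Method I (and Method III) fixed-effects combining-ability analysis with a
    genotype-by-environment extension, chained-equations multiple imputation by
    predictive mean matching with Rubin's-rules pooling, a Bayesian hierarchical
    diallel mixed model (additive, inbred, maternal, and cross-specific effect
    classes) fit by Gibbs sampling, posterior degree-of-dominance and diallel
    variance-projection summaries, hybrid rankings with highest-posterior-density
    intervals, and GGE-biplot tester selection.  Includes a synthetic-data
    generator with the full effect structure for simulation studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), coda, jsonlite, MASS, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
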