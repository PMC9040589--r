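Package: crossfeedr
Title: Inference of Microbial Cross-Feeding Networks from Dynamic Exometabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers metabolic cross-feeding networks in defined microbial
    communities from time-resolved exometabolome profiles of monocultures
    grown in fresh and spent media. Provides accurate-mass annotation of
    deprotonated ions against a formula database, four-parameter logistic
    growth-curve fitting, statistical calling of consumed and secreted
    metabolites from intensity time courses (OD correlation, linear and
    exponential fits, dilution-series-calibrated fold-change thresholds),
    construction of producer-consumer-metabolite interaction networks with
    public/private-good classification and enrichment statistics, carbon-
    and nitrogen-atom mass-flow networks, detection of gut metabolic modules
    from ortholog lists, and a seeded synthetic-data generator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
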