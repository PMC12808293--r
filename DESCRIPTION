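Package: recatmem
Title: Exemplar Forgetting Models of Category Learning Under Uniform and
    Power-Law Presentation Schedules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how environmental recency statistics shape
    category-learning curves and model comparisons. Generates rule-plus-exception
    binary-feature category structures and nonsense-word renderings, builds
    uniform (permutation-block) and power-law presentation schedules with recency
    diagnostics (need odds, mean delay, presentation counts), and implements four
    classification models over a growing exemplar store: a prototype model, a
    generalized-context-model exemplar model, an exemplar model with power-law
    memory decay, and a prototype-exemplar mixture. Includes constrained
    maximum-fit estimation under aggregated sum-squared-error and trial-level
    mean-squared-error objectives, Bernoulli response simulation from any model
    family, and model-recovery analyses (accuracy by segment and item type,
    fit partitions by exception status, mixture-versus-forgetting comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
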