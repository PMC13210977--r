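Package: mechadapt
Title: Mechanization-Adaptability Evaluation of Processing Pepper Varieties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trait-based evaluation of processing pepper (Capsicum annuum)
    varieties for suitability to mechanized transplanting and harvesting.
    Implements a 21-indicator registry spanning seedling and harvest stages,
    formula-level trait scoring (substrate disintegration rate, lodging grade,
    fruit uniformity coefficients of variation, fruit setting position),
    variation and diversity summaries, CRITIC objective weighting from
    contrast intensity and inter-indicator conflict, VIKOR compromise ranking
    by group utility and individual regret, and auxiliary multivariate
    analyses (hierarchical clustering, principal components with comprehensive
    scores, Pearson correlation reports). A synthetic-cohort generator draws
    variety trait matrices from truncated normal marginals, optionally coupled
    through a Gaussian copula, so the full pipeline is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
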