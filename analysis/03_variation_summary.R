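#!/usr/bin/env Rscript
# Variation and diversity analysis: per-indicator max/min/mean/SD/CV tables
# for both cohorts, and the ranking of indicators by CV — biomechanical
# traits are expected to vary far more than morphological ones.

library(mechadapt)

dir.create("results", showWarnings = FALSE)

for (grp in c("erect", "pendent")) {
  x <- read_trait_matrix(file.path("results/cohorts", paste0(grp, "_traits.csv")),
                         group = grp)
  s <- summarize_traits(x)
  write_trait_summary(s, file.path("results", paste0(grp, "_variation.csv")))
  top <- s[order(-s$cv_percent), ][1:5, c("code", "cv_percent")]
  cat(sprintf("%s cohort, top-5 CV indicators: %s\n", grp,
              paste(sprintf("%s %.1f%%", top$code, top$cv_percent),
                    collapse = ", ")))
}
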