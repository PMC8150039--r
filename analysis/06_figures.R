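#!/usr/bin/env Rscript
# Stage 6 — figures.
#
# Specification curve with decision panel, per-decision box plots, and the
# decomposed-variance bar chart.

library(specwell)

results <- read_survey("results/curve_results.csv")
results$degenerate <- as.logical(results$degenerate)
results$coefs <- replicate(nrow(results), NULL, simplify = FALSE)

plot_specification_curve(results, "results/specification_curve",
                         formats = c("png", "svg"))
plot_choice_boxplots(results, "results/choice_boxplots",
                     formats = c("png", "svg"))
vc <- decompose_variance(results)
vc_red <- rerun_without_predictor(results, "odba")
plot_variance_shares(vc, vc_red, path = "results/variance_shares",
                     formats = c("png", "svg"))
cat("figures written under results/\n")
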