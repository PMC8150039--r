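#!/usr/bin/env Rscript
# Stage 4 — the specification curves.
#
# Fits all 3 x 9 x 18 x 2 = 972 justifiable regressions of well-being on
# dysregulated-gaming severity, then the 3 x 15 x 18 x 2 = 1620 single-item
# models (DSM-5/ICD-11 items as predictors). Writes flat per-model results
# and per-variable summary tables (median/min/max beta, median-model CI,
# median semipartial R2).

library(specwell)

scored <- read_survey("results/scored.csv")
scored$outlier <- as.logical(scored$outlier)
scored$gender <- factor(scored$gender, levels = c("female", "male", "other"))
scored$education <- factor(scored$education, levels = c("tertiary", "secondary"))

space <- build_default_space(scored)
results <- run_curve(scored, space, covariate_stats = TRUE)
write.csv(dplyr::select(results, -coefs), "results/curve_results.csv",
          row.names = FALSE)

overall <- summarize_curve(results)
write.csv(overall, "results/curve_overall.csv", row.names = FALSE)
cat(sprintf("%d models: median beta %.3f [%.3f, %.3f], range %.3f to %.3f; %.1f%% significant\n",
            overall$n_models, overall$median_beta, overall$ci_lo,
            overall$ci_hi, overall$min_beta, overall$max_beta,
            100 * overall$frac_significant))

tab <- summarize_curve_table(results, space)
write.csv(tab, "results/curve_summary.csv", row.names = FALSE)

ispace <- build_default_space(scored, item_level = TRUE)
iresults <- run_curve(scored, ispace, covariate_stats = FALSE)
write.csv(dplyr::select(iresults, -coefs), "results/item_curve_results.csv",
          row.names = FALSE)
isum <- summarize_curve_table(iresults, ispace)
isum <- isum[order(isum$median_beta), ]
write.csv(isum, "results/item_curve_summary.csv", row.names = FALSE)
cat("strongest single-item predictor:", isum$variable[1],
    sprintf("(median beta %.3f)\n", isum$median_beta[1]))
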