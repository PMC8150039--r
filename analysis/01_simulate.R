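#!/usr/bin/env Rscript
# Stage 1 — simulate the survey.
#
# Generates the default synthetic study: 743 Dutch/Flemish-style gamer survey
# starters with latent dysregulation and well-being constructs, Likert items
# from factor loadings with threshold discretization, page-level dropout
# (38.9%), careless check-failers among completers (6.6%) and extreme-playtime
# outliers (~5% of the cleaned sample). Writes the raw respondent table and
# the ground-truth record.

library(specwell)

seed <- 20240424
dir.create("results", showWarnings = FALSE)

cfg <- survey_config(seed = seed)
survey <- generate_survey(cfg)
write_survey(survey, "results/survey.csv", "results/ground_truth.json")

cat("simulated", nrow(survey$data), "respondents;",
    sum(survey$truth$labels$dropout), "dropouts,",
    sum(survey$truth$labels$careless), "careless,",
    sum(survey$truth$labels$outlier), "playtime outliers\n")
cat("observed-scale effect targets (D vs W1..W3):",
    paste(cfg$latent_corr["D", c("W1", "W2", "W3")], collapse = ", "), "\n")
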