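#!/usr/bin/env Rscript
# Stage 2 — cleaning cascade and scoring.
#
# Removes incomplete respondents, then attention-check failers; scores the
# nine dysregulated-gaming operationalizations, the three well-being outcomes
# (depressive mood reversed), weekly game time (5 x weekday + 2 x weekend),
# and flags playtime outliers (>= mean + 3 SD weekly hours or session
# minutes, or zero weekly hours).

library(specwell)

raw <- read_survey("results/survey.csv")
cl <- clean_dataset(raw)
print(cl$report)
jsonlite::write_json(unclass(cl$report)[1:7], "results/cleaning_report.json",
                     auto_unbox = TRUE, pretty = TRUE)

scored <- score_dataset(cl$data)
write.csv(scored, "results/scored.csv", row.names = FALSE)
cat("scored", nrow(scored), "respondents;", sum(scored$outlier),
    "flagged as playtime outliers\n")

write.csv(as.data.frame(correlation_matrix(scored)),
          "results/correlation_matrix.csv")
cat("zero-order correlations written (outlier-excluded sample)\n")
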