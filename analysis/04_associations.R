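#!/usr/bin/env Rscript
# Individual-differences battery: the 12-factor x 2-shape-parameter
# correlation grid (Pearson/Spearman by scale type, Bonferroni m = 24) and
# the exploratory per-group regressions of shape parameters on Stroop and
# N-back scores. Reads results/shape_params.csv and results/cohort/.

suppressPackageStartupMessages(library(pupilci))

cohort <- read_cohort("results/cohort")
shapes <- read.csv("results/shape_params.csv")

events <- cohort$events
behavior <- aggregate(cbind(prop_correct = keywords_correct / n_keywords,
                            tlx_mean = tlx_score) ~ participant_id,
                      data = events, FUN = mean)

cors <- correlation_table(cohort$profiles, shapes, behavior, m = 24)
write.csv(cors, "results/correlation_table.csv", row.names = FALSE, na = "")

groups <- shapes[, c("participant_id", "wordgroup")]
mods <- moderated_regressions(shapes, cohort$profiles, groups)
write.csv(mods, "results/moderated_regressions.csv", row.names = FALSE, na = "")

cat("correlation battery (", nrow(cors), "cells, Bonferroni m = 24 ):\n")
print(cors[order(cors$p), ], digits = 3, row.names = FALSE)
sig <- cors[cors$significant, ]
cat("\nsignificant after correction:",
    if (nrow(sig)) paste(sig$factor, "vs", sig$target, collapse = "; ")
    else "none", "\n")
cat("\nexploratory per-group regressions written to results/moderated_regressions.csv\n")
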