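#!/usr/bin/env Rscript
# Group-level psychometric models: SNR-condition and polynomial (linear +
# quadratic) mixed models of PPD, logistic mixed models of keyword accuracy
# and NASA-TLX, and the word-recognition median-split interaction analysis.
# Reads results/cell_means.csv and results/cohort/, writes model summaries
# and per-participant shape parameters.

suppressPackageStartupMessages(library(pupilci))

cells <- read.csv("results/cell_means.csv")
cohort <- read_cohort("results/cohort")

cond <- fit_condition_model(cells)
poly <- fit_polynomial_model(cells)
acc <- fit_accuracy_model(cohort$events)
tlx <- unique(cohort$events[, c("participant_id", "snr", "tlx_score")])
names(tlx)[3] <- "tlx"
tlxm <- fit_tlx_model(tlx)
wg <- wordgroup_analysis(cells, cohort$profiles)

cat("== SNR condition effect on PPD ==\n"); print(cond$lrt, row.names = FALSE)
cat("\n== polynomial shape of PPD over SNR ==\n"); print(poly$lrt, row.names = FALSE)
print(poly$fixed_effects, digits = 3, row.names = FALSE)
cat("\n== SNR effect on keyword accuracy (logistic) ==\n")
print(acc$lrt, row.names = FALSE)
cat("\n== SNR effect on NASA-TLX (logit scale) ==\n")
print(tlxm$lrt, row.names = FALSE)
cat("\n== SNR x word-group interaction on PPD ==\n")
print(wg$interaction$lrt, row.names = FALSE)

shapes <- merge(shape_table(cells), wg$groups, by = "participant_id")
write.csv(shapes, "results/shape_params.csv", row.names = FALSE, na = "")

to_list <- function(f) list(family = f$family, formula = f$formula_descr,
                            singular = f$singular,
                            fixed_effects = f$fixed_effects, lrt = f$lrt,
                            posthoc = f$posthoc)
jsonlite::write_json(
  list(condition = to_list(cond), polynomial = to_list(poly),
       accuracy = to_list(acc), tlx = to_list(tlxm),
       wordgroup_interaction = to_list(wg$interaction),
       wordgroup_covariate_tests = wg$covariate_tests),
  "results/model_summaries.json", auto_unbox = TRUE, digits = NA,
  dataframe = "rows", na = "null")
cat("\nshape parameters and model summaries written under results/\n")
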