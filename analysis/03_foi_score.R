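#!/usr/bin/env Rscript
# Stage 3: score and classify the simulated FOI table, summarise class
# counts by stratum, and characterise the score distribution.

suppressPackageStartupMessages(library(whaledens))

foi <- read_foi_table("results/simulated/foi.csv")
counts <- classified_counts(foi$label)
message(sprintf("%d FOIs: %d definite, %d probable, %d unclassified",
                counts$n_total, counts$n_definite, counts$n_probable,
                counts$n_unclassified))

strat <- stratify_counts(foi)
print(strat)

nb <- fit_score_distribution(foi$C_s)
message(sprintf("negative-binomial score fit: mu = %.2f, size = %.2f (AIC %.1f)",
                nb$mu, nb$size, nb$aic))

# classification concordance against the ground truth kept by the generator
truth <- read.csv("results/simulated/foi_truth.csv")$is_whale
dp <- foi$label %in% c("definite", "probable")
message(sprintf("definite+probable captures %.0f%% of true whales; %.1f%% of clutter crosses the threshold",
                100 * mean(dp[truth]), 100 * mean(dp[!truth])))

dir.create("results/foi", showWarnings = FALSE, recursive = TRUE)
write_table_csv(foi[c("foi_id", "C_s", "label", "sea_state", "stratum")],
                "results/foi/scored.csv")
write_table_csv(strat, "results/foi/stratified_counts.csv")
jsonlite::write_json(c(unclass(counts), nb = list(nb)),
                     "results/foi/counts.json", auto_unbox = TRUE, digits = NA)
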