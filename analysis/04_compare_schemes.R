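#!/usr/bin/env Rscript
# Statistical comparison of the schemes per species: Shapiro-Wilk normality
# on each metric sample, Levene homoscedasticity across each pair, then a
# pooled-variance t-test or a Wilcoxon-Mann-Whitney test at alpha = 0.05.
# Also tabulates the TSS thresholds and the five-class areas of the maps.
# Reads the study report written by 03_fit_models.R.

library(tgbsdm)

report <- readRDS("results/study_seed1/report.rds")

cmp <- report$comparisons
cat("Pairwise comparisons (cascade-selected tests):\n")
print(cmp[, c("species", "metric", "scheme_a", "scheme_b", "test_used",
              "statistic", "p_value", "significant")],
      row.names = FALSE, digits = 3)

sig_dev <- cmp[cmp$metric == "DEVIANCE" & cmp$significant, ]
cat(sprintf("\n%d of %d deviance comparisons are significant at 0.05\n",
            nrow(sig_dev), sum(cmp$metric == "DEVIANCE")))
sig_auc <- cmp[cmp$metric == "AUC" & cmp$significant, ]
cat(sprintf("%d of %d AUC comparisons are significant at 0.05\n",
            nrow(sig_auc), sum(cmp$metric == "AUC")))

cat("\nTSS thresholds (max-TSS rule and 10th-percentile rule):\n")
print(read.csv("results/study_seed1/tss.csv"), row.names = FALSE, digits = 3)

cat("\nDominant suitability class per combination:\n")
areas <- read.csv("results/study_seed1/class_areas.csv")
for (key in unique(paste(areas$species, areas$scheme))) {
  a <- areas[paste(areas$species, areas$scheme) == key, ]
  i <- which.max(a$percent)
  cat(sprintf("  %-30s class %.1f-%.1f: %.0f ha (%.1f%%)\n", key,
              a$lower[i], a$upper[i], a$extent_ha[i], a$percent[i]))
}
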