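#!/usr/bin/env Rscript
# Build the synthetic study system: a 20 x 20 landscape of eight correlated
# environmental layers and a four-species amphibian-like community totalling
# 320 occurrence records (focal species with 73, 24 and 55 presences plus a
# filler group), every species on its own raster cells. Writes the layers as
# ESRI ASCII grids and the pooled occurrence table as CSV.

library(tgbsdm)

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- study_config(seed = seed)
stack <- make_env_stack(cfg$n_rows, cfg$n_cols, cfg$n_layers,
                        cfg$layer_correlation, seed = seed)
group <- make_target_group(stack, cfg$species, seed = seed + 101)

print(stack)
print(group)

for (nm in stack$layer_names)
  write_ascii_grid(stack, file.path(out, paste0(nm, ".asc")), layer = nm)
write_occurrences(group, file.path(out, "occurrences.csv"))

cm <- cor(sapply(stack$layers[setdiff(stack$layer_names,
                                      c("SLOPE", "ASPECT"))], as.vector))
cat(sprintf("\nmean pairwise correlation of the climatic layers: %.2f\n",
            mean(cm[upper.tri(cm)])))
cat("wrote", length(stack$layer_names), "layers and",
    group$D, "occurrence records to", out, "\n")
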