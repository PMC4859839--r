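#!/usr/bin/env Rscript
# Stage 5: statistics over interaction-energy component tables.
#
# Recomputes the rank-correlation matrix and the covalency-ratio
# classification from the packaged per-residue component table (the
# published pocket decomposition), then applies the same machinery to the
# model-dimer components computed in stage 4.

suppressMessages(library(pocketEDA))
dir.create("results", showWarnings = FALSE)

table2 <- read_component_table(
  system.file("extdata", "table2.csv", package = "pocketEDA"))

cat("== rank correlations over the 15 pocket residues ==\n")
cm <- correlation_table(table2)  # ADP/NICO ligand sub-fragments excluded
print(cm)
write.csv(round(unclass(cm), 4), "results/component_correlations.csv")

cat("\n== covalency classification of the hydrogen-bonded complexes ==\n")
distances <- with(read.csv(system.file("extdata", "table4_distances.csv",
                                       package = "pocketEDA")),
                  setNames(distance, label))
rep4 <- covalency_report(table2, labels = names(distances),
                         distances = distances)
print(rep4, row.names = FALSE)
write.csv(rep4, "results/covalency_report.csv", row.names = FALSE)

model_path <- "results/model_dimer_components.csv"
if (file.exists(model_path)) {
  cat("\n== covalency ratios of the stage-4 model dimers ==\n")
  model <- read_component_table(model_path, additivity_tol = 1e-6)
  print(covalency_report(model), row.names = FALSE)
} else {
  cat("\n(stage-4 output not found; run analysis/04_dimer_eda.R first)\n")
}
cat("\nwrote results/component_correlations.csv,",
    "results/covalency_report.csv\n")
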