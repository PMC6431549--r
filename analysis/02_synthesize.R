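#!/usr/bin/env Rscript
# Generates the synthetic study region used by the rest of the workflow:
# a 100x100 five-class landscape with autocorrelated patches, the six
# driver rasters, and a 10-year history simulated under the known annual
# transition matrix with a planted road-attraction effect on degradation.

suppressPackageStartupMessages(library(lulcsim))

cfg <- synth_config(nrow = 100, ncol = 100, n_years = 10, seed = 20260920L)
bundle <- write_synth_bundle(cfg, "results/synthetic_bundle")

land <- bundle$landscape
cat("Generated landscape class shares:\n")
print(round(table(unname(land$class_labels)[land$values]) /
              length(land$values), 3))
cat("Requested:\n")
print(cfg$shares)
cat(sprintf("\nHistory: %d annual steps; %d maps written to %s\n",
            cfg$n_years, cfg$n_years + 1, "results/synthetic_bundle"))
cat("True annual matrix:\n")
print(round(cfg$true_matrix$P, 4))
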