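#!/usr/bin/env Rscript

## Stage 3 — stability. At the threshold-voltage equilibrium, sweep the
## constant external drive injected into the interneuron pairs and find the
## current at which the Jacobian's leading eigenvalue turns positive, for
## both chemical models on integer and binary edges. The gap model's
## Jacobian (-alpha_leak I - alpha_gap L) does not depend on the drive, so
## it never destabilizes.

suppressPackageStartupMessages(library(fibersync))
dir.create("results", showWarnings = FALSE)

fx <- locomotion_fixture(1L)
targets <- c("AVBL", "AVBR", "PVCL", "PVCR", "RIBL", "RIBR")
I_max <- 100e-12

rows <- list()
for (model in c("chem1", "chem2")) {
  for (weighted in c(TRUE, FALSE)) {
    net <- fx$network
    if (!weighted) {
      e <- net$edges; e$weight <- 1
      net <- locomotion_network(e, nodes = net$nodes)
    }
    rep <- instability_threshold(net, model_params(model), targets,
                                 I_max = I_max, step = 0.5e-12)
    rows[[length(rows) + 1L]] <- data.frame(
      model = model, edge_type = if (weighted) "integer" else "binary",
      targets = "interneuron pairs",
      threshold_pA = if (is.na(rep$threshold)) NA else rep$threshold * 1e12)
  }
}
gap <- instability_threshold(fx$network, model_params("gap"), targets)
rows[[length(rows) + 1L]] <- data.frame(
  model = "gap", edge_type = "integer", targets = "interneuron pairs",
  threshold_pA = NA)

tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/stability.csv", row.names = FALSE)
cat("Instability thresholds of the external drive (NA = stable up to the scan\n")
cat(sprintf("ceiling of %g pA; the gap model is drive-independent):\n", I_max * 1e12))
print(tab, row.names = FALSE)
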