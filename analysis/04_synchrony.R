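#!/usr/bin/env Rscript

## Stage 4 — dynamics vs structure. Two simulation settings on the fixture:
## free-running from randomized initial conditions (no stimulus), and driven
## at 90% of the instability threshold plus a 5% sinusoid through the
## interneuron pairs (2 Hz; gap runs get a second 1 Hz motor-neuron drive to
## break their global synchrony). The last second's LoS matrix is binarized
## and compared against the fiber partition's ideal block matrix; zero
## agreement = perfect fiber separation, negative = extra cross-fiber
## synchrony (allowed by the theory), positive would falsify the partition.

suppressPackageStartupMessages(library(fibersync))
dir.create("results", showWarnings = FALSE)
seed <- 1L

fx <- locomotion_fixture(seed)
net <- fx$network
col <- fx$coloring
duration <- 3

rows <- list()
for (model in c("gap", "chem1", "chem2")) {
  params <- model_params(model)

  ## free running (test-1 style)
  pr1 <- simulation_protocol(1, net, col, params)
  sim1 <- simulate_network(net, params, pr1$stimulus, init = pr1$init(seed),
                           duration = duration)
  los1 <- los_matrix(sim1, window = 1)
  sc1 <- agreement_score(los1, ideal_matrix(col, order = rownames(los1)))

  ## driven below instability (test-2 style)
  I_star <- if (model == "gap") 10e-12 else {
    rep <- instability_threshold(net, params,
                                 c("AVBL", "AVBR", "PVCL", "PVCR", "RIBL", "RIBR"),
                                 I_max = 100e-12, step = 0.5e-12)
    if (is.na(rep$threshold)) 100e-12 else rep$threshold
  }
  pr2 <- simulation_protocol(2, net, col, params, I_star = I_star)
  sim2 <- simulate_network(net, params, pr2$stimulus, duration = duration,
                           seed = seed)
  los2 <- los_matrix(sim2, window = 1)
  sc2 <- agreement_score(los2, ideal_matrix(col, order = rownames(los2)))
  utils::write.csv(format(unclass(los2), digits = 8),
                   sprintf("results/los_driven_%s.csv", model))

  rows[[length(rows) + 1L]] <- data.frame(
    model = model, I_star_pA = I_star * 1e12,
    agreement_free = sc1, agreement_driven = sc2)
}

tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/synchrony_scores.csv", row.names = FALSE)
cat("Agreement between simulated LoS and the fiber partition\n")
cat("(0 = exact fiber separation, negative = fibers synchronizing together):\n")
print(tab, row.names = FALSE)
stopifnot(all(tab$agreement_driven <= 0))
cat("\nNo positive score: the dynamics never split a predicted fiber.\n")
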