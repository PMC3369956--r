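#!/usr/bin/env Rscript
# Simulate the pooled competitive-growth experiment: a genome-scale deletion
# collection (4607 strains, 5% zinc-sensitive and 5% apparently resistant at
# mean effect 0.3 doublings/generation) grown for 15 pool generations in
# treatment (zinc-limiting) and control (zinc-replete) media, four replicate
# cultures each, with a serial-dilution bottleneck at generation 8, then
# read out as barcode-array log2 signals.
#
# Writes: results/pool_truth.tsv, results/signals.tsv

library(dssa)

dir.create("results", showWarnings = FALSE)
seed <- 20120607

truth <- make_truth(4607, frac_sensitive = 0.05, frac_resistant = 0.05,
                    effect_size = 0.3, seed = seed)
write_pool_truth(truth, "results/pool_truth.tsv")

signals <- simulate_experiment(
  truth, generations = 15, n_replicates = 4, inoculum_per_strain = 1600,
  bottleneck = list(size = 1.5e7, at = 8),
  affinity_sd = 1, noise_sd = 0.25, seed = seed
)
write_signal_matrix(signals, "results/signals.tsv")

cat(sprintf(
  "Simulated %d strains (%d sensitive, %d resistant, %d neutral)\n",
  nrow(truth), sum(truth$true_call == "sensitive"),
  sum(truth$true_call == "resistant"), sum(truth$true_call == "neutral")
))
cat(sprintf("Signal matrix: %d strains x %d arrays -> results/signals.tsv\n",
            nrow(signals$values), ncol(signals$values)))
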