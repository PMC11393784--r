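#!/usr/bin/env Rscript

# Step 1: generate the synthetic GWAS "cohorts" every later step consumes.
#
# One exposure -> mediator -> outcome causal chain at the default study
# conditions (100 exposure loci, 100 mediator loci, 100 outcome loci,
# samples of 100,000 each, kappa = 0.4, theta_M = 0.5, theta_dir = 0.1, so
# the true mediated proportion is 2/3), plus a block LD structure so the
# clumping step has real work to do.

suppressMessages(library(twostepmr))

out_dir <- "results/sim"
cf <- chain_sim_config(seed = 20260901L)
sim <- simulate_chain(cf)
blocks <- simulate_ld_blocks(cf, block_size = 3, within_r2 = 0.8)

sim$exposure <- set_variant_positions(sim$exposure, blocks$positions)
sim$mediator <- set_variant_positions(sim$mediator, blocks$positions)
sim$outcome <- set_variant_positions(sim$outcome, blocks$positions)

write_chain(sim, out_dir, ld = blocks$ld)

message(sprintf("simulated %d variants per trait into %s", nrow(sim$exposure), out_dir))
message(sprintf("generative truth: theta_total = %.3f, mediated proportion = %.1f%%",
                sim$truth$theta_total, 100 * sim$truth$proportion_true))
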