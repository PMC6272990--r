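#!/usr/bin/env Rscript
# Step 1 — generate the working dataset.
#
# The study's raw gel scores were never deposited, so the workflow runs on a
# synthetic band matrix drawn under the study design: 20 accessions of the
# published *Dactylis glomerata* panel (9 subspecies, 196 diploids in groups
# of 9-10), 21 SSR + 15 IT-ISJ primers with 3-13 scored bands each, and
# Balding-Nichols among-accession divergence F = 0.2.  The truth table
# (per-population dominant-allele frequencies) is written alongside so any
# downstream estimate can be checked against it.

library(bandpop)

seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 20L
cfg <- sim_config(seed = seed)
sim <- simulate_band_matrix(cfg)
print(sim)

dir <- "results/data"
write_simulation(sim, dir)
cat("wrote", paste(list.files(dir), collapse = ", "), "to", dir, "\n")
cat(sprintf("band presence overall: %.3f; polymorphic bands: %d/%d\n",
            mean(sim$matrix$values),
            sum(polymorphism_summary(sim$matrix)$NPB),
            ncol(sim$matrix$values)))
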