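#!/usr/bin/env Rscript
# Simulate the study cohort: 15 donors varying in amyloid/tau pathology and
# APOE/TREM2 genotype, four nucleus populations (protoplasmic and fibrous
# astrocytes plus two doublet classes) with a latent reactivity axis in the
# protoplasmic nuclei and planted 52-up / 144-down gene programs.
library(astrotraj)

cfg <- simulation_config(seed = 1L)
ds <- simulate_dataset(cfg)
write_dataset(ds, "results/data")

print(ds)
sig <- truth_signature(ds)
cat(sprintf("planted programs: %d up, %d down (+%d weak co-varying genes)\n",
            length(sig$up), length(sig$down), cfg$n_weak))
cat(sprintf("amyloid-positive donors: %d of %d; planted reactivity shift %.3f\n",
            cfg$amyloid_positive, cfg$n_samples, cfg$amyloid_shift))
cat("wrote results/data (MTX + TSV + truth + manifest)\n")
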