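#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-farm herd that the rest of the
# workflow analyses. The configuration defaults define the study
# conditions: 8 farms x 40 founder cows, three pedigree generations,
# monthly milk recording, UK-like seasonal weather, and an injected
# in-utero effect of -5 LRS points per unit of mean trimester-3 THI_max.
library(resilherd)

cfg <- sim_config(seed = 1L)
sim <- simulate_herds(cfg)
write_herd_csvs(sim, "results/herd")

cat("Simulated", nrow(sim$cows), "cows on", cfg$n_farms, "farms:",
    sum(sim$truth$cows$generation == 1), "founders,",
    sum(sim$truth$cows$generation == 2), "daughters,",
    sum(sim$truth$cows$generation == 3), "granddaughters\n")
cat(nrow(sim$calvings), "calvings,", nrow(sim$milk), "milk recordings,",
    nrow(sim$events), "recorded events,", nrow(sim$weather),
    "station-days of weather\n")
cat("Herd tables written to results/herd/\n")
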