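#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study with known ground truth.
#
# Emulates a four-otter FGM monitoring study: opportunistic fecal sampling
# over multi-year spans (233/122/72/60 samples per animal), lognormal
# per-animal baselines for the cortisol- and corticosterone-immunoreactive
# metabolites, three injected acute and one three-day chronic 5-SD stress
# event per animal (both metabolites), notes for 39% of events plus
# decoys, and the full EIA plate layer (duplicate wells, 4PL response,
# 4% multiplicative OD noise, jittered extraction masses).

library(fgmassay)

seed <- 20160101 %% 2^31
out_dir <- "results/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

sim <- sim_defaults()
truthed <- simulate_series(sim = sim, seed = seed)
plates <- simulate_study_plates(truthed$series, sim = sim, seed = seed)

write.csv(plates$layout, file.path(out_dir, "layout.csv"), row.names = FALSE)
write.csv(plates$od, file.path(out_dir, "od.csv"), row.names = FALSE)
write.csv(plates$extractions, file.path(out_dir, "extractions.csv"),
          row.names = FALSE)
write.csv(truthed$series, file.path(out_dir, "series_truth.csv"),
          row.names = FALSE)
write.csv(truthed$events, file.path(out_dir, "events_truth.csv"),
          row.names = FALSE)
write.csv(truthed$notes, file.path(out_dir, "notes.csv"), row.names = FALSE)

cat(sprintf("simulated %d animals, %d samples, %d plates, %d injected events, %d notes\n",
            nrow(sim$animals), nrow(plates$extractions),
            length(unique(plates$layout$plate_id)),
            nrow(truthed$events), nrow(truthed$notes)))
cat("wrote", out_dir, "\n")
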