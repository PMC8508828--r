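#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study-design dataset.
#
# Emulates the assay design: the 74-biomarker reporter library exposed to
# five test materials at six concentrations (0.031-32 mg/L, four-fold
# series) in triplicate, OD600/GFP read every 5 min over 2 h, with blank,
# vehicle, and housekeeping controls, 5% multiplicative measurement CV, and
# concentration-dependent optical backgrounds. Also writes reference-compound
# (MMC-like, H2O2-like) response tables and correlated phenotype tables.
# Everything is a deterministic function of the seed.

suppressMessages(library(pelitox))

seed <- 1L
out <- "results/data"

truth <- synthetic_truth(seed = seed)
print(truth)
phen <- simulate_phenotypes(truth)
paths <- write_synthetic_dataset(truth, out, phenotypes = phen)

plate <- read_plate_export(paths[["plate"]], read_plate_map(paths[["plate_map"]]))
cat(sprintf("wrote %d files to %s\n", length(paths), out))
cat(sprintf("plate: %d wells x %d timepoints; %d responsive ORFs programmed\n",
            nrow(plate$od), length(plate$time_min), sum(truth$orfs$responsive)))
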