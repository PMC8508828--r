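#!/usr/bin/env Rscript
# Stage 2: raw plate readings -> blank-corrected expression -> log induction
# factors (ln I) -> PELI at biomarker, stress-category, and total levels.
#
# Writes results/tables/ln_i.csv (tidy trajectories), peli.csv, and the
# biomarker x condition matrix of mean ln I used by the multivariate stage.

suppressMessages({library(pelitox); library(readr); library(tibble)})

data_dir <- "results/data"
out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

lib <- read_library(file.path(data_dir, "library.tsv"))
plate <- read_plate_export(file.path(data_dir, "plate_long.csv"),
                           read_plate_map(file.path(data_dir, "plate_map.csv")))

norm <- normalize_expression(plate)
profiles <- induction_profiles(norm)
peli <- peli_table(profiles, lib)
mat <- profile_matrix(profiles)

write_csv(profiles, file.path(out, "ln_i.csv"))
write_csv(peli, file.path(out, "peli.csv"))
write_csv(as_tibble(mat, rownames = "orf"), file.path(out, "profile_matrix.csv"))

pos <- peli[peli$level == "orf" & classify_toxicity(peli$peli), ]
cat(sprintf("ln I computed for %d biomarkers x %d conditions\n",
            nrow(mat), ncol(mat)))
cat(sprintf("%d positive biomarker calls (PELI > 1.5) across conditions;\n",
            nrow(pos)))
cat(sprintf("strongest single-biomarker response: PELI = %.2f (%s at %g mg/L)\n",
            max(pos$peli), pos$compound[which.max(pos$peli)],
            pos$concentration_mg_L[which.max(pos$peli)]))
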