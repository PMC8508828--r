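#!/usr/bin/env Rscript
# Stage 4: stress-category GSEA with an empirical permutation null for every
# condition, and hypergeometric ontology enrichment of the activated ORFs
# (PELI_ORF > 1.5) at 32 mg/L against the 74-biomarker library reference.

suppressMessages({library(pelitox); library(readr); library(dplyr)})

out <- "results/tables"
seed <- 1L
lib <- read_library("results/data/library.tsv")
term_map <- read_term_map("results/data/term_map.tsv")
peli <- read_csv(file.path(out, "peli.csv"), show_col_types = FALSE)

gsea <- gsea_all_conditions(peli, lib, n_perm = 1000, seed = seed)
write_csv(gsea, file.path(out, "gsea.csv"))

top_c <- max(peli$concentration_mg_L)
onto <- bind_rows(lapply(unique(peli$compound), function(cp) {
  hits <- activated_orfs(peli, cp, top_c)
  res <- ontology_enrichment(hits, lib, term_map)
  if (nrow(res) > 0) res$compound <- cp
  res
}))
write_csv(onto, file.path(out, "ontology.csv"))

sig <- gsea[gsea$significant, ]
cat(sprintf("GSEA: %d of %d category x condition tests significant (p < 0.05)\n",
            nrow(sig), nrow(gsea)))
cat("significant categories at 32 mg/L:\n")
print(as.data.frame(sig[sig$concentration_mg_L == top_c,
                        c("compound", "category", "statistic", "p_value")]),
      row.names = FALSE)
cat(sprintf("\nontology: %d of %d term tests overrepresented at %g mg/L\n",
            sum(onto$overrepresented), nrow(onto), top_c))
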