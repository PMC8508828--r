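#!/usr/bin/env Rscript
# Stage 6: phenotypic anchoring. ROS fold changes (with H2O2-equivalent
# doses) are correlated with oxidative and total PELI at the two highest
# concentrations; comet % Tail DNA positivity is tested per compound against
# the untreated control and correlated with DNA-category PELI at 32 mg/L.

suppressMessages({library(pelitox); library(readr); library(dplyr)})

out <- "results/tables"
peli <- read_csv(file.path(out, "peli.csv"), show_col_types = FALSE)
ros <- read_csv("results/data/ros.csv", show_col_types = FALSE)
comet <- read_csv("results/data/comet.csv", show_col_types = FALSE)
std <- read_csv("results/data/h2o2_standard.csv", show_col_types = FALSE)

cat_tab <- peli[peli$level %in% c("category", "total"), ]
oxi <- cat_tab[cat_tab$key == "oxidative",
               c("compound", "concentration_mg_L", "peli")]
tot <- cat_tab[cat_tab$key == "total",
               c("compound", "concentration_mg_L", "peli")]
ros <- ros |>
  inner_join(rename(oxi, peli_oxidative = peli),
             by = c("compound", "concentration_mg_L")) |>
  inner_join(rename(tot, peli_total = peli),
             by = c("compound", "concentration_mg_L"))
eq <- lapply(ros$fold_change, h2o2_equivalent, standard_curve = std)
ros$h2o2_equiv_mg_L <- vapply(eq, `[[`, 0, "value")
write_csv(ros, file.path(out, "ros_endpoints.csv"))

control <- comet$tail_pct[comet$compound == "control"]
comet_tab <- bind_rows(lapply(setdiff(unique(comet$compound), "control"),
  function(cp) {
    res <- comet_positivity(comet$tail_pct[comet$compound == cp], control)
    tibble::tibble(compound = cp, mean_tail_pct = res$mean_treatment,
                   delta_tail_pct = res$mean_treatment - res$mean_control,
                   p_value = res$p_value, positive = res$positive)
  }))
top_c <- max(peli$concentration_mg_L)
geno <- cat_tab[cat_tab$key == "DNA" & cat_tab$concentration_mg_L == top_c,
                c("compound", "peli")]
comet_tab <- inner_join(comet_tab, rename(geno, peli_DNA = peli),
                        by = "compound")
write_csv(comet_tab, file.path(out, "comet_endpoints.csv"))

cors <- bind_rows(
  c(endpoint_pair = "ros_vs_peli_oxidative",
    correlate(ros$fold_change, ros$peli_oxidative)),
  c(endpoint_pair = "ros_vs_peli_total",
    correlate(ros$fold_change, ros$peli_total)),
  c(endpoint_pair = "tail_dna_vs_peli_DNA",
    correlate(comet_tab$delta_tail_pct, comet_tab$peli_DNA)))
write_csv(cors, file.path(out, "correlations.csv"))

cat(sprintf("%d of %d compounds comet-positive (one-sided Welch, p < 0.05)\n",
            sum(comet_tab$positive), nrow(comet_tab)))
cat("molecular vs phenotypic endpoint correlations:\n")
print(as.data.frame(cors), row.names = FALSE)
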