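#!/usr/bin/env Rscript
# Stage 5: multivariate structure of the differential-expression profiles:
# average-linkage hierarchical clustering on correlation distance (both
# conditions and biomarkers; Newick export) and PCA of the 30 conditions.

suppressMessages({library(pelitox); library(readr)})

out <- "results/tables"
wide <- read_csv(file.path(out, "profile_matrix.csv"), show_col_types = FALSE)
mat <- as.matrix(wide[, -1]); rownames(mat) <- wide$orf

hc_cond <- cluster_profiles(mat, axis = "columns")
hc_orf <- cluster_profiles(mat, axis = "rows")
dendrogram_newick(hc_cond, file.path(out, "dendrogram_conditions.nwk"))
dendrogram_newick(hc_orf, file.path(out, "dendrogram_biomarkers.nwk"))

pca <- pca_profiles(mat)
tabs <- pca_tables(pca)
write_csv(tabs$scores, file.path(out, "pca_scores.csv"))
write_csv(tabs$variance, file.path(out, "pca_variance.csv"))

cat(sprintf("clustered %d conditions and %d biomarkers (correlation distance, average linkage)\n",
            ncol(mat), nrow(mat)))
top_pair <- labels(stats::as.dendrogram(hc_cond))[1:2]
cat(sprintf("deepest condition merge joins: %s | %s\n",
            top_pair[1], top_pair[2]))
cat(sprintf("PCA: PC1 explains %.1f%%, PC2 %.1f%% (PC1+PC2 = %.1f%% of variance)\n",
            100 * pca$variance_fractions[1], 100 * pca$variance_fractions[2],
            100 * sum(pca$variance_fractions[1:2])))
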