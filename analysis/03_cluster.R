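#!/usr/bin/env Rscript
## Discover the dominant seasonal patterns: standardize the fitted curves of
## the significant features, scan k = 2..10 by average silhouette width over
## fuzzy C-means partitions (m = 2, 10 restarts), and keep the winning model.
## A PCA of the curves summarizes how low-dimensional the pattern space is.
## Inputs:  results/visits.tsv, feature_values.tsv
## Outputs: results/k_selection.tsv, cluster_membership.tsv,
##          cluster_centroids.tsv, curve_pca.tsv

library(seasonomics)

seed <- 20260922
visits <- read_visits("results/visits.tsv")
values <- read_feature_table("results/feature_values.tsv")

scan <- seasonality_scan(values, visits, model_spec())
curves <- standardize_curves(scan, p_threshold = 0.05)
message(sprintf("%d standardized curves enter clustering", nrow(curves)))

ks <- select_k(curves, 2:10, m = 2, seed = seed, n_restarts = 10)
print(ks)
write_tsv(ks$table, "results/k_selection.tsv")

model <- ks$models[[as.character(ks$chosen_k)]]
memb <- data.frame(feature_id = model$feature_ids,
                   round(model$membership, 4), hard_label = model$hard,
                   check.names = FALSE)
names(memb)[2:(model$k + 1)] <- sprintf("cluster_%d", seq_len(model$k))
write_tsv(memb, "results/cluster_membership.tsv")
write_tsv(data.frame(cluster = rep(seq_len(model$k), each = 365),
                     day = rep(1:365, model$k),
                     value = as.vector(t(model$centroids))),
          "results/cluster_centroids.tsv")

pca <- pca_summary(curves, labels = model$hard)
message(sprintf("PC1+PC2 carry %.0f%% of curve variance",
                100 * pca$cumulative[2]))
write_tsv(cbind(feature_id = rownames(curves), pca$scores),
          "results/curve_pca.tsv")
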