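#!/usr/bin/env Rscript
## Relate external data streams to the learned seasonal patterns: fit each
## stream's annual curve, standardize it, and compute its fuzzy membership
## against the fixed cluster centroids (the centroids are NOT refitted).
## Inputs:  results/visits.tsv, feature_values.tsv (to rebuild the model)
## Outputs: results/projection_membership.tsv

library(seasonomics)

seed <- 20260922
visits <- read_visits("results/visits.tsv")
values <- read_feature_table("results/feature_values.tsv")

scan <- seasonality_scan(values, visits, model_spec())
curves <- standardize_curves(scan, p_threshold = 0.05)
ks <- select_k(curves, 2:10, m = 2, seed = seed, n_restarts = 10)
model <- ks$models[[as.character(ks$chosen_k)]]

streams <- generate_external_streams(seed = seed + 20L)
ids <- unique(streams$stream_id)
rows <- do.call(rbind, lapply(ids, function(id) {
  s <- streams[streams$stream_id == id, ]
  v <- data.frame(sample_id = sprintf("%s_%03d", id, s$day_of_year),
                  subject_id = "stream", day_of_year = s$day_of_year)
  f <- fit_seasonal_model(s$value, v, model_spec(covariates = character(0)))
  cv <- f$fitted_curve
  (cv - mean(cv)) / sd(cv)
}))
rownames(rows) <- ids

proj <- project_membership(rows, model)
out <- data.frame(stream_id = ids, round(proj, 4), check.names = FALSE)
print(out, row.names = FALSE)
write_tsv(out, "results/projection_membership.tsv")
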