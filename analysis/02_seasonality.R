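#!/usr/bin/env Rscript
## Per-analyte seasonality: penalized cyclic cubic spline with IR/IS and BMI
## covariates and subject random intercepts, GCV-selected smoothing, and a
## likelihood-ratio test of the smooth. Features with p <= 0.05 are the
## candidates for pattern clustering.
## Inputs:  results/visits.tsv, results/feature_values.tsv
## Outputs: results/seasonality.tsv (one row per feature),
##          results/curves.tsv (fitted annual curve + 95% band per feature)

library(seasonomics)

visits <- read_visits("results/visits.tsv")
values <- read_feature_table("results/feature_values.tsv")

scan <- seasonality_scan(values, visits, model_spec())
write_tsv(scan$table, "results/seasonality.tsv")

curves <- do.call(rbind, lapply(scan$fits, function(f) {
  if (!inherits(f, "seasonal_fit")) return(NULL)
  data.frame(curve_id = f$feature_id, day = 1:365, value = f$fitted_curve,
             lower = f$curve_band[, "lower"], upper = f$curve_band[, "upper"])
}))
write_tsv(curves, "results/curves.tsv")

n_sig <- sum(scan$table$p_value <= 0.05, na.rm = TRUE)
message(sprintf("%d/%d features fitted; %d seasonal at p <= 0.05",
                sum(scan$table$fitted), nrow(scan$table), n_sig))
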