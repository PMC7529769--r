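#' Aggregate taxon counts to a taxonomic level
#'
#' Sums counts within the groups defined by the taxonomy map at the
#' requested rank. Taxa without a lineage entry are bucketed into
#' `"unclassified"`. Per-sample totals are conserved.
#'
#' @param counts samples x taxa count matrix (colnames = taxon ids).
#' @param taxonomy `data.frame` with a `taxon` column plus lineage columns
#'   (`genus`, `family`, `order`, `class`, `phylum`).
#' @param level one of the lineage column names.
#' @return samples x groups count matrix.
#' @export
aggregate_taxa <- function(counts, taxonomy, level) {
  counts <- as.matrix(counts)
  if (!level %in% setdiff(names(taxonomy), "taxon"))
    stopf("unknown taxonomic level '%s' (have: %s)", level,
          paste(setdiff(names(taxonomy), "taxon"), collapse = ", "))
  grp <- taxonomy[[level]][match(colnames(counts), taxonomy$taxon)]
  grp[is.na(grp)] <- "unclassified"
  t(rowsum(t(counts), grp))
}

#' Chao1 richness estimator
#'
#' Nonparametric richness from singleton (`F1`) and doubleton (`F2`)
#' counts. Classic form: `S_obs + F1^2 / (2 F2)` (when `F2 > 0`, else
#' `S_obs + F1 (F1 - 1) / 2`); bias-corrected form (default):
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`. Both variants equal `S_obs` when
#' there are no singletons, and the estimate never falls below the observed
#' richness. An all-zero sample yields estimate 0 with a warning.
#'
#' @param counts non-negative integer vector (one sample) or samples x taxa
#'   matrix.
#' @param bias_corrected use the bias-corrected variant (default `TRUE`).
#' @return `data.frame` with `sample_id`, `observed_richness`, `chao1`.
#' @export
#' @examples
#' chao1(c(5, 1, 1, 2), bias_corrected = FALSE)  # 4 + 2^2/(2*1) = 6
#' chao1(c(5, 1, 1, 2))                          # 4 + 2*1/(2*2) = 4.5
chao1 <- function(counts, bias_corrected = TRUE) {
  m <- if (is.matrix(counts) || is.data.frame(counts)) as.matrix(counts)
       else matrix(counts, nrow = 1, dimnames = list("sample_1", NULL))
  if (any(m < 0) || any(m != round(m)))
    stopf("counts must be non-negative integers")
  est <- apply(m, 1, function(x) {
    s_obs <- sum(x > 0)
    if (s_obs == 0) {
      warning("all-zero sample: Chao1 estimate 0", call. = FALSE)
      return(c(0, 0))
    }
    f1 <- sum(x == 1); f2 <- sum(x == 2)
    ch <- if (bias_corrected) s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
          else if (f2 > 0) s_obs + f1^2 / (2 * f2)
          else s_obs + f1 * (f1 - 1) / 2
    c(s_obs, ch)
  })
  data.frame(sample_id = rownames(m) %||% sprintf("sample_%d", seq_len(nrow(m))),
             observed_richness = est[1, ], chao1 = est[2, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Seasonality of microbial richness
#'
#' Estimates per-sample Chao1 richness (optionally after aggregation to a
#' taxonomic level), joins the estimates to the visit table and fits the
#' cyclic-spline seasonal model to the richness series. Reports the
#' seasonality p-value and the winter-vs-summer fitted contrast: the mean of
#' the fitted curve over winter days (1..60 and 335..365) minus its mean
#' over summer days (152..244).
#'
#' @param counts samples x taxa count matrix (rownames = `sample_id`).
#' @param visits visit table containing those samples.
#' @param taxonomy,level optional aggregation before estimation.
#' @param bias_corrected Chao1 variant.
#' @param spec a [model_spec()].
#' @return list with `fit` (a `seasonal_fit` of the richness series),
#'   `estimates`, `winter_summer_contrast`, `pvalue`, `level`.
#' @export
diversity_seasonality <- function(counts, visits, taxonomy = NULL,
                                  level = NULL, bias_corrected = TRUE,
                                  spec = model_spec()) {
  if (!is.null(level)) {
    if (is.null(taxonomy)) stopf("aggregation to '%s' needs a taxonomy map", level)
    counts <- aggregate_taxa(counts, taxonomy, level)
  }
  est <- chao1(counts, bias_corrected = bias_corrected)
  idx <- match(visits$sample_id, est$sample_id)
  if (all(is.na(idx))) stopf("no overlap between count samples and visits")
  y <- est$chao1[idx]
  fit <- fit_seasonal_model(y, visits, spec,
                            feature_id = paste0("chao1",
                                                if (is.null(level)) "" else paste0("_", level)))
  if (inherits(fit, "seasonal_skip"))
    stopf("too few richness observations to fit seasonality")
  curve <- fit$fitted_curve
  contrast <- mean(curve[c(1:60, 335:365)]) - mean(curve[152:244])
  list(fit = fit, estimates = est, winter_summer_contrast = contrast,
       pvalue = fit$seasonality_pvalue, level = level)
}
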