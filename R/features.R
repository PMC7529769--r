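#' Archetype seasonal curves
#'
#' The two dominant seasonal shapes used by the synthetic cohort are smooth
#' von Mises shaped bumps on the 365-day circle, rescaled to `[0, 1]`:
#' pattern 1 peaks in late April (center day 115) and pattern 2 peaks in
#' December (center day 350), which places its trough in March-July. The
#' concentration default gives a full width at half maximum of about 120 days.
#'
#' @param pattern_id 1 or 2.
#' @param day numeric day(s) of year; fractional days allowed, and values
#'   outside `[1, 365]` are wrapped onto the period.
#' @param kappa von Mises concentration.
#' @return numeric vector of curve values in `[0, 1]`.
#' @export
#' @examples
#' which.max(archetype_curve(1, 1:365))  # near day 115
archetype_curve <- function(pattern_id, day, kappa = 1.42) {
  if (any(!is.finite(day))) stopf("day must be finite")
  center <- switch(as.character(pattern_id), "1" = 115, "2" = 350,
                   stopf("unknown pattern_id '%s' (must be 1 or 2)", pattern_id))
  a <- exp(kappa * (cos(2 * pi * (day - center) / 365) - 1))
  (a - exp(-2 * kappa)) / (1 - exp(-2 * kappa))
}

#' Specify one synthetic feature
#'
#' A feature is generated per visit as
#' `subject_intercept + amplitude * shape(day + phase_shift) + bmi_beta * BMI
#'  + group_effect(day) + noise`,
#' where `shape` depends on `kind`: the pattern-1 or pattern-2 archetype, the
#' average of both (`bimodal`, two annual peaks), or no seasonal term (`null`,
#' `differential`). For `kind = "differential"` an IR-vs-IS group effect of
#' size `diff_effect` is active inside `diff_window` (whole year when `NULL`),
#' switched on smoothly with 15-day cosine ramps. The per-feature phase shift
#' is drawn once, uniformly in `[-phase_jitter, phase_jitter]` days.
#'
#' @param feature_id identifier.
#' @param kind one of `"seasonal_p1"`, `"seasonal_p2"`, `"bimodal"`, `"null"`,
#'   `"differential"`.
#' @param amplitude seasonal amplitude (signal units, >= 0).
#' @param phase_jitter maximum phase shift (days, >= 0).
#' @param noise_sd residual (visit-level) noise SD (> 0 unless exactly 0 for
#'   degenerate checks).
#' @param subject_sd SD of the subject random baseline.
#' @param bmi_beta linear BMI coefficient (signal units per kg/m^2).
#' @param diff_window length-2 day window `[start, end]` inside `[1, 365]`, or
#'   `NULL` for a whole-year group effect.
#' @param diff_effect IR-minus-IS group effect size inside the window.
#' @param ome ome label carried through to output tables.
#' @return a `feature_spec` list.
#' @export
feature_spec <- function(feature_id, kind = "null", amplitude = 1,
                         phase_jitter = 0, noise_sd = 1, subject_sd = 1,
                         bmi_beta = 0, diff_window = NULL, diff_effect = 0,
                         ome = "omics") {
  kind <- match.arg(kind, c("seasonal_p1", "seasonal_p2", "bimodal",
                            "null", "differential"))
  if (amplitude < 0) stopf("amplitude must be >= 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (subject_sd < 0) stopf("subject_sd must be >= 0")
  if (phase_jitter < 0) stopf("phase_jitter must be >= 0")
  if (!is.null(diff_window)) {
    if (length(diff_window) != 2 || any(diff_window < 1 | diff_window > 365) ||
        diff_window[1] > diff_window[2])
      stopf("diff_window must be an increasing day pair within [1, 365]")
  }
  structure(list(feature_id = as.character(feature_id), kind = kind,
                 amplitude = amplitude, phase_jitter = phase_jitter,
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 bmi_beta = bmi_beta, diff_window = diff_window,
                 diff_effect = diff_effect, ome = ome),
            class = "feature_spec")
}

#' Default mixed panel of synthetic features
#'
#' A 200-feature panel at the generator's study conditions: 30% pattern-1
#' seasonal, 30% pattern-2 seasonal, 10% bimodal, 20% non-seasonal, and 10%
#' IR/IS-differential (half whole-year, half inside a 120-day window),
#' with amplitude 3, phase jitter 15 days, unit noise and unit subject SD.
#'
#' @param n_features total number of features.
#' @param amplitude,phase_jitter,noise_sd,subject_sd passed to every spec.
#' @param diff_effect group effect size of the differential features.
#' @return list of [feature_spec()] objects.
#' @export
default_feature_specs <- function(n_features = 200, amplitude = 3,
                                  phase_jitter = 15, noise_sd = 1,
                                  subject_sd = 1, diff_effect = 2) {
  n_p1 <- round(0.3 * n_features); n_p2 <- round(0.3 * n_features)
  n_bi <- round(0.1 * n_features); n_df <- round(0.1 * n_features)
  n_null <- n_features - n_p1 - n_p2 - n_bi - n_df
  kinds <- rep(c("seasonal_p1", "seasonal_p2", "bimodal", "null",
                 "differential"), c(n_p1, n_p2, n_bi, n_null, n_df))
  lapply(seq_len(n_features), function(i) {
    k <- kinds[i]
    win <- if (k == "differential" && i %% 2 == 0) c(121, 240) else NULL
    feature_spec(sprintf("F%04d", i), kind = k,
                 amplitude = if (k %in% c("null", "differential")) 0 else amplitude,
                 phase_jitter = phase_jitter, noise_sd = noise_sd,
                 subject_sd = subject_sd,
                 diff_window = win,
                 diff_effect = if (k == "differential") diff_effect else 0)
  })
}

#' Generate a synthetic feature table with ground truth
#'
#' Draws per-subject random baselines and per-visit values for every feature
#' according to its [feature_spec()], over the visits of a cohort. Returns the
#' long-format value table together with a `GroundTruth` table recording, for
#' each feature, its true kind, seasonal pattern, phase shift and differential
#' window, enabling recovery tests downstream.
#'
#' @param design a [cohort_design()].
#' @param specs list of [feature_spec()]s (non-empty).
#' @param visits visit table from [generate_visits()]; generated from
#'   `design` when missing.
#' @param seed RNG seed for the feature draws (`NULL` = current stream).
#' @return list with elements `data` (long `data.frame`: visit columns plus
#'   `feature_id`, `ome`, `value`), `truth` (one row per feature) and
#'   `visits`.
#' @export
generate_features <- function(design, specs = default_feature_specs(),
                              visits = NULL, seed = design$seed) {
  stopifnot(inherits(design, "cohort_design"))
  if (length(specs) == 0) stopf("specs must contain at least one feature_spec")
  if (is.null(visits)) visits <- generate_visits(design, seed = seed)
  with_seed(if (is.null(seed)) NULL else seed + 1L, {
    nv <- nrow(visits)
    subj <- factor(visits$subject_id)
    ns <- nlevels(subj)
    is_ir <- visits$group == "IR"
    blocks <- vector("list", length(specs))
    truth <- vector("list", length(specs))
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      phase <- if (sp$phase_jitter > 0)
        stats::runif(1, -sp$phase_jitter, sp$phase_jitter) else 0
      day <- (visits$day_of_year + phase - 1) %% 365 + 1
      shape <- switch(sp$kind,
        seasonal_p1 = archetype_curve(1, day),
        seasonal_p2 = archetype_curve(2, day),
        bimodal = (archetype_curve(1, day) + archetype_curve(2, day)) / 2,
        numeric(nv))
      grp_eff <- if (sp$kind == "differential" && sp$diff_effect != 0) {
        w <- if (is.null(sp$diff_window)) rep(1, nv)
             else window_weight(visits$day_of_year, sp$diff_window[1],
                                sp$diff_window[2])
        sp$diff_effect * w * is_ir
      } else 0
      b_subj <- stats::rnorm(ns, 0, sp$subject_sd)[as.integer(subj)]
      value <- b_subj + sp$amplitude * shape + sp$bmi_beta * visits$bmi +
        grp_eff + stats::rnorm(nv, 0, sp$noise_sd)
      blocks[[i]] <- value
      truth[[i]] <- data.frame(
        feature_id = sp$feature_id, kind = sp$kind,
        pattern_id = switch(sp$kind, seasonal_p1 = 1L, seasonal_p2 = 2L,
                            NA_integer_),
        amplitude = sp$amplitude, phase_shift = phase,
        diff_start = if (is.null(sp$diff_window)) {
          if (sp$kind == "differential") 1L else NA_integer_
        } else sp$diff_window[1],
        diff_end = if (is.null(sp$diff_window)) {
          if (sp$kind == "differential") 365L else NA_integer_
        } else sp$diff_window[2],
        diff_effect = sp$diff_effect, ome = sp$ome,
        stringsAsFactors = FALSE)
    }
    data <- cbind(
      visits[rep(seq_len(nv), length(specs)), , drop = FALSE],
      feature_id = rep(vapply(specs, `[[`, "", "feature_id"), each = nv),
      ome = rep(vapply(specs, `[[`, "", "ome"), each = nv),
      value = unlist(blocks))
    rownames(data) <- NULL
    list(data = data, truth = do.call(rbind, truth), visits = visits)
  })
}

#' Simulate simple external data streams for membership projection
#'
#' Periodic daily series emulating the kinds of external measurements that
#' can be projected onto learned seasonal patterns: air temperature (peaks
#' mid summer), tree/grass pollen (spring bumps), mold spores (late spring)
#' and a winter respiratory-infection index. These are demonstration streams,
#' not meteorological models.
#'
#' @param noise_sd observation noise added to each daily value.
#' @param seed RNG seed.
#' @return long `data.frame` with columns `stream_id`, `day_of_year`, `value`.
#' @export
generate_external_streams <- function(noise_sd = 0.3, seed = NULL) {
  with_seed(seed, {
    day <- 1:365
    shapes <- list(
      temperature = archetype_curve(1, (day + 75 - 1) %% 365 + 1),  # peak ~ day 190
      tree_pollen = archetype_curve(1, (day + 25 - 1) %% 365 + 1, kappa = 4),
      grass_pollen = archetype_curve(1, day, kappa = 4),
      mold_spores = archetype_curve(1, (day - 20 - 1) %% 365 + 1, kappa = 3),
      infection_index = archetype_curve(2, day))
    do.call(rbind, lapply(names(shapes), function(nm) {
      data.frame(stream_id = nm, day_of_year = day,
                 value = shapes[[nm]] + stats::rnorm(365, 0, noise_sd),
                 stringsAsFactors = FALSE)
    }))
  })
}
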