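## handmade group fits on a T-point grid
mk_group_fit <- function(fit, se, group = "A", Tn = length(fit)) {
  structure(list(group = group, days = seq(1, 365, length.out = Tn),
                 fit = fit, se = se, n = 100), class = "group_fit")
}

test_that("interval statistics follow the closed form and are antisymmetric", {
  Tn <- 53
  fA <- mk_group_fit(rep(1, Tn), rep(1, Tn), "A")
  fB <- mk_group_fit(rep(0, Tn), rep(1, Tn), "B")
  st <- interval_statistics(fA, fB)
  expect_equal(length(st$statistic), Tn - 1)
  ## constant offset 1, SE = 1 both: statistic = 1 / sqrt(2) exactly
  expect_equal(st$statistic, rep(1 / sqrt(2), Tn - 1), tolerance = 1e-12)
  st_swap <- interval_statistics(fB, fA)
  expect_equal(st_swap$statistic, -st$statistic, tolerance = 1e-12)

  ## identical curves give all-zero statistics
  expect_equal(interval_statistics(fA, fA)$statistic, rep(0, Tn - 1))

  ## zero SEs: 0/0 -> 0, otherwise an error
  f0 <- mk_group_fit(rep(2, Tn), rep(0, Tn))
  expect_equal(interval_statistics(f0, f0)$statistic, rep(0, Tn - 1))
  expect_error(interval_statistics(f0, mk_group_fit(rep(0, Tn), rep(0, Tn))),
               "zero standard error")
  expect_error(interval_statistics(fA, mk_group_fit(rep(0, 10), rep(1, 10))),
               "shared grid")
})

test_that("permutation p-values reproduce hand counts and the boundaries", {
  pool <- structure(list(statistics = matrix(c(0.5, 1.5), 1, 2), B = 1,
                         unit = "subject", days = seq(1, 365, length.out = 3)),
                    class = "null_pool")
  ## observed (1.0, 2.0), positive direction: exceedances (1, 0) of 2
  expect_equal(interval_pvalues(c(1, 2), pool), c(0.5, 0))
  ## below the whole pool (positive direction) -> p = 1
  expect_equal(interval_pvalues(c(0.1, 0.1), pool), c(1, 1))
  ## negative direction counts values smaller than the observed
  pool_neg <- structure(list(statistics = matrix(c(-0.5, -1.5), 1, 2), B = 1,
                             unit = "subject",
                             days = seq(1, 365, length.out = 3)),
                        class = "null_pool")
  expect_equal(interval_pvalues(c(-1, -2), pool_neg), c(0.5, 0))
  expect_error(interval_pvalues(c(1, 2, 3), pool), "intervals")
})

test_that("larger observed magnitudes never get larger p-values", {
  set.seed(10)
  pool <- structure(list(statistics = matrix(rnorm(500), 10, 50), B = 10,
                         unit = "subject",
                         days = seq(1, 365, length.out = 51)),
                    class = "null_pool")
  obs_pos <- sort(runif(50, 0, 3))
  p_pos <- interval_pvalues(obs_pos, pool)
  expect_true(all(diff(p_pos) <= 0))
  p_neg <- interval_pvalues(-obs_pos, pool)
  expect_true(all(diff(p_neg) <= 0))
})

test_that("BH interval calling matches the brute-force definition", {
  res <- call_significant(c(0.01, 0.02, 0.04, 0.5), alpha = 0.05,
                          days = seq(1, 365, length.out = 5))
  expect_equal(res$adj_p, c(0.04, 0.04, 0.04 * 4 / 3, 0.5), tolerance = 1e-12)
  expect_true(all(res$adj_p >= res$p))
  set.seed(11)
  for (i in 1:25) {
    p <- runif(20)
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(call_significant(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("features are classified global, partial or none with merged ranges", {
  Tn <- 11
  days <- seq(1, 365, length.out = Tn)
  expect_equal(call_significant(rep(1, Tn - 1), days = days)$classification,
               "none")
  expect_equal(call_significant(rep(0, Tn - 1), days = days)$classification,
               "global")
  half <- c(rep(0, 5), rep(1, 5))
  res <- call_significant(half, days = days)
  expect_equal(res$classification, "partial")
  expect_equal(nrow(res$ranges), 1)
  ## significance touching both year ends merges into one wrapping range
  wrap <- rep(1, Tn - 1)
  wrap[c(1, 2, Tn - 1)] <- 0
  rw <- call_significant(wrap, days = days)
  expect_equal(sum(rw$ranges$wraps), 1)
  wr <- rw$ranges[rw$ranges$wraps, ]
  expect_gt(wr$start_day, wr$end_day)
})

test_that("identical groups produce near-identical curves, offsets are recovered", {
  ## two groups built from the same subject-level data
  base <- generate_visits(cohort_design(n_subjects = 10, n_years = 2,
                                        visits_per_year = 6, seed = 31))
  twin <- base
  twin$subject_id <- paste0(twin$subject_id, "b")
  twin$sample_id <- paste0(twin$sample_id, "b")
  visits <- rbind(base, twin)
  visits$group <- rep(c("IR", "IS"), each = nrow(base))
  set.seed(32)
  y0 <- rnorm(nrow(base)) + archetype_curve(1, base$day_of_year)
  fits <- fit_group_curves(c(y0, y0), visits, spec = quick_diff_spec())
  expect_lt(max(abs(fits[[1]]$fit - fits[[2]]$fit)), 1e-6)

  ## constant offset between groups, no seasonality
  v2 <- generate_visits(cohort_design(n_subjects = 40, seed = 33))
  set.seed(34)
  y2 <- rep(rnorm(40, 0, 0.3), each = 12) + rnorm(nrow(v2), 0, 1) +
    1 * (v2$group == "IR")
  f2 <- fit_group_curves(y2, v2, spec = quick_diff_spec())
  gap <- f2[["IR"]]$fit - f2[["IS"]]$fit
  expect_lt(abs(mean(gap) - 1), 0.3)
  expect_lt(max(abs(gap - 1)), 0.7)

  expect_error(fit_group_curves(y2, v2, labels = rep("IR", nrow(v2))),
               "2 groups")
})

test_that("group-curve standard errors shrink with more data", {
  se_at <- function(n_subj, vpy, seed) {
    v <- generate_visits(cohort_design(n_subjects = n_subj, n_years = 1,
                                       visits_per_year = vpy, seed = seed))
    set.seed(seed + 1)
    y <- rep(rnorm(n_subj, 0, 1), each = vpy) + rnorm(nrow(v))
    f <- fit_group_curves(y, v, spec = quick_diff_spec())
    median(c(f[[1]]$se, f[[2]]$se))
  }
  expect_lt(se_at(50, 8, 41), se_at(25, 4, 41))
})

test_that("the permutation null is seeded, sized and unit-aware", {
  v <- generate_visits(cohort_design(n_subjects = 14, n_years = 2,
                                     visits_per_year = 4, seed = 51))
  set.seed(52)
  y <- rep(rnorm(14), each = 8) + rnorm(nrow(v))
  np1 <- permutation_null(y, v, B = 8, seed = 9, spec = quick_diff_spec(),
                          grid_size = 20)
  np2 <- permutation_null(y, v, B = 8, seed = 9, spec = quick_diff_spec(),
                          grid_size = 20)
  expect_identical(np1$statistics, np2$statistics)
  expect_equal(dim(np1$statistics), c(8, 19))
  nps <- permutation_null(y, v, B = 8, unit = "sample", seed = 9,
                          spec = quick_diff_spec(), grid_size = 20)
  expect_false(identical(np1$statistics, nps$statistics))
  expect_error(permutation_null(y, v, B = 0), "B must be")
})

test_that("on null data the observed statistics are exchangeable with the null", {
  ## Interval statistics are strongly dependent within a relabeling (a random
  ## group-mean offset moves all intervals together), so the clean form of
  ## "observed and permuted statistics share a distribution" is rank
  ## uniformity: the observed summary's rank among the permutation summaries
  ## is uniform across independent null datasets.
  ranks <- vapply(1:15, function(r) {
    v <- generate_visits(cohort_design(n_subjects = 16, n_years = 2,
                                       visits_per_year = 4, seed = 60 + r))
    set.seed(600 + r)
    y <- rep(rnorm(16), each = 8) + rnorm(nrow(v))
    de <- seasonomics:::differential_engine(v, quick_diff_spec(), 20)
    fits <- fit_group_curves(y, v, spec = quick_diff_spec(), grid_size = 20,
                             engine = de)
    obs <- mean(interval_statistics(fits[[1]], fits[[2]])$statistic)
    np <- permutation_null(y, v, B = 39, seed = 700 + r,
                           spec = quick_diff_spec(), grid_size = 20,
                           engine = de)
    (1 + sum(rowMeans(np$statistics) <= obs)) / (np$B + 2)
  }, 0)
  expect_gt(suppressWarnings(ks.test(ranks, "punif")$p.value), 0.01)
})

test_that("null features rarely get any significant interval", {
  v <- generate_visits(cohort_design(n_subjects = 20, n_years = 2,
                                     visits_per_year = 4, seed = 80))
  de <- seasonomics:::differential_engine(v, quick_diff_spec(), 26)
  set.seed(81)
  any_sig <- vapply(1:15, function(i) {
    y <- rep(rnorm(20), each = 8) + rnorm(nrow(v))
    res <- interval_differential(y, v, B = 100, grid_size = 26,
                                 seed = 810 + i, spec = quick_diff_spec(),
                                 engine = de)
    any(res$significant)
  }, TRUE)
  ## family-wise fraction with any call should stay near 2 * alpha = 0.1
  expect_lte(sum(any_sig), 4)
})

test_that("the end-to-end interval test flags an injected window", {
  sim <- generate_features(
    cohort_design(seed = 71),
    list(feature_spec("d", "differential", amplitude = 0, noise_sd = 1,
                      subject_sd = 1, diff_window = c(120, 210),
                      diff_effect = 2.5)))
  y <- sim$data$value
  res <- interval_differential(y, sim$visits, B = 60, seed = 72,
                               spec = quick_diff_spec(), feature_id = "d")
  expect_s3_class(res, "interval_result")
  expect_true(res$classification %in% c("partial", "global"))
  called <- called_day_mask(res)
  expect_gt(mean(called[120:210]), 0.5)
  ## reproducible under the same seed
  res2 <- interval_differential(y, sim$visits, B = 60, seed = 72,
                                spec = quick_diff_spec(), feature_id = "d")
  expect_identical(res$adj_p, res2$adj_p)
})
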