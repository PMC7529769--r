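test_that("visit generation honors the design and is deterministic", {
  v1 <- generate_visits(cohort_design(n_subjects = 1, n_years = 1,
                                      visits_per_year = 4, seed = 3))
  expect_equal(nrow(v1), 4)
  expect_true(all(v1$day_of_year >= 1 & v1$day_of_year <= 365))

  v <- generate_visits(full_cohort_design(seed = 5))
  expect_equal(length(unique(v$subject_id)), 105)
  expect_equal(nrow(v), 105 * 4 * 4)

  grp <- tapply(v$group, v$subject_id, function(g) length(unique(g)))
  expect_true(all(grp == 1))
  expect_equal(sum(tapply(v$group, v$subject_id, `[`, 1) == "IR"),
               round(0.5 * 105))

  expect_identical(v, generate_visits(full_cohort_design(seed = 5)))
  expect_false(identical(v, generate_visits(full_cohort_design(seed = 6))))
})

test_that("visit days are uniform over the year", {
  v <- generate_visits(cohort_design(n_subjects = 300, n_years = 2,
                                     visits_per_year = 6, seed = 42))
  bins <- cut(v$day_of_year, breaks = c(0, 91.25, 182.5, 273.75, 365))
  expect_gt(suppressWarnings(chisq.test(table(bins))$p.value), 0.01)
})

test_that("archetype curves peak and trough where the patterns should", {
  days <- 1:365
  p1 <- archetype_curve(1, days)
  p2 <- archetype_curve(2, days)
  expect_true(which.max(p1) >= 105 && which.max(p1) <= 125)
  am2 <- which.max(p2)
  expect_true(am2 >= 335 || am2 <= 10)
  expect_true(which.min(p2) >= 60 && which.min(p2) <= 190)
  expect_true(all(p1 >= 0 & p1 <= 1))
  ## periodic: day 1 equals the wrap of day 366
  expect_equal(archetype_curve(1, 1), archetype_curve(1, 366), tolerance = 1e-12)
  expect_error(archetype_curve(3, 1), "unknown pattern")
})

test_that("feature generation matches its closed-form moments", {
  big <- cohort_design(n_subjects = 150, n_years = 2, visits_per_year = 6,
                       seed = 9)
  specs <- list(
    feature_spec("null1", "null", amplitude = 0, noise_sd = 1, subject_sd = 1),
    feature_spec("det1", "null", amplitude = 0, noise_sd = 0, subject_sd = 0,
                 bmi_beta = 0.5),
    feature_spec("diff1", "differential", amplitude = 0, noise_sd = 1,
                 subject_sd = 0, diff_window = c(100, 200), diff_effect = 2))
  out <- generate_features(big, specs)
  d <- out$data

  ## null feature: var = subject_sd^2 + noise_sd^2 = 2
  v_null <- var(d$value[d$feature_id == "null1"])
  expect_gt(v_null, 2 * 0.85)
  expect_lt(v_null, 2 * 1.15)

  ## fully deterministic feature equals the covariate term
  det <- d[d$feature_id == "det1", ]
  expect_equal(det$value, 0.5 * det$bmi, tolerance = 1e-12)

  ## differential: group-mean gap ~ 2 inside the window core, ~ 0 far outside
  df <- d[d$feature_id == "diff1", ]
  core <- df$day_of_year >= 120 & df$day_of_year <= 180
  outs <- df$day_of_year >= 250 & df$day_of_year <= 350
  gap <- function(rows) mean(rows$value[rows$group == "IR"]) -
    mean(rows$value[rows$group == "IS"])
  expect_equal(gap(df[core, ]), 2, tolerance = 0.2)
  expect_equal(gap(df[outs, ]), 0, tolerance = 0.2)

  ## ground truth covers every feature exactly once
  expect_setequal(out$truth$feature_id, c("null1", "det1", "diff1"))
  expect_equal(anyDuplicated(out$truth$feature_id), 0L)
  expect_false(anyNA(d$value))
})

test_that("feature specs validate their fields", {
  expect_error(feature_spec("x", amplitude = -1), "amplitude")
  expect_error(feature_spec("x", diff_window = c(400, 20)), "diff_window")
  expect_error(generate_features(tiny_design, list()), "at least one")
})

test_that("taxon counts are multinomial with winter-boosted richness", {
  des <- cohort_design(n_subjects = 30, n_years = 2, visits_per_year = 6,
                       seed = 21)
  tc <- generate_taxon_counts(des, n_taxa = 80, depth = 4000,
                              winter_richness_boost = 1.5)
  expect_true(all(tc$counts >= 0))
  expect_true(all(tc$counts == round(tc$counts)))
  expect_true(all(rowSums(tc$counts) == 4000))
  expect_setequal(tc$taxonomy$taxon, colnames(tc$counts))

  day <- tc$visits$day_of_year
  s_obs <- rowSums(tc$counts > 0)
  winter <- day <= 60 | day >= 335
  summer <- day >= 152 & day <= 244
  expect_gt(mean(s_obs[winter]), mean(s_obs[summer]))

  ## boost = 1: winter-vs-summer gap within Monte-Carlo noise
  tc0 <- generate_taxon_counts(des, n_taxa = 80, depth = 4000,
                               winter_richness_boost = 1)
  s0 <- rowSums(tc0$counts > 0)
  d0 <- tc0$visits$day_of_year
  gap0 <- mean(s0[d0 <= 60 | d0 >= 335]) - mean(s0[d0 >= 152 & d0 <= 244])
  se0 <- sqrt(var(s0) * (1 / sum(d0 <= 60 | d0 >= 335) +
                           1 / sum(d0 >= 152 & d0 <= 244)))
  expect_lt(abs(gap0), 4 * se0 + 1)

  expect_error(generate_taxon_counts(des, n_taxa = 20, depth = 100,
                                     winter_richness_boost = 3), "infeasible")
  expect_error(generate_taxon_counts(des, n_taxa = 1), "n_taxa")
})

test_that("calendar dates map to the clamped day-of-year circle", {
  d <- day_of_year(as.Date(c("2020-01-01", "2020-12-31", "2020-02-29",
                             "2021-12-31")))
  expect_equal(d, c(1L, 365L, 60L, 365L))
})

test_that("simulate_cohort is reproducible end to end", {
  s1 <- simulate_cohort(cohort_design(n_subjects = 8, seed = 77),
                        default_feature_specs(10), taxa = TRUE, n_taxa = 20)
  s2 <- simulate_cohort(cohort_design(n_subjects = 8, seed = 77),
                        default_feature_specs(10), taxa = TRUE, n_taxa = 20)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$counts, s2$counts)
})
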