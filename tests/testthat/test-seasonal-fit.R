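test_that("a constant series yields a flat curve with no seasonal freedom", {
  y <- rep(3, nrow(tiny_visits))
  f <- fit_seasonal_model(y, tiny_visits, quick_spec())
  expect_s3_class(f, "seasonal_fit")
  expect_equal(unname(f$fitted_curve), rep(3, 365), tolerance = 1e-6)
  expect_lt(f$edf_smooth, 0.1)
  expect_lt(f$rss, 1e-12)
  expect_equal(f$seasonality_pvalue, 1)
  ## zero residual variance -> zero-width band
  expect_lt(max(f$curve_band[, "upper"] - f$curve_band[, "lower"]), 1e-6)
})

test_that("a noiseless sine is recovered at the unpenalized end of the grid", {
  y <- sin(2 * pi * std_visits$day_of_year / 365)
  f <- fit_seasonal_model(y, std_visits,
                          model_spec(lambda_grid = 1e-9,
                                     subject_ridge_grid = 1))
  expect_lt(max(abs(f$fitted_curve - sin(2 * pi * (1:365) / 365))), 1e-3)

  ## oracle: direct unpenalized least squares by normal equations
  eng <- seasonomics:::seasonal_engine(std_visits,
                                       model_spec(lambda_grid = 1e-9,
                                                  subject_ridge_grid = 1))
  X <- eng$X
  P <- diag(0, ncol(X)); diag(P)[eng$idx_z] <- 1
  beta <- solve(crossprod(X) + 1e-9 * 0 + P, crossprod(X, y))
  expect_equal(unname(drop(X %*% f$coefficients)), unname(drop(X %*% beta)),
               tolerance = 1e-6)
})

test_that("heavy smoothing collapses the curve to the mean level", {
  set.seed(1)
  y <- rnorm(nrow(std_visits)) + 2 * archetype_curve(1, std_visits$day_of_year)
  f <- fit_seasonal_model(y, std_visits,
                          model_spec(lambda_grid = 1e12,
                                     subject_ridge_grid = 1))
  expect_lt(max(f$fitted_curve) - min(f$fitted_curve), 1e-3)
})

test_that("the penalized fit with zero penalties equals ordinary least squares", {
  set.seed(2)
  y <- rnorm(nrow(tiny_visits)) + tiny_visits$bmi * 0.1
  spec0 <- model_spec(lambda_grid = 0, subject_ridge_grid = 0)
  f <- fit_seasonal_model(y, tiny_visits, spec0)
  eng <- seasonomics:::seasonal_engine(tiny_visits, spec0)
  ols <- lm.fit(eng$X, y)
  expect_equal(unname(drop(eng$X %*% f$coefficients)), unname(ols$fitted.values),
               tolerance = 1e-8)
  expect_equal(f$rss, sum(ols$residuals^2), tolerance = 1e-8)
})

test_that("GCV selects from the grid and the choice is reproducible", {
  set.seed(3)
  y <- rnorm(nrow(std_visits)) + 3 * archetype_curve(2, std_visits$day_of_year) +
    rep(rnorm(40), each = 12)
  sp <- quick_spec()
  f <- fit_seasonal_model(y, std_visits, sp)
  expect_true(f$lambda %in% sp$lambda_grid)
  expect_true(f$ridge %in% sp$subject_ridge_grid)
  ## refitting at the selected penalties reproduces the coefficients
  f2 <- fit_seasonal_model(y, std_visits,
                           model_spec(lambda_grid = f$lambda,
                                      subject_ridge_grid = f$ridge))
  expect_equal(f$coefficients, f2$coefficients, tolerance = 1e-10)
})

test_that("smooth EDF never increases with the smoothing parameter", {
  eng <- seasonomics:::seasonal_engine(std_visits,
                                       model_spec(subject_ridge_grid = 1))
  edf <- vapply(eng$full, `[[`, 0, "edf_s")
  lam <- vapply(eng$full, `[[`, 0, "lambda")
  edf <- edf[order(lam)]
  expect_true(all(diff(edf) <= 1e-8))
})

test_that("fitted annual curves wrap across the year boundary", {
  set.seed(4)
  y <- rnorm(nrow(std_visits)) + 2 * archetype_curve(2, std_visits$day_of_year)
  f <- fit_seasonal_model(y, std_visits, quick_spec())
  ev <- evaluate_curve(f, c(1, 366))
  expect_lt(abs(ev$fit[1] - ev$fit[2]), 1e-8)
})

test_that("the 95% band is symmetric and matches the brute-force quadratic form", {
  set.seed(5)
  y <- rnorm(nrow(tiny_visits)) + archetype_curve(1, tiny_visits$day_of_year)
  f <- fit_seasonal_model(y, tiny_visits, quick_spec())
  ev <- evaluate_curve(f, c(15, 200, 301))
  expect_equal(ev$upper - ev$fit, ev$fit - ev$lower, tolerance = 1e-12)
  ## brute force: sd(day) = sqrt(x' V x) with explicit loops
  Pm <- f$engine$predict_mat(c(15, 200, 301))
  for (r in 1:3) {
    x <- Pm[r, ]
    s2 <- 0
    for (i in seq_along(x)) for (j in seq_along(x))
      s2 <- s2 + x[i] * f$cov[i, j] * x[j]
    expect_equal(ev$se[r], sqrt(s2), tolerance = 1e-10)
  }
  ## band contains the fitted curve pointwise
  expect_true(all(f$curve_band[, "lower"] <= f$fitted_curve &
                    f$fitted_curve <= f$curve_band[, "upper"]))
})

test_that("seasonality p-values handle edge cases and mismatched inputs", {
  y <- rep(3, nrow(tiny_visits))
  f <- fit_seasonal_model(y, tiny_visits, quick_spec())
  expect_equal(seasonality_pvalue(f), 1)
  expect_error(seasonality_pvalue(f, null_fit = list(n_obs = 5, rss = 1)),
               "observations")
  set.seed(6)
  f2 <- fit_seasonal_model(rnorm(nrow(tiny_visits)), tiny_visits, quick_spec())
  p_lrt <- seasonality_pvalue(f2, method = "lrt")
  p_edf <- seasonality_pvalue(f2, method = "edf")
  expect_true(p_lrt >= 0 && p_lrt <= 1)
  expect_true(p_edf >= 0 && p_edf <= 1)
})

test_that("too-few observations give a skip signal, NAs are dropped", {
  small <- tiny_visits[1:6, ]
  sk <- fit_seasonal_model(rnorm(6), small, quick_spec(), feature_id = "f")
  expect_s3_class(sk, "seasonal_skip")
  set.seed(7)
  y <- rnorm(nrow(tiny_visits))
  y[c(3, 10, 50)] <- NA
  f <- fit_seasonal_model(y, tiny_visits, quick_spec())
  expect_equal(f$n_obs, nrow(tiny_visits) - 3)
})

test_that("the scan shares the design and matches single-feature fits", {
  set.seed(8)
  m <- cbind(a = rnorm(nrow(tiny_visits)),
             b = 2 * archetype_curve(1, tiny_visits$day_of_year) +
               rnorm(nrow(tiny_visits), 0, 0.5))
  sc <- seasonality_scan(m, tiny_visits, quick_spec())
  expect_equal(nrow(sc$table), 2)
  f_single <- fit_seasonal_model(m[, "b"], tiny_visits, quick_spec())
  expect_equal(sc$fits$b$seasonality_pvalue, f_single$seasonality_pvalue,
               tolerance = 1e-12)
  expect_equal(sc$fits$b$fitted_curve, f_single$fitted_curve,
               tolerance = 1e-10)
  ## long-format input gives the same result
  long <- data.frame(sample_id = rep(tiny_visits$sample_id, 2),
                     feature_id = rep(c("a", "b"), each = nrow(tiny_visits)),
                     value = c(m[, "a"], m[, "b"]))
  sc2 <- seasonality_scan(long, tiny_visits, quick_spec())
  expect_equal(sc2$table$p_value, sc$table$p_value, tolerance = 1e-12)
})
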