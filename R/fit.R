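#' Specify the seasonal model
#'
#' Controls the penalized regression behind every seasonal fit: a cyclic
#' cubic spline of day-of-year (sum-to-zero constrained, with an explicit
#' intercept), linear covariates, and ridge-penalized subject indicator
#' coefficients -- the penalized-regression representation of Gaussian
#' random intercepts. The spline smoothing parameter and the subject ridge
#' are selected jointly by generalized cross-validation (GCV) over the
#' supplied grids.
#'
#' @param n_basis number of spline knots over the year (>= 4).
#' @param lambda_grid positive smoothing values scanned by GCV.
#' @param subject_ridge_grid positive ridge values for the subject
#'   intercepts.
#' @param covariates visit-table columns entering linearly. `"group"` becomes
#'   an IR indicator; numeric columns are mean-centered.
#' @param gcv_gamma GCV effective-degrees-of-freedom inflation; values above
#'   1 guard against GCV's tendency to undersmooth (1.4 is the customary
#'   correction).
#' @param pvalue_method `"lrt"` (default): exact Gaussian likelihood-ratio
#'   F-test of the unpenalized spline block against the no-season model.
#'   `"edf"`: chi-squared on the penalized deviance difference with
#'   `round(EDF)` degrees of freedom.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(n_basis = 10,
                       lambda_grid = 10^seq(-4, 6, length.out = 30),
                       subject_ridge_grid = 10^seq(-2, 2, length.out = 5),
                       covariates = c("group", "bmi"),
                       gcv_gamma = 1.4,
                       pvalue_method = c("lrt", "edf")) {
  if (n_basis < 4) stopf("n_basis must be >= 4")
  if (length(lambda_grid) == 0 || any(lambda_grid < 0))
    stopf("lambda_grid must be non-empty and non-negative")
  if (length(subject_ridge_grid) == 0 || any(subject_ridge_grid < 0))
    stopf("subject_ridge_grid must be non-empty and non-negative")
  structure(list(n_basis = as.integer(n_basis), lambda_grid = lambda_grid,
                 subject_ridge_grid = subject_ridge_grid,
                 covariates = covariates, gcv_gamma = gcv_gamma,
                 pvalue_method = match.arg(pvalue_method)),
            class = "model_spec")
}

#' @rdname model_spec
#' @details `differential_model_spec()` is the default used by the
#'   interval-wise differential stage: age and BMI covariates (the group is
#'   what is being tested), a coarser grid to keep hundreds of permutation
#'   refits affordable, and `gcv_gamma = 1` since the permutation null runs
#'   the identical procedure.
#' @export
differential_model_spec <- function(covariates = c("age", "bmi"),
                                    lambda_grid = 10^seq(-2, 5, length.out = 8),
                                    subject_ridge_grid = 10^seq(-1, 2, length.out = 3),
                                    gcv_gamma = 1, ...) {
  model_spec(covariates = covariates, lambda_grid = lambda_grid,
             subject_ridge_grid = subject_ridge_grid, gcv_gamma = gcv_gamma,
             ...)
}

## ---- internal engine -------------------------------------------------------

## Symmetric-PSD solve with pseudo-inverse fallback for singular penalties
## (e.g. lambda = ridge = 0, where intercept and subject indicators are
## collinear; fitted values remain the unique least-squares projection).
pen_inverse <- function(A) {
  out <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
  if (is.null(out)) out <- MASS::ginv(A)
  out
}

## Design + precomputed grid solves shared across features on the same visits.
seasonal_engine <- function(visits, spec = model_spec()) {
  check_days(visits$day_of_year)
  subj <- factor(visits$subject_id)
  ns <- nlevels(subj)
  n <- nrow(visits)
  ## covariates, all mean-centered so that prediction at zero is the
  ## population-average curve
  Xc <- NULL
  kept <- character()
  for (cv in spec$covariates) {
    col <- if (cv == "group") {
      if (!"group" %in% names(visits)) stopf("visits lacks a 'group' column")
      as.numeric(visits$group == "IR")
    } else {
      if (!cv %in% names(visits)) stopf("visits lacks covariate column '%s'", cv)
      v <- visits[[cv]]
      if (!is.numeric(v)) stopf("covariate '%s' must be numeric", cv)
      v
    }
    if (stats::var(col) < 1e-12) next  # constant within these visits
    Xc <- cbind(Xc, col - mean(col))
    kept <- c(kept, cv)
  }
  if (!is.null(Xc)) colnames(Xc) <- kept
  sm <- mgcv::smoothCon(mgcv::s(day_of_year, bs = "cc", k = spec$n_basis),
                        data = visits,
                        knots = list(day_of_year = seq(1, 366, length.out = spec$n_basis)),
                        absorb.cons = TRUE)[[1]]
  Z <- matrix(0, n, ns, dimnames = list(NULL, paste0("subj_", levels(subj))))
  Z[cbind(seq_len(n), as.integer(subj))] <- 1
  X <- cbind(`(Intercept)` = 1, Xc, sm$X, Z)
  pf <- 1 + length(kept)
  q <- ncol(sm$X)
  idx_s <- pf + seq_len(q)
  idx_z <- pf + q + seq_len(ns)
  S <- sm$S[[1]]
  XtX <- crossprod(X)
  penalty_at <- function(lam, rb) {
    P <- matrix(0, ncol(X), ncol(X))
    P[idx_s, idx_s] <- lam * S
    diag(P)[idx_z] <- diag(P)[idx_z] + rb
    P
  }
  grid_entry <- function(A, sub = NULL) {
    XtXs <- if (is.null(sub)) XtX else XtX[sub, sub, drop = FALSE]
    Ainv <- pen_inverse(A)
    edf <- rowSums(Ainv * XtXs)
    list(Ainv = Ainv, edf = edf, edft = sum(edf))
  }
  ## largest penalties first so that GCV ties resolve to the smoothest fit
  grid <- expand.grid(lambda = sort(spec$lambda_grid, decreasing = TRUE),
                      ridge = sort(spec$subject_ridge_grid, decreasing = TRUE))
  full <- lapply(seq_len(nrow(grid)), function(g) {
    e <- grid_entry(XtX + penalty_at(grid$lambda[g], grid$ridge[g]))
    e$lambda <- grid$lambda[g]; e$ridge <- grid$ridge[g]
    e$edf_s <- sum(e$edf[idx_s])
    e
  })
  sub0 <- c(seq_len(pf), idx_z)  # no-season design columns
  null <- lapply(spec$subject_ridge_grid, function(rb) {
    A <- XtX[sub0, sub0, drop = FALSE]
    diag(A)[pf + seq_len(ns)] <- diag(A)[pf + seq_len(ns)] + rb
    e <- grid_entry(A, sub = sub0)
    e$ridge <- rb
    e
  })
  unp <- lapply(spec$subject_ridge_grid, function(rb) {
    e <- grid_entry(XtX + penalty_at(0, rb))
    e$ridge <- rb
    e
  })
  predict_mat <- function(days, subject_weights = rep(1 / ns, ns)) {
    d <- (days - 1) %% 365 + 1
    Pm <- mgcv::PredictMat(sm, data.frame(day_of_year = d))
    cbind(1, matrix(0, length(days), pf - 1), Pm,
          matrix(subject_weights, length(days), ns, byrow = TRUE))
  }
  list(X = X, XtX = XtX, n = n, subj = subj, subjects = levels(subj),
       sm = sm, S = S, idx_f = seq_len(pf), idx_s = idx_s, idx_z = idx_z,
       sub0 = sub0, q = q, covariates = kept, spec = spec,
       full = full, null = null, unp = unp, predict_mat = predict_mat)
}

## ---- public fitting --------------------------------------------------------

#' Fit the seasonal model for one analyte
#'
#' Minimizes `||y - X b||^2 + lambda * b_s' S b_s + ridge * ||b_z||^2` where
#' `b_s` are cyclic-spline coefficients and `b_z` subject intercepts, with
#' `lambda` and `ridge` chosen by GCV, then tests for seasonality (see
#' [model_spec()] for the test) and evaluates the fitted annual curve with a
#' 95% band (`fit +/- 1.96 * sd`, sd propagated from the coefficient
#' covariance through the basis).
#'
#' @param y numeric response vector aligned with `visits` rows; `NA`s are
#'   dropped.
#' @param visits visit table ([generate_visits()] or equivalent long-format
#'   metadata with `subject_id`, `day_of_year` and covariate columns).
#' @param spec a [model_spec()].
#' @param engine precomputed [seasonal_engine] shared across features on
#'   identical complete visits (internal optimization; built when `NULL`).
#' @param feature_id,ome labels carried into summaries.
#' @return an object of class `seasonal_fit`, or `seasonal_skip` when fewer
#'   than `n_basis + n_covariates + 2` observations remain.
#' @export
fit_seasonal_model <- function(y, visits, spec = model_spec(), engine = NULL,
                               feature_id = NA_character_, ome = NA_character_) {
  stopifnot(length(y) == nrow(visits))
  keep <- is.finite(y)
  if (!all(keep)) {
    visits <- visits[keep, , drop = FALSE]
    y <- y[keep]
    engine <- NULL
  }
  min_n <- spec$n_basis + length(spec$covariates) + 2
  if (length(y) < min_n) {
    return(structure(list(feature_id = feature_id, ome = ome,
                          n_obs = length(y),
                          reason = sprintf("needs >= %d observations", min_n)),
                     class = "seasonal_skip"))
  }
  if (is.null(engine)) engine <- seasonal_engine(visits, spec)
  fit_with_engine(y, engine, feature_id = feature_id, ome = ome)
}

## Core fit given a prepared engine; y must be complete and aligned.
fit_with_engine <- function(y, engine, feature_id = NA_character_,
                            ome = NA_character_) {
  spec <- engine$spec
  n <- engine$n
  gamma <- spec$gcv_gamma
  Xty <- crossprod(engine$X, y)
  yty <- sum(y^2)
  pick <- function(entries, sub = NULL) {
    XtXs <- if (is.null(sub)) engine$XtX else engine$XtX[sub, sub, drop = FALSE]
    xts <- if (is.null(sub)) Xty else Xty[sub, , drop = FALSE]
    best <- NULL
    for (e in entries) {
      beta <- e$Ainv %*% xts
      rss <- max(yty - 2 * sum(beta * xts) +
                   drop(crossprod(beta, XtXs %*% beta)), 0)
      denom <- n - gamma * e$edft
      gcv <- if (denom > 0) n * rss / denom^2 else Inf
      if (is.null(best) || gcv < best$gcv)
        best <- list(gcv = gcv, beta = beta, rss = rss, entry = e)
    }
    best
  }
  full <- pick(engine$full)
  null <- pick(engine$null, sub = engine$sub0)
  ## unpenalized spline fit at the null model's chosen ridge (the LRT compares
  ## nested models under a common subject penalty)
  rbs <- vapply(engine$unp, `[[`, 0, "ridge")
  unp <- pick(engine$unp[which.min(abs(rbs - null$entry$ridge))])
  sigma2 <- full$rss / max(n - full$entry$edft, 1)
  p <- seasonality_pvalue_internal(
    rss_null = null$rss, rss_unp = unp$rss, rss_pen = full$rss,
    sigma2_pen = sigma2, edf_s = full$entry$edf_s,
    edft_unp = unp$entry$edft, q = engine$q, n = n,
    method = spec$pvalue_method)
  V <- sigma2 * full$entry$Ainv
  Pm <- engine$predict_mat(1:365)
  curve <- drop(Pm %*% full$beta)
  se <- sqrt(pmax(rowSums((Pm %*% V) * Pm), 0))
  structure(list(
    feature_id = feature_id, ome = ome, n_obs = n,
    coefficients = stats::setNames(drop(full$beta), colnames(engine$X)),
    smooth_coefficients = drop(full$beta)[engine$idx_s],
    cov = V, sigma2 = sigma2,
    lambda = full$entry$lambda, ridge = full$entry$ridge,
    edf_smooth = full$entry$edf_s, edf_total = full$entry$edft,
    rss = full$rss, gcv = full$gcv,
    null_rss = null$rss, null_ridge = null$entry$ridge,
    unp_rss = unp$rss, unp_edft = unp$entry$edft, q_smooth = engine$q,
    seasonality_pvalue = p,
    fitted_curve = curve, curve_se = se,
    curve_band = cbind(lower = curve - 1.96 * se, upper = curve + 1.96 * se),
    peak_day = which.max(curve), amplitude = max(curve) - min(curve),
    engine = engine),
    class = "seasonal_fit")
}

seasonality_pvalue_internal <- function(rss_null, rss_unp, rss_pen, sigma2_pen,
                                        edf_s, edft_unp, q, n, method = "lrt") {
  if (method == "lrt") {
    if (rss_null - rss_unp <= 1e-10 * max(rss_null, 1e-300)) return(1)
    if (rss_unp <= 1e-12) return(if (rss_null <= 1e-12) 1 else 0)
    Fstat <- ((rss_null - rss_unp) / q) / (rss_unp / max(n - edft_unp, 1))
    stats::pf(Fstat, q, max(n - edft_unp, 1), lower.tail = FALSE)
  } else {
    if (rss_null - rss_pen <= 1e-10 * max(rss_null, 1e-300)) return(1)
    if (sigma2_pen <= 1e-12) return(if (rss_null <= 1e-12) 1 else 0)
    D <- (rss_null - rss_pen) / sigma2_pen
    stats::pchisq(D, max(1, round(edf_s)), lower.tail = FALSE)
  }
}

#' Seasonality p-value from fitted models
#'
#' Compares the model with the cyclic smooth against the same model without
#' it (same observations, same covariates and subject penalty). With the
#' default `"lrt"` method this is the exact Gaussian likelihood-ratio F-test
#' of the unpenalized smooth block; `"edf"` uses a chi-squared on the
#' penalized deviance difference with `round(EDF of smooth)` degrees of
#' freedom (minimum 1).
#'
#' @param fit a [fit_seasonal_model()] result (which embeds its own null
#'   fit summary).
#' @param null_fit optional externally fitted no-season model; must be fit
#'   to the same observations.
#' @param method `"lrt"` or `"edf"`; defaults to the fit's spec.
#' @return p-value in `[0, 1]`.
#' @export
seasonality_pvalue <- function(fit, null_fit = NULL, method = NULL) {
  stopifnot(inherits(fit, "seasonal_fit"))
  rss_null <- fit$null_rss
  if (!is.null(null_fit)) {
    if (!is.null(null_fit$n_obs) && null_fit$n_obs != fit$n_obs)
      stopf("null fit has %d observations, full fit has %d",
            null_fit$n_obs, fit$n_obs)
    rss_null <- null_fit$rss
  }
  seasonality_pvalue_internal(
    rss_null = rss_null, rss_unp = fit$unp_rss, rss_pen = fit$rss,
    sigma2_pen = fit$sigma2, edf_s = fit$edf_smooth,
    edft_unp = fit$unp_edft, q = fit$q_smooth, n = fit$n_obs,
    method = method %||% fit$engine$spec$pvalue_method)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate the fitted annual curve with its 95% band
#'
#' The pointwise band is `fit +/- 1.96 * sd`, where `sd(day) =
#' sqrt(x_day' V x_day)` propagates the coefficient covariance `V` through
#' the prediction basis row `x_day` (intercept, centered covariates at zero,
#' spline basis, averaged subject effects).
#'
#' @param fit a `seasonal_fit`.
#' @param days days of year (wrapped onto `[1, 365]`).
#' @return `data.frame` with `day`, `fit`, `se`, `lower`, `upper`.
#' @export
evaluate_curve <- function(fit, days = 1:365) {
  stopifnot(inherits(fit, "seasonal_fit"))
  Pm <- fit$engine$predict_mat(days)
  f <- drop(Pm %*% fit$coefficients)
  se <- sqrt(pmax(rowSums((Pm %*% fit$cov) * Pm), 0))
  data.frame(day = days, fit = f, se = se,
             lower = f - 1.96 * se, upper = f + 1.96 * se)
}

#' @export
print.seasonal_fit <- function(x, ...) {
  cat(sprintf("Seasonal fit%s: n = %d, lambda = %.3g, EDF(smooth) = %.2f, p = %.3g\n",
              if (is.na(x$feature_id)) "" else paste0(" [", x$feature_id, "]"),
              x$n_obs, x$lambda, x$edf_smooth, x$seasonality_pvalue))
  cat(sprintf("  peak day %d, amplitude %.3g\n", x$peak_day, x$amplitude))
  invisible(x)
}

#' @export
print.seasonal_skip <- function(x, ...) {
  cat(sprintf("Not fitted%s: %s (n = %d)\n",
              if (is.na(x$feature_id)) "" else paste0(" [", x$feature_id, "]"),
              x$reason, x$n_obs))
  invisible(x)
}

#' Fit the seasonal model across many features
#'
#' Shares the design construction and all grid factorizations across features
#' observed on the same visits, which makes scanning hundreds of analytes
#' fast. Features containing missing values fall back to an individual fit on
#' their complete observations.
#'
#' @param values numeric matrix (visits x features, colnames = feature ids)
#'   or a long `data.frame` with `sample_id`, `feature_id`, `value` (and
#'   optionally `ome`).
#' @param visits the visit table the rows refer to.
#' @param spec a [model_spec()].
#' @return object of class `seasonality_scan`: list with `fits` (named list
#'   of `seasonal_fit` / `seasonal_skip`) and `table` (one row per feature:
#'   `feature_id`, `ome`, `n`, `p_value`, `edf`, `lambda`, `peak_day`,
#'   `amplitude`).
#' @export
seasonality_scan <- function(values, visits, spec = model_spec()) {
  omes <- NULL
  if (is.data.frame(values)) {
    need <- c("sample_id", "feature_id", "value")
    if (!all(need %in% names(values)))
      stopf("long input needs columns %s", paste(need, collapse = ", "))
    ids <- unique(values$feature_id)
    m <- matrix(NA_real_, nrow(visits), length(ids),
                dimnames = list(visits$sample_id, ids))
    ri <- match(values$sample_id, visits$sample_id)
    if (anyNA(ri)) stopf("sample_id values not present in visits")
    m[cbind(ri, match(values$feature_id, ids))] <- values$value
    if ("ome" %in% names(values))
      omes <- vapply(split(as.character(values$ome), values$feature_id),
                     `[`, "", 1)[ids]
    values <- m
  }
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("F%04d", seq_len(ncol(values)))
  if (is.null(omes)) omes <- rep(NA_character_, ncol(values))
  engine <- seasonal_engine(visits, spec)
  fits <- vector("list", ncol(values))
  names(fits) <- colnames(values)
  for (j in seq_len(ncol(values))) {
    y <- values[, j]
    fits[[j]] <- if (all(is.finite(y)))
      fit_with_engine(y, engine, feature_id = colnames(values)[j],
                      ome = omes[j])
    else
      fit_seasonal_model(y, visits, spec, feature_id = colnames(values)[j],
                         ome = omes[j])
  }
  tab <- do.call(rbind, lapply(fits, function(f) {
    if (inherits(f, "seasonal_skip"))
      data.frame(feature_id = f$feature_id, ome = f$ome, n = f$n_obs,
                 p_value = NA_real_, edf = NA_real_, lambda = NA_real_,
                 peak_day = NA_integer_, amplitude = NA_real_,
                 fitted = FALSE, stringsAsFactors = FALSE)
    else
      data.frame(feature_id = f$feature_id, ome = f$ome, n = f$n_obs,
                 p_value = f$seasonality_pvalue, edf = f$edf_smooth,
                 lambda = f$lambda, peak_day = f$peak_day,
                 amplitude = f$amplitude, fitted = TRUE,
                 stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab, spec = spec),
            class = "seasonality_scan")
}

#' @export
print.seasonality_scan <- function(x, ...) {
  ok <- x$table$fitted
  cat(sprintf("Seasonality scan: %d features (%d fitted), %d with p <= 0.05\n",
              nrow(x$table), sum(ok),
              sum(x$table$p_value[ok] <= 0.05, na.rm = TRUE)))
  invisible(x)
}
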