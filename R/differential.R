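## Interval-wise two-group trajectory testing: group-specific cyclic spline
## fits on a shared annual grid, a studentized area statistic per interval,
## and a pooled permutation null with BH-adjusted interval calls.

## Shared machinery for one visit table: design, per-subject sufficient
## statistics (so each permutation refit is a small-matrix solve), penalties
## and the annual prediction grid.
differential_engine <- function(visits, spec = differential_model_spec(),
                                grid_size = 52) {
  check_days(visits$day_of_year)
  if (grid_size < 3) stopf("grid_size must be >= 3")
  eng <- seasonal_engine(visits, spec)
  subj_rows <- split(seq_len(eng$n), eng$subj)
  Cs <- lapply(subj_rows, function(r) crossprod(eng$X[r, , drop = FALSE]))
  grid <- expand.grid(lambda = sort(spec$lambda_grid, decreasing = TRUE),
                      ridge = sort(spec$subject_ridge_grid, decreasing = TRUE))
  p <- ncol(eng$X)
  Pens <- lapply(seq_len(nrow(grid)), function(g) {
    P <- matrix(0, p, p)
    P[eng$idx_s, eng$idx_s] <- grid$lambda[g] * eng$S
    diag(P)[eng$idx_z] <- diag(P)[eng$idx_z] + grid$ridge[g]
    P
  })
  tgrid <- seq(1, 365, length.out = grid_size)
  Pm <- mgcv::PredictMat(eng$sm, data.frame(day_of_year = tgrid))
  Xg0 <- cbind(1, matrix(0, grid_size, length(eng$idx_f) - 1), Pm,
               matrix(0, grid_size, length(eng$idx_z)))
  list(eng = eng, subj_rows = subj_rows, Cs = Cs, Pens = Pens,
       grid = grid, tgrid = tgrid, Xg0 = Xg0, spec = spec)
}

## Fit one group's curve given the member subjects (sufficient-statistics
## path). The curve is the group mean: averaged subject effects enter the
## prediction row, keeping the functional identifiable at any ridge strength.
fit_group_sufficient <- function(de, y, subj_idx, group = NA_character_) {
  eng <- de$eng
  XtX <- Reduce(`+`, de$Cs[subj_idx])
  rows <- unlist(de$subj_rows[subj_idx], use.names = FALSE)
  fit_group_core(de, XtX, crossprod(eng$X[rows, , drop = FALSE], y[rows]),
                 sum(y[rows]^2), length(rows),
                 subj_weight_idx = eng$idx_z[subj_idx], group = group)
}

## Generic row-subset path (used for sample-level permutation, where a
## subject's visits can split between groups).
fit_group_rows <- function(de, y, rows, group = NA_character_) {
  eng <- de$eng
  Xr <- eng$X[rows, , drop = FALSE]
  w <- colSums(Xr[, eng$idx_z, drop = FALSE])
  fit_group_core(de, crossprod(Xr), crossprod(Xr, y[rows]), sum(y[rows]^2),
                 length(rows), subj_weight_idx = eng$idx_z,
                 subj_weights = w / sum(w), group = group)
}

fit_group_core <- function(de, XtX, Xty, yty, n, subj_weight_idx,
                           subj_weights = NULL, group = NA_character_) {
  gamma <- de$spec$gcv_gamma
  best <- NULL
  for (g in seq_along(de$Pens)) {
    A <- XtX + de$Pens[[g]]
    Ainv <- tryCatch(chol2inv(chol(A)), error = function(e) NULL)
    if (is.null(Ainv)) next
    beta <- Ainv %*% Xty
    rss <- max(yty - 2 * sum(beta * Xty) + drop(crossprod(beta, XtX %*% beta)), 0)
    edft <- sum(Ainv * XtX)
    denom <- n - gamma * edft
    gcv <- if (denom > 0) n * rss / denom^2 else Inf
    if (is.null(best) || gcv < best$gcv)
      best <- list(gcv = gcv, beta = beta, Ainv = Ainv, rss = rss,
                   edft = edft, g = g)
  }
  if (is.null(best)) stopf("group fit failed for every penalty grid point")
  sigma2 <- best$rss / max(n - best$edft, 1)
  Xg <- de$Xg0
  if (is.null(subj_weights)) Xg[, subj_weight_idx] <- 1 / length(subj_weight_idx)
  else Xg[, subj_weight_idx] <- matrix(subj_weights, nrow(Xg),
                                       length(subj_weights), byrow = TRUE)
  f <- drop(Xg %*% best$beta)
  V <- sigma2 * best$Ainv
  se <- sqrt(pmax(rowSums((Xg %*% V) * Xg), 0))
  structure(list(group = group, days = de$tgrid, fit = f, se = se, n = n,
                 lambda = de$grid$lambda[best$g], ridge = de$grid$ridge[best$g],
                 rss = best$rss, edf_total = best$edft),
            class = "group_fit")
}

#' Fit group-specific annual curves on a shared grid
#'
#' Fits the cyclic-spline seasonal model (see [model_spec()]) separately to
#' the two groups' observations, with common covariate centering, and
#' evaluates each group-mean curve with pointwise standard errors on a
#' shared annual grid of `grid_size` days.
#'
#' @param y response vector aligned with `visits`.
#' @param visits visit table.
#' @param labels group label per row (exactly two levels, e.g. IR/IS);
#'   defaults to `visits$group`.
#' @param spec a [model_spec()]; [differential_model_spec()] by default.
#' @param grid_size number of grid timepoints over the year (default 52).
#' @param engine precomputed engine (internal reuse).
#' @return named list of two `group_fit` objects (`days`, `fit`, `se`, ...).
#' @export
fit_group_curves <- function(y, visits, labels = visits$group,
                             spec = differential_model_spec(),
                             grid_size = 52, engine = NULL) {
  stopifnot(length(y) == nrow(visits), length(labels) == nrow(visits))
  lev <- unique(labels)
  if (length(lev) != 2) stopf("labels must have exactly 2 groups, got %d",
                              length(lev))
  for (g in lev) if (!any(labels == g)) stopf("group '%s' is empty", g)
  de <- engine %||% differential_engine(visits, spec, grid_size)
  subj_lab <- tapply(as.character(labels), de$eng$subj, function(v) {
    if (length(unique(v)) > 1) NA_character_ else v[1]
  })[de$eng$subjects]
  out <- if (anyNA(subj_lab)) {
    lapply(lev, function(g) fit_group_rows(de, y, which(labels == g), group = g))
  } else {
    lapply(lev, function(g) fit_group_sufficient(de, y, which(subj_lab == g),
                                                 group = g))
  }
  stats::setNames(out, lev)
}

#' Studentized area statistics per time interval
#'
#' For each of the `T - 1` consecutive grid intervals, computes the
#' difference in trapezoid areas under the two group curves over the unit
#' interval, studentized by the averaged endpoint standard errors:
#' `(A1 - A2) / sqrt(((SE1_t + SE1_{t+1})/2)^2 + ((SE2_t + SE2_{t+1})/2)^2)`.
#' The statistic is antisymmetric under group exchange. When both standard
#' errors vanish the statistic is 0 if the area difference is 0, otherwise
#' an error.
#'
#' @param fit1,fit2 `group_fit` objects on the same grid (first group minus
#'   second).
#' @return object of class `interval_statistics`: `statistic` (length
#'   `T - 1`), `area1`, `area2`, `days` (grid).
#' @export
interval_statistics <- function(fit1, fit2) {
  stopifnot(inherits(fit1, "group_fit"), inherits(fit2, "group_fit"))
  if (length(fit1$fit) != length(fit2$fit) ||
      max(abs(fit1$days - fit2$days)) > 1e-9)
    stopf("group fits are not on a shared grid")
  Tn <- length(fit1$fit)
  a1 <- (fit1$fit[-Tn] + fit1$fit[-1]) / 2
  a2 <- (fit2$fit[-Tn] + fit2$fit[-1]) / 2
  den <- sqrt(((fit1$se[-Tn] + fit1$se[-1]) / 2)^2 +
                ((fit2$se[-Tn] + fit2$se[-1]) / 2)^2)
  num <- a1 - a2
  st <- num / den
  zero_den <- den == 0
  if (any(zero_den & num != 0))
    stopf("zero standard error with non-zero area difference in interval(s) %s",
          paste(which(zero_den & num != 0), collapse = ", "))
  st[zero_den] <- 0
  structure(list(statistic = st, area1 = a1, area2 = a2, days = fit1$days,
                 groups = c(fit1$group, fit2$group)),
            class = "interval_statistics")
}

#' Permutation null pool of interval statistics
#'
#' Permutes the group labels `B` times -- by default at the subject level,
#' so all visits of a subject move together (group is a subject attribute
#' with repeated measures); `unit = "sample"` permutes visit rows instead --
#' and recomputes the group fits and interval statistics for each
#' relabeling.
#'
#' @inheritParams fit_group_curves
#' @param B number of permutations (>= 1).
#' @param unit `"subject"` or `"sample"`.
#' @param seed RNG seed.
#' @return object of class `null_pool`: `statistics` (`B x (T-1)` matrix),
#'   `B`, `unit`, `days`.
#' @export
permutation_null <- function(y, visits, labels = visits$group, B = 200,
                             unit = c("subject", "sample"), seed = NULL,
                             spec = differential_model_spec(), grid_size = 52,
                             engine = NULL) {
  unit <- match.arg(unit)
  if (B < 1) stopf("B must be >= 1")
  de <- engine %||% differential_engine(visits, spec, grid_size)
  lev <- unique(labels)
  if (length(lev) != 2) stopf("labels must have exactly 2 groups")
  with_seed(seed, {
    stats_mat <- matrix(NA_real_, B, grid_size - 1)
    if (unit == "subject") {
      subj_lab <- tapply(as.character(labels), de$eng$subj, `[`, 1)[de$eng$subjects]
      n1 <- sum(subj_lab == lev[1])
      ns <- length(subj_lab)
      for (b in seq_len(B)) {
        perm <- sample.int(ns)
        f1 <- fit_group_sufficient(de, y, perm[seq_len(n1)], group = lev[1])
        f2 <- fit_group_sufficient(de, y, perm[(n1 + 1):ns], group = lev[2])
        stats_mat[b, ] <- interval_statistics(f1, f2)$statistic
      }
    } else {
      n1 <- sum(labels == lev[1])
      nr <- length(labels)
      for (b in seq_len(B)) {
        perm <- sample.int(nr)
        f1 <- fit_group_rows(de, y, perm[seq_len(n1)], group = lev[1])
        f2 <- fit_group_rows(de, y, perm[(n1 + 1):nr], group = lev[2])
        stats_mat[b, ] <- interval_statistics(f1, f2)$statistic
      }
    }
    structure(list(statistics = stats_mat, B = B, unit = unit,
                   days = de$tgrid, seed = seed),
              class = "null_pool")
  })
}

#' Permutation p-values per interval
#'
#' Each observed interval statistic is compared against the pooled null of
#' all `B * (T - 1)` permuted statistics: the p-value is the fraction of
#' pooled values more extreme in the observed statistic's own direction
#' (greater when the observed value is non-negative, smaller when negative).
#' No pseudo-count is added, so an observed statistic beyond the whole pool
#' yields p = 0.
#'
#' @param observed an [interval_statistics()] result (or numeric vector).
#' @param null a [permutation_null()] pool on the same grid.
#' @return numeric p-values, one per interval.
#' @export
interval_pvalues <- function(observed, null) {
  stopifnot(inherits(null, "null_pool"))
  obs <- if (inherits(observed, "interval_statistics")) observed$statistic
         else as.numeric(observed)
  if (length(obs) != ncol(null$statistics))
    stopf("observed has %d intervals but the null pool has %d",
          length(obs), ncol(null$statistics))
  pool <- as.vector(null$statistics)
  if (length(pool) == 0) stopf("empty null pool")
  npool <- length(pool)
  vapply(obs, function(s) {
    if (s >= 0) sum(pool > s) / npool else sum(pool < s) / npool
  }, 0)
}

#' Call significant time intervals for one feature
#'
#' Benjamini-Hochberg adjusts the feature's interval p-values and flags
#' intervals with adjusted p below `alpha / 2` (one-sided exceedance in the
#' observed direction combined with the halved threshold gives two-sided
#' control at `alpha`). Features are classified `"global"` when every
#' interval is significant, `"partial"` when some are, `"none"` otherwise;
#' contiguous significant day ranges are reported with runs touching the
#' year boundary merged across day 365 -> 1.
#'
#' @param pvalues numeric interval p-values (length `T - 1`).
#' @param alpha two-sided significance level (default 0.05).
#' @param days grid of `T` timepoints the intervals refer to (default an
#'   even annual grid).
#' @param feature_id label carried through.
#' @return object of class `interval_result`: `p`, `adj_p`, `significant`,
#'   `classification`, `ranges` (`data.frame`: start_day, end_day, wraps).
#' @export
call_significant <- function(pvalues, alpha = 0.05,
                             days = seq(1, 365, length.out = length(pvalues) + 1),
                             feature_id = NA_character_) {
  if (any(pvalues < 0 | pvalues > 1)) stopf("p-values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  adj <- stats::p.adjust(pvalues, method = "BH")
  sig <- adj < alpha / 2
  classification <- if (all(sig)) "global" else if (any(sig)) "partial" else "none"
  ranges <- significant_ranges(sig, days)
  structure(list(feature_id = feature_id, p = pvalues, adj_p = adj,
                 significant = sig, alpha = alpha, days = days,
                 classification = classification, ranges = ranges),
            class = "interval_result")
}

significant_ranges <- function(sig, days) {
  Tn <- length(days)
  if (!any(sig))
    return(data.frame(start_day = numeric(0), end_day = numeric(0),
                      wraps = logical(0)))
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  wraps <- FALSE
  if (nrow(runs) > 1 && runs$start[1] == 1 && runs$end[nrow(runs)] == Tn - 1) {
    ## merge the year-boundary runs into one wrapping range
    first <- runs[1, ]; last <- runs[nrow(runs), ]
    runs <- runs[-c(1, nrow(runs)), , drop = FALSE]
    runs <- rbind(runs, data.frame(start = last$start, end = first$end))
    wraps <- c(rep(FALSE, nrow(runs) - 1), TRUE)
  } else if (nrow(runs) == 1 && runs$start[1] == 1 && runs$end[1] == Tn - 1) {
    wraps <- FALSE
  } else {
    wraps <- rep(FALSE, nrow(runs))
  }
  data.frame(start_day = days[runs$start], end_day = days[runs$end + 1],
             wraps = wraps)
}

#' Interval-wise differential trajectory test for one feature
#'
#' End-to-end test: group curves ([fit_group_curves()]), interval statistics
#' ([interval_statistics()]), subject-level permutation null
#' ([permutation_null()]), pooled permutation p-values
#' ([interval_pvalues()]) and BH interval calling ([call_significant()]).
#'
#' @inheritParams permutation_null
#' @param alpha significance level.
#' @param feature_id label.
#' @return an `interval_result` additionally carrying `statistics`
#'   (observed), `group_fits` and `null`.
#' @export
interval_differential <- function(y, visits, labels = visits$group, B = 200,
                                  grid_size = 52, alpha = 0.05,
                                  unit = "subject", seed = NULL,
                                  spec = differential_model_spec(),
                                  engine = NULL, feature_id = NA_character_) {
  de <- engine %||% differential_engine(visits, spec, grid_size)
  fits <- fit_group_curves(y, visits, labels, spec, grid_size, engine = de)
  obs <- interval_statistics(fits[[1]], fits[[2]])
  null <- permutation_null(y, visits, labels, B = B, unit = unit, seed = seed,
                           spec = spec, grid_size = grid_size, engine = de)
  p <- interval_pvalues(obs, null)
  res <- call_significant(p, alpha = alpha, days = de$tgrid,
                          feature_id = feature_id)
  res$statistics <- obs
  res$group_fits <- fits
  res$null <- null
  res
}

#' @export
print.interval_result <- function(x, ...) {
  cat(sprintf("Interval differential%s: %d/%d intervals significant (adj p < %.3g) -> %s\n",
              if (is.na(x$feature_id)) "" else paste0(" [", x$feature_id, "]"),
              sum(x$significant), length(x$significant), x$alpha / 2,
              x$classification))
  if (nrow(x$ranges) > 0) {
    for (i in seq_len(nrow(x$ranges)))
      cat(sprintf("  days %.0f-%.0f%s\n", x$ranges$start_day[i],
                  x$ranges$end_day[i], if (x$ranges$wraps[i]) " (wraps)" else ""))
  }
  invisible(x)
}
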