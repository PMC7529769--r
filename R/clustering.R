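#' Standardize fitted annual curves for clustering
#'
#' Keeps the features whose seasonality p-value passes the threshold and
#' z-scores each fitted curve across days 1..365 (mean 0, SD 1), so that
#' clustering sees only the shape of the annual pattern, not its level or
#' amplitude. Constant curves (SD ~ 0) and unfitted features are excluded
#' with a recorded reason.
#'
#' @param fits a [seasonality_scan()] result or a (named) list of
#'   `seasonal_fit` objects.
#' @param p_threshold seasonality p-value cutoff (default 0.05).
#' @return a `features x 365` matrix of class `curve_matrix` with an
#'   `excluded` attribute (`data.frame`: feature_id, reason). Signals a
#'   classed error (`seasonomics_empty_curves`) when no feature passes.
#' @export
standardize_curves <- function(fits, p_threshold = 0.05) {
  if (inherits(fits, "seasonality_scan")) fits <- fits$fits
  rows <- list()
  excl <- list()
  for (nm in names(fits)) {
    f <- fits[[nm]]
    if (inherits(f, "seasonal_skip")) {
      excl[[nm]] <- "not fitted"
    } else if (f$seasonality_pvalue > p_threshold) {
      excl[[nm]] <- sprintf("p = %.3g > threshold", f$seasonality_pvalue)
    } else if (stats::sd(f$fitted_curve) < 1e-10) {
      excl[[nm]] <- "constant fitted curve"
    } else {
      cv <- f$fitted_curve
      rows[[nm]] <- (cv - mean(cv)) / stats::sd(cv)
    }
  }
  excluded <- data.frame(feature_id = names(excl),
                         reason = unlist(excl, use.names = FALSE),
                         stringsAsFactors = FALSE)
  if (length(excl) > 0)
    message(sprintf("standardize_curves: excluded %d feature(s)", length(excl)))
  if (length(rows) == 0)
    stop(errorCondition("no feature passed the seasonality threshold",
                        class = c("seasonomics_empty_curves", "error", "condition")))
  m <- do.call(rbind, rows)
  structure(m, class = c("curve_matrix", class(m)), excluded = excluded)
}

#' Fuzzy C-means clustering of seasonal curves
#'
#' Bezdek's alternating optimization: memberships
#' `u_ij = 1 / sum_l (d_ij / d_il)^(2/(m-1))` and centroids as
#' `u^m`-weighted means, iterated until the objective
#' `sum_ij u_ij^m d_ij^2` changes by less than `tol` (Euclidean distances).
#' The best of `n_restarts` random initializations is returned. A row at zero
#' distance from a centroid receives membership 1 there.
#'
#' @param curves numeric matrix (rows = items, e.g. a
#'   [standardize_curves()] result).
#' @param k number of clusters (>= 1, <= rows).
#' @param m fuzzifier (> 1).
#' @param seed RNG seed for the restarts.
#' @param n_restarts random restarts (best objective kept).
#' @param max_iter,tol convergence controls.
#' @param debug assert per-iteration objective monotonicity.
#' @return object of class `cluster_model`: `centroids` (k x cols),
#'   `membership` (rows x k, rows sum to 1), `hard` (argmax labels),
#'   `objective`, `k`, `m`, `iterations`.
#' @export
fuzzy_cmeans <- function(curves, k, m = 2, seed = NULL, n_restarts = 10,
                         max_iter = 1000, tol = 1e-9, debug = FALSE) {
  curves <- as.matrix(curves)
  n <- nrow(curves)
  if (k < 1) stopf("k must be >= 1")
  if (k > n) stopf("k = %d exceeds the %d rows available", k, n)
  if (m <= 1) stopf("fuzzifier m must be > 1")
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      res <- cmeans_once(curves, k, m, max_iter, tol, debug)
      if (is.null(best) || res$objective < best$objective) best <- res
    }
    structure(c(best, list(k = k, m = m, seed = seed,
                           n_restarts = n_restarts,
                           feature_ids = rownames(curves))),
              class = "cluster_model")
  })
}

cmeans_once <- function(x, k, m, max_iter, tol, debug) {
  n <- nrow(x)
  cent <- x[sample.int(n, k), , drop = FALSE]
  obj_prev <- Inf
  u <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- pmax(sq_dist(x, cent), 0)
    u <- membership_from_d2(d2, m)
    um <- u^m
    obj <- sum(um * d2)
    if (debug && obj > obj_prev + 1e-8)
      stopf("objective increased at iteration %d", it)
    cent <- crossprod(um, x) / colSums(um)
    if (is.finite(obj_prev) && abs(obj_prev - obj) < tol) break
    obj_prev <- obj
  }
  list(centroids = cent, membership = u, hard = max.col(u, "first"),
       objective = obj, iterations = it)
}

## squared Euclidean distances rows(x) x rows(cent)
sq_dist <- function(x, cent) {
  outer(rowSums(x^2), rep(1, nrow(cent))) +
    outer(rep(1, nrow(x)), rowSums(cent^2)) - 2 * tcrossprod(x, cent)
}

membership_from_d2 <- function(d2, m) {
  pw <- d2^(-1 / (m - 1))
  u <- pw / rowSums(pw)
  ## a (numerically) zero distance wins its whole row outright
  zero <- d2 <= 1e-12 * pmax(apply(d2, 1, max), 1e-300)
  hit <- rowSums(zero) > 0
  if (any(hit)) u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  u
}

#' Project new curves onto existing cluster centroids
#'
#' Computes fuzzy membership values for new (standardized) annual curves
#' against the fixed centroids and fuzzifier of a fitted [fuzzy_cmeans()]
#' model -- the mechanism used to relate external data streams (clinical
#' labs, meteorology, pollen counts) to the learned seasonal patterns.
#'
#' @param new_curve numeric vector (one curve) or matrix (rows = curves),
#'   standardized the same way as the training curves.
#' @param model a `cluster_model`.
#' @return membership matrix (rows x k), each row summing to 1; a curve at
#'   zero distance from a centroid gets membership 1 there.
#' @export
project_membership <- function(new_curve, model) {
  stopifnot(inherits(model, "cluster_model"))
  x <- if (is.matrix(new_curve)) new_curve else matrix(new_curve, nrow = 1)
  if (ncol(x) != ncol(model$centroids))
    stopf("curve length %d does not match centroid length %d",
          ncol(x), ncol(model$centroids))
  u <- membership_from_d2(pmax(sq_dist(x, model$centroids), 0), model$m)
  rownames(u) <- rownames(x)
  colnames(u) <- sprintf("cluster_%d", seq_len(model$k))
  u
}

#' Choose the number of seasonal patterns
#'
#' Runs [fuzzy_cmeans()] for each `k`, hardens memberships by argmax and
#' scores the partition by the average silhouette width (Euclidean distance;
#' singleton clusters score 0 by convention, via [cluster::silhouette()]).
#' The within-cluster sum of squares is reported alongside for an elbow
#' reading. The chosen `k` maximizes the average silhouette. `k = 1` is not
#' scanned: the silhouette is undefined there.
#'
#' @param curves a `curve_matrix` (or plain matrix).
#' @param k_range candidate cluster counts (subset of `2..(n-1)`).
#' @param m fuzzifier.
#' @param seed RNG seed (each k gets a deterministic sub-seed).
#' @param n_restarts restarts per k.
#' @return object of class `k_selection`: `table` (`k`,
#'   `avg_silhouette`, `within_ss`), `chosen_k`, `models` (one
#'   `cluster_model` per k).
#' @export
select_k <- function(curves, k_range = 2:10, m = 2, seed = NULL,
                     n_restarts = 10) {
  curves <- as.matrix(curves)
  n <- nrow(curves)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) stopf("k_range has no feasible values (n = %d)", n)
  dd <- stats::dist(curves)
  models <- list()
  tab <- data.frame(k = k_range, avg_silhouette = NA_real_,
                    within_ss = NA_real_)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    mod <- fuzzy_cmeans(curves, k, m = m,
                        seed = if (is.null(seed)) NULL else seed + k,
                        n_restarts = n_restarts)
    models[[as.character(k)]] <- mod
    hard <- mod$hard
    tab$within_ss[i] <- sum(vapply(seq_len(k), function(j) {
      rows <- curves[hard == j, , drop = FALSE]
      if (nrow(rows) == 0) 0 else sum(sweep(rows, 2, colMeans(rows))^2)
    }, 0))
    tab$avg_silhouette[i] <- if (length(unique(hard)) < 2) 0 else
      mean(cluster::silhouette(hard, dd)[, "sil_width"])
  }
  structure(list(table = tab, chosen_k = tab$k[which.max(tab$avg_silhouette)],
                 models = models),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Cluster-number selection (average silhouette):\n")
  print(x$table, row.names = FALSE)
  cat("chosen k =", x$chosen_k, "\n")
  invisible(x)
}

#' PCA summary of standardized seasonal curves
#'
#' Centered principal component analysis of the curve matrix; used to check
#' how much of the curve variation the leading components carry and to plot
#' features in pattern space.
#'
#' @param curves matrix with >= 3 rows.
#' @param labels optional cluster labels attached to the scores.
#' @return list with `scores` (first two PCs), `variance_fraction`
#'   (per component, non-increasing, summing to 1), `cumulative`.
#' @export
pca_summary <- function(curves, labels = NULL) {
  curves <- as.matrix(curves)
  if (nrow(curves) < 3) stopf("PCA summary needs at least 3 curves")
  pc <- stats::prcomp(curves, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as.data.frame(pc$x[, 1:2, drop = FALSE])
  if (!is.null(labels)) scores$cluster <- labels
  list(scores = scores, variance_fraction = vf, cumulative = cumsum(vf))
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("Fuzzy C-means: k = %d, m = %.2f, objective = %.4g (%d restarts)\n",
              x$k, x$m, x$objective, x$n_restarts))
  cat("cluster sizes (hard):", tabulate(x$hard, x$k), "\n")
  invisible(x)
}
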