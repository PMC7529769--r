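## Shared fixtures and independent oracles. Everything is generated in code;
## fixtures are built once when the helper loads.

quick_spec <- function(...) {
  model_spec(lambda_grid = 10^seq(-4, 6, length.out = 12),
             subject_ridge_grid = c(0.1, 1, 10), ...)
}

quick_diff_spec <- function(...) {
  differential_model_spec(lambda_grid = 10^seq(-2, 5, length.out = 6),
                          subject_ridge_grid = c(0.1, 1, 10), ...)
}

tiny_design <- cohort_design(n_subjects = 12, n_years = 2, visits_per_year = 4,
                             seed = 11)
tiny_visits <- generate_visits(tiny_design)

std_design <- cohort_design(seed = 101)  # 40 subjects x 3 years x 4 visits
std_visits <- generate_visits(std_design)

## Brute-force Benjamini-Hochberg from the definition: step-up over the
## sorted p-values with the cumulative-minimum enforcing monotonicity.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(n)
  running <- Inf
  for (i in seq_len(n)) {
    idx <- o[i]
    rank <- n - i + 1
    running <- min(running, p[idx] * n / rank)
    adj[idx] <- min(running, 1)
  }
  adj
}

## standardized archetype curve rows for direct clustering tests
std_archetype_row <- function(pattern, shift = 0) {
  cv <- archetype_curve(pattern, ((1:365) + shift - 1) %% 365 + 1)
  (cv - mean(cv)) / sd(cv)
}

## best label agreement between two hard clusterings (over label permutations)
perms_all <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(j)
    lapply(perms_all(v[-j]), function(r) c(v[j], r))))
}

label_agreement <- function(a, b) {
  k <- max(a, b)
  max(vapply(perms_all(seq_len(k)), function(p) mean(p[a] == b), 0))
}

## Jaccard overlap between a called day mask and a true day window
jaccard_days <- function(called, true) {
  u <- sum(called | true)
  if (u == 0) return(1)
  sum(called & true) / u
}

## days covered by significant intervals of an interval_result
called_day_mask <- function(res) {
  mask <- rep(FALSE, 365)
  g <- res$days
  for (t in which(res$significant)) {
    mask[max(1, ceiling(g[t])):min(365, floor(g[t + 1]))] <- TRUE
  }
  mask
}
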