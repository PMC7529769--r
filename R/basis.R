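#' Cyclic cubic regression spline basis with roughness penalty
#'
#' Builds the periodic spline basis used by every seasonal fit: a cyclic cubic
#' regression spline on the day-of-year circle whose value and first two
#' derivatives match at day 1 and day 366, so fitted annual curves wrap
#' smoothly across the year boundary. Coefficients are the curve values at the
#' distinct knots, hence a constant curve is represented exactly by equal
#' coefficients. The quadratic penalty is the integrated squared second
#' derivative (symmetric positive semi-definite, with constants in its null
#' space). Construction is delegated to [mgcv::smoothCon()].
#'
#' @param days numeric days in `[1, 365]` at which to evaluate the basis.
#' @param n_basis number of knots spanning one period (default 10, giving
#'   `n_basis - 1` free coefficients after cyclic closure).
#' @param period period in days.
#' @return an object of class `cyclic_basis` with elements `basis_matrix`
#'   (`length(days) x (n_basis - 1)`), `penalty_matrix`, `knots`, `period`.
#' @export
#' @examples
#' b <- build_cyclic_basis(c(1, 100, 365))
#' rowSums(b$basis_matrix)  # constants are exactly representable
build_cyclic_basis <- function(days, n_basis = 10, period = 365) {
  check_days(days, "days")
  if (n_basis < 4) stopf("n_basis must be >= 4")
  knots <- seq(1, period + 1, length.out = n_basis)
  sm <- mgcv::smoothCon(mgcv::s(day, bs = "cc", k = n_basis),
                        data = data.frame(day = days),
                        knots = list(day = knots), absorb.cons = FALSE)[[1]]
  structure(list(basis_matrix = sm$X, penalty_matrix = sm$S[[1]],
                 knots = knots, period = period, sm = sm),
            class = "cyclic_basis")
}

#' Evaluate a cyclic basis at new days
#'
#' @param basis a [build_cyclic_basis()] object.
#' @param days days at which to evaluate; values are wrapped onto the period,
#'   so day 366 evaluates identically to day 1.
#' @return matrix with one row per day.
#' @export
evaluate_basis <- function(basis, days) {
  stopifnot(inherits(basis, "cyclic_basis"))
  d <- (days - 1) %% basis$period + 1
  mgcv::PredictMat(basis$sm, data.frame(day = d))
}
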