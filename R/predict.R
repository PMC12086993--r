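#' Hyperbolic yield-density predictions
#'
#' The per-plant biomass of a plant grown with `N` neighbours of its own
#' species follows the hyperbolic yield-density law
#' `w = wm * (1 + a * N)^(-b)`: `wm` is the mean biomass of an isolated
#' plant, `a` the per-plant crowding coefficient (interpretable as the area a
#' plant needs to reach `wm`) and `b` the dimensionless exponent. In a
#' two-species stand the crowding term splits into conspecific and
#' allospecific contributions,
#' `w = wm * (1 + beta * n_self + alpha * n_other)^(-b)`, so
#' `predict_biculture()` with `n_other = 0` reduces exactly to
#' `predict_monoculture()` with `beta` in the role of `a`. Densities are
#' totals at harvest and include the focal plant. Predictions are strictly
#' decreasing in either density when the corresponding coefficient and `b`
#' are positive.
#'
#' @param wm mean isolated-plant biomass (g), > 0.
#' @param a,beta,alpha crowding/competition coefficients per plant, >= 0.
#' @param b hyperbolic exponent, >= 0.
#' @param N,n_self,n_other plant densities, >= 0 (vectorized).
#' @return predicted per-plant biomass in grams.
#' @examples
#' predict_monoculture(0.1, 1, 1, N = 1) # 0.05
#' predict_biculture(0.1, beta = 0, alpha = 1, b = 1, n_self = 3, n_other = 1)
#' @export
predict_monoculture <- function(wm, a, b, N) {
  stopifnot(wm > 0, a >= 0, b >= 0)
  if (any(N < 0)) {
    stop("domain error: density N must be >= 0", call. = FALSE)
  }
  wm * exp(-b * log1p(a * N))
}

#' @rdname predict_monoculture
#' @export
predict_biculture <- function(wm, beta, alpha, b, n_self, n_other) {
  stopifnot(wm > 0, beta >= 0, alpha >= 0, b >= 0)
  if (any(n_self < 0) || any(n_other < 0)) {
    stop("domain error: densities must be >= 0", call. = FALSE)
  }
  wm * exp(-b * log1p(beta * n_self + alpha * n_other))
}

#' Pseudo-r-squared on the log scale
#'
#' Goodness of fit for the log-scale nonlinear models:
#' `1 - SSE / SST`, with SST taken about the mean of the observed natural-log
#' responses. Can be negative for a fit worse than the mean; undefined
#' (returned as `NA`) when the observations are constant.
#'
#' @param observed observed log responses.
#' @param fitted fitted log responses, same length.
#' @return a single number in (-Inf, 1], or `NA` if SST is zero.
#' @export
pseudo_r2 <- function(observed, fitted) {
  stopifnot(length(observed) == length(fitted), length(observed) >= 2L)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) {
    return(NA_real_)
  }
  1 - sum((observed - fitted)^2) / sst
}
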