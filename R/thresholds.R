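#' Neighbour density causing a given biomass decline
#'
#' Inverts the hyperbolic competition model one coefficient at a time: with
#' the other species' density held at zero, per-capita biomass falls to a
#' fraction `1 - f` of the isolated-plant biomass `wm` when
#' `(1 + c * N)^(-b) = 1 - f`, i.e. at the (real-valued) density
#' `N = ((1 - f)^(-1/b) - 1) / c`. Use the intraspecific coefficient for
#' conspecific-crowding thresholds and the interspecific coefficient for
#' allospecific ones. The threshold decreases in `c` and `b` and increases in
#' `f`; a zero coefficient gives an infinite threshold (that species never
#' causes the decline).
#'
#' @param c_coef competition coefficient per plant, >= 0 (vectorized).
#' @param b hyperbolic exponent, > 0.
#' @param f decline fraction in (0, 1), e.g. 0.5 for a 50% biomass drop.
#' @return density in plants (real-valued; `Inf` when `c_coef` is 0).
#' @examples
#' decline_threshold(1, 1, 0.5) # 1: doubling the denominator halves biomass
#' @export
decline_threshold <- function(c_coef, b, f) {
  if (any(c_coef < 0)) {
    stop("domain error: coefficient must be >= 0", call. = FALSE)
  }
  if (any(b <= 0)) stop("domain error: b must be > 0", call. = FALSE)
  if (any(f <= 0 | f >= 1)) {
    stop("domain error: decline fraction f must be in (0, 1)", call. = FALSE)
  }
  ifelse(c_coef == 0, Inf, expm1(-log1p(-f) / b) / c_coef)
}

#' Decline-density threshold with a parametric-bootstrap interval
#'
#' Point estimate: the analytic plug-in inversion of [decline_threshold()]
#' at the fitted coefficients. Uncertainty: parameter vectors are drawn from
#' a multivariate normal centred at the internal (log-scale) estimates with
#' the fitted covariance — so every draw yields positive coefficients — and
#' the threshold is recomputed per draw; the 2.5% and 97.5% percentiles give
#' the 95% confidence interval. This propagates the estimation uncertainty
#' through the back-transformation and accommodates the strong right skew
#' such thresholds typically show. For biculture fits the fixed exponent `b`
#' is held constant across draws (its monoculture-stage uncertainty is not
#' propagated); for monoculture fits `b` varies with its own uncertainty.
#'
#' @param fit a `yd_fit` (biculture for interspecific thresholds).
#' @param mode `"intraspecific"` (conspecific coefficient: `beta`, or `a` for
#'   a monoculture fit) or `"interspecific"` (`alpha`; biculture fits only).
#' @param f decline fraction in (0, 1).
#' @param n_boot number of bootstrap draws, >= 1000.
#' @param seed optional integer seed (caller's RNG state is restored).
#' @param level confidence level (default 0.95).
#' @return object of class `"threshold_estimate"`: a list with
#'   `focal_species`, `mode`, `f`, `n_star` (plug-in estimate), `ci_low`,
#'   `ci_high`, `level`, `method`, `n_boot`, `seed`.
#' @export
threshold_ci <- function(fit, mode = c("intraspecific", "interspecific"),
                         f, n_boot = 10000L, seed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "yd_fit"))
  mode <- match.arg(mode)
  if (n_boot < 1000L) {
    stop("n_boot must be at least 1000", call. = FALSE)
  }
  coef_name <- if (mode == "intraspecific") {
    if (fit$kind == "monoculture") "a" else "beta"
  } else {
    if (fit$kind == "monoculture") {
      stop("interspecific thresholds require a biculture fit", call. = FALSE)
    }
    "alpha"
  }
  est <- fit$coefficients
  if (est[[coef_name]] == 0) {
    # Bounded fit put the coefficient on its zero boundary: that species
    # never causes the decline under the fitted model.
    return(structure(
      list(
        focal_species = fit$species, mode = mode, f = f,
        n_star = Inf, ci_low = Inf, ci_high = Inf, level = level,
        method = "coefficient at zero boundary; threshold infinite",
        n_boot = n_boot, seed = seed
      ),
      class = "threshold_estimate"
    ))
  }
  b_at <- function(draws) {
    if (fit$b_fixed) rep(fit$b, nrow(draws)) else exp(draws[, "log_b"])
  }
  n_star <- decline_threshold(est[[coef_name]], fit$b, f)
  v <- fit$vcov_internal
  if (any(!is.finite(v))) {
    stop("degenerate covariance: non-finite entries", call. = FALSE)
  }
  ci <- with_seed(seed, {
    draws <- MASS::mvrnorm(n_boot, mu = fit$internal, Sigma = v)
    colnames(draws) <- names(fit$internal)
    thr <- decline_threshold(
      exp(draws[, paste0("log_", coef_name)]), b_at(draws), f
    )
    ok <- is.finite(thr) & thr > 0
    if (mean(ok) < 0.5) {
      stop("more than 50% of bootstrap draws were invalid (",
        sum(!ok), " of ", n_boot, ")",
        call. = FALSE
      )
    }
    quantile(thr[ok], probs = c((1 - level) / 2, 1 - (1 - level) / 2),
      names = FALSE, type = 7L)
  })
  structure(
    list(
      focal_species = fit$species, mode = mode, f = f,
      n_star = n_star, ci_low = ci[1L], ci_high = ci[2L], level = level,
      method = "analytic plug-in point + parametric bootstrap percentile CI",
      n_boot = n_boot, seed = seed
    ),
    class = "threshold_estimate"
  )
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf(
    "%s %s decline threshold (%.0f%% biomass decline):\n",
    x$focal_species, x$mode, 100 * x$f
  ))
  cat(sprintf(
    "  %.5f plants (%.0f%% CI %.5f, %.5f; %d bootstrap draws)\n",
    x$n_star, 100 * x$level, x$ci_low, x$ci_high, x$n_boot
  ))
  invisible(x)
}

#' Relative competitive ability
#'
#' The ratio of a species' intraspecific to interspecific competition
#' coefficient, `RCA = beta / alpha`. Its reciprocal, the density
#' equivalence, is the number of allospecific individuals whose competitive
#' effect on the focal species equals one conspecific: an RCA of 0.5 means
#' two allospecific plants match one conspecific; an RCA below 1 means
#' allospecific neighbours suppress the focal species more strongly than
#' conspecifics do.
#'
#' @param beta intraspecific coefficient, > 0.
#' @param alpha interspecific coefficient, > 0.
#' @param species optional focal-species label carried into the result.
#' @return object of class `"rca_result"`: list with `species`, `rca`,
#'   `density_equivalence`.
#' @examples
#' rca(0.1309, 5.6387)$rca # 0.0232...
#' @export
rca <- function(beta, alpha, species = NA_character_) {
  if (!is.numeric(beta) || !is.numeric(alpha) || beta <= 0 || alpha <= 0) {
    stop("domain error: beta and alpha must be positive", call. = FALSE)
  }
  structure(
    list(
      species = species,
      rca = beta / alpha,
      density_equivalence = alpha / beta
    ),
    class = "rca_result"
  )
}

#' @export
print.rca_result <- function(x, ...) {
  cat(sprintf(
    "Relative competitive ability%s: %.3f\n",
    if (is.na(x$species)) "" else paste0(" of ", x$species), x$rca
  ))
  cat(sprintf(
    "  (~%.1f allospecific plants equal one conspecific)\n",
    x$density_equivalence
  ))
  invisible(x)
}

#' Density equivalence from a relative competitive ability
#'
#' The reciprocal of an RCA value: how many allospecific individuals are
#' competitively equivalent to one conspecific for the focal species.
#'
#' @param rca_value positive RCA value.
#' @return number of allospecific plants per conspecific plant.
#' @examples
#' density_equivalence_statement(0.5) # 2
#' @export
density_equivalence_statement <- function(rca_value) {
  if (!is.numeric(rca_value) || any(rca_value <= 0)) {
    stop("domain error: RCA must be positive", call. = FALSE)
  }
  1 / rca_value
}
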