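#' Methods for fitted yield-density models
#'
#' Standard model-object methods for fits returned by [fit_monoculture()]
#' and [fit_biculture()]. `coef()` returns natural-scale estimates; `vcov()`
#' returns the covariance on the `"natural"` (delta-method) or `"internal"`
#' (log-parameter) scale; `confint()` builds Wald intervals on the internal
#' scale and back-transforms them, so bounds are always positive;
#' `predict()` evaluates the fitted curve at new densities; `simulate()`
#' draws new log-biomass responses at the observed design using the fitted
#' residual SD.
#'
#' @param object,x a `yd_fit`.
#' @param ... unused.
#' @name yd_fit-methods
NULL

#' @rdname yd_fit-methods
#' @export
print.yd_fit <- function(x, ...) {
  cat(sprintf(
    "%s yield-density fit, species %s (n = %d)\n",
    if (x$kind == "monoculture") "Monoculture" else "Biculture",
    x$species, x$n
  ))
  print(signif(x$coefficients, 6))
  if (x$b_fixed) {
    cat(sprintf("exponent b fixed at %.5f (from monoculture fit)\n", x$b))
  }
  if (isTRUE(x$degenerate_ridge)) {
    cat(sprintf(
      "exponent b unidentifiable; fixed at %.2f (reciprocal-yield fallback)\n",
      x$b
    ))
  }
  if (length(x$boundary) > 0L) {
    cat(sprintf(
      "bounded fit: %s on the zero boundary\n",
      paste(x$boundary, collapse = ", ")
    ))
  }
  cat(sprintf("pseudo-r2 = %.3f\n", x$pseudo_r2))
  invisible(x)
}

#' @rdname yd_fit-methods
#' @export
summary.yd_fit <- function(object, ...) {
  tab <- cbind(
    Estimate = object$coefficients,
    `Std. Error` = object$se,
    `t value` = object$t,
    `Pr(>|t|)` = object$p
  )
  out <- list(
    kind = object$kind, species = object$species, table = tab,
    b = object$b, b_fixed = object$b_fixed, df = object$df,
    sigma = object$sigma, pseudo_r2 = object$pseudo_r2, n = object$n
  )
  class(out) <- "summary.yd_fit"
  out
}

#' @export
print.summary.yd_fit <- function(x, ...) {
  cat(sprintf(
    "%s yield-density model (log scale), species %s\n\n",
    if (x$kind == "monoculture") "Monoculture" else "Biculture", x$species
  ))
  stats::printCoefmat(x$table, digits = 5, P.values = TRUE,
    has.Pvalue = TRUE)
  if (x$b_fixed) {
    cat(sprintf("\nExponent b fixed at %.5f (monoculture stage)\n", x$b))
  }
  cat(sprintf(
    "\nResidual SD (log scale): %.4f on %d df; pseudo-r2 = %.3f; n = %d\n",
    x$sigma, x$df, x$pseudo_r2, x$n
  ))
  invisible(x)
}

#' @rdname yd_fit-methods
#' @export
coef.yd_fit <- function(object, ...) {
  object$coefficients
}

#' @rdname yd_fit-methods
#' @param scale `"natural"` for the gram/per-plant scale (delta method) or
#'   `"internal"` for the log-parameter scale the model is estimated on.
#' @export
vcov.yd_fit <- function(object, scale = c("natural", "internal"), ...) {
  scale <- match.arg(scale)
  if (scale == "natural") object$vcov_natural else object$vcov_internal
}

#' @rdname yd_fit-methods
#' @param parm parameter names (natural scale) to report; defaults to all.
#' @param level confidence level.
#' @export
confint.yd_fit <- function(object, parm, level = 0.95, ...) {
  nm <- names(object$coefficients)
  if (missing(parm)) parm <- nm
  q <- qt(1 - (1 - level) / 2, df = object$df)
  se_int <- sqrt(diag(object$vcov_internal))
  lo <- exp(object$internal - q * se_int)
  hi <- exp(object$internal + q * se_int)
  out <- cbind(lo, hi)
  dimnames(out) <- list(
    nm,
    sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  )
  out[parm, , drop = FALSE]
}

#' @rdname yd_fit-methods
#' @param newdata data frame of densities: `n_self` (and `n_other` for
#'   biculture fits; monoculture fits also accept a column `N`). Defaults to
#'   the fitting frame.
#' @param type `"response"` for grams, `"link"` for the natural-log scale.
#' @export
predict.yd_fit <- function(object, newdata = NULL,
                           type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    mu <- object$fitted
    return(if (type == "link") mu else exp(mu))
  }
  est <- object$coefficients
  if (object$kind == "monoculture") {
    N <- if ("n_self" %in% names(newdata)) newdata$n_self else newdata$N
    if (is.null(N)) stop("newdata needs a column n_self (or N)", call. = FALSE)
    w <- predict_monoculture(est[["wm"]], est[["a"]], est[["b"]], N)
  } else {
    if (!all(c("n_self", "n_other") %in% names(newdata))) {
      stop("newdata needs columns n_self and n_other", call. = FALSE)
    }
    w <- predict_biculture(
      est[["wm"]], est[["beta"]], est[["alpha"]], object$b,
      newdata$n_self, newdata$n_other
    )
  }
  if (type == "link") log(w) else w
}

#' @rdname yd_fit-methods
#' @export
fitted.yd_fit <- function(object, ...) {
  object$fitted
}

#' @rdname yd_fit-methods
#' @export
residuals.yd_fit <- function(object, ...) {
  object$residuals
}

#' @rdname yd_fit-methods
#' @param nsim number of response vectors to draw.
#' @param seed optional seed; the caller's RNG state is restored.
#' @export
simulate.yd_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    out <- as.data.frame(replicate(
      nsim,
      object$fitted + rnorm(object$n, sd = object$sigma)
    ))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' @rdname yd_fit-methods
#' @export
plot.yd_fit <- function(x, ...) {
  frame <- x$frame
  if (x$kind == "monoculture") {
    graphics::plot(frame$n_self, frame$log_w,
      xlab = "Realized density (plants/pot)",
      ylab = "ln biomass (g)",
      main = sprintf("%s monoculture", x$species), ...
    )
    grid_n <- seq(min(frame$n_self), max(frame$n_self), length.out = 100)
    graphics::lines(
      grid_n,
      predict(x, data.frame(n_self = grid_n), type = "link")
    )
  } else {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
    for (col in c("n_self", "n_other")) {
      graphics::plot(frame[[col]], frame$log_w,
        xlab = sprintf(
          "Realized %s density",
          if (col == "n_self") "conspecific" else "allospecific"
        ),
        ylab = "ln biomass (g)",
        main = sprintf("%s biculture", x$species), ...
      )
      grid_n <- seq(min(frame[[col]]), max(frame[[col]]), length.out = 100)
      held <- median(frame[[setdiff(c("n_self", "n_other"), col)]])
      nd <- if (col == "n_self") {
        data.frame(n_self = grid_n, n_other = held)
      } else {
        data.frame(n_self = held, n_other = grid_n)
      }
      graphics::lines(grid_n, predict(x, nd, type = "link"))
    }
  }
  invisible(x)
}
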