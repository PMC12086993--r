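#' Control parameters for yield-density fits
#'
#' @param restarts maximum number of additional jittered starts tried when
#'   the optimizer fails to converge from the data-driven start.
#' @param ftol,ptol Levenberg-Marquardt convergence tolerances on the
#'   relative reduction in the sum of squares and in the parameters.
#' @param maxiter maximum optimizer iterations per start.
#' @return list of class `"yd_control"`.
#' @export
yd_control <- function(restarts = 10L, ftol = 1e-12, ptol = 1e-12,
                       maxiter = 1024L) {
  structure(
    list(
      restarts = as.integer(restarts), ftol = ftol, ptol = ptol,
      maxiter = as.integer(maxiter)
    ),
    class = "yd_control"
  )
}

# Deterministic start offsets (internal log scale) used for restarts, so that
# fitting never consumes the caller's RNG stream.
start_offsets <- function() {
  rbind(
    c(0, 0, 0),
    c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1),
    c(0, -1, -1), c(0, 1, 1), c(1, -2, 0), c(-1, 2, 0),
    c(0, -3, 1), c(0, 3, -1)
  )
}

# Profiled start for the monoculture model. For fixed a the log-scale model
# is linear in the remaining parameters, so scanning log(a) over a wide grid
# locates the global basin, which the Levenberg-Marquardt polish then
# refines. Without this, starts far from the optimum can stall on the
# a -> 0, b -> Inf ridge along which the hyperbola degenerates to its
# log-linear limit. `lnwm` fixes the intercept (plug-in mean mode).
profile_start_mono <- function(log_w, N, lnwm = NULL) {
  grid <- seq(-14, 8, by = 0.25)
  best <- NULL
  for (la in grid) {
    l_crowd <- log1p(exp(la) * N)
    if (is.null(lnwm)) {
      fit <- stats::lm.fit(cbind(1, -l_crowd), log_w)
      b <- fit$coefficients[2L]
      intercept <- fit$coefficients[1L]
      sse <- sum(fit$residuals^2)
    } else {
      b <- sum(l_crowd * (lnwm - log_w)) / sum(l_crowd^2)
      intercept <- lnwm
      sse <- sum((log_w - lnwm + b * l_crowd)^2)
    }
    if (!is.finite(b) || b <= 0) next
    if (is.null(best) || sse < best$sse) {
      best <- list(theta = c(intercept, la, log(b)), sse = sse, la = la)
    }
  }
  if (is.null(best)) {
    stop("fit error: no positive-exponent start found; biomass does not ",
      "decline with density",
      call. = FALSE
    )
  }
  # Profiled optimum running off toward a -> 0 (with b -> Inf at constant
  # a*b) marks the degenerate ridge: the data do not resolve the hyperbola's
  # curvature from its log-linear limit.
  best$degenerate <- best$la <= -10
  best
}

# Coarse grid start for the biculture model: log wm has a closed form given
# (beta, alpha) and the fixed exponent (or is supplied, in plug-in mean
# mode), so a 2-D scan over the coefficients finds the global basin cheaply.
# The grid edges diagnose the two boundary modes of this likelihood: a
# coefficient running to 0 (bounded estimate at zero) and the joint scale
# ridge on which beta, alpha and wm grow without bound while only their
# ratios stay identified (the "+1" of the crowding term, i.e. the overall
# scale, is unresolved by the data).
profile_start_bi <- function(log_w, ns, no, b, lnwm = NULL) {
  grid <- seq(-13, 7, by = 0.5)
  best <- NULL
  for (lb in grid) {
    for (la in grid) {
      crowd <- b * log1p(exp(lb) * ns + exp(la) * no)
      intercept <- if (is.null(lnwm)) mean(log_w + crowd) else lnwm
      sse <- sum((log_w - intercept + crowd)^2)
      if (is.null(best) || sse < best$sse) {
        best <- list(
          theta = c(intercept, lb, la), sse = sse, lb = lb, la = la
        )
      }
    }
  }
  hi <- max(grid)
  lo <- min(grid)
  best$scale_ridge <- is.null(lnwm) &&
    (best$lb >= hi - 0.25 || best$la >= hi - 0.25)
  best$beta_zero <- best$lb <= lo + 0.25
  best$alpha_zero <- best$la <= lo + 0.25
  best
}

# Shared Levenberg-Marquardt driver on the internal log-parameter scale.
# `resid_fn(theta)` returns residuals, `jac_fn(theta)` their Jacobian.
lm_fit <- function(theta0, resid_fn, jac_fn, control) {
  offsets <- start_offsets()
  n_try <- min(nrow(offsets), control$restarts + 1L)
  ctrl <- minpack.lm::nls.lm.control(
    ftol = control$ftol, ptol = control$ptol, maxiter = control$maxiter
  )
  last_msg <- "no attempt made"
  for (i in seq_len(n_try)) {
    start <- theta0 + offsets[i, seq_along(theta0)]
    ans <- tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = resid_fn, jac = jac_fn, control = ctrl
      ),
      error = function(e) e
    )
    if (inherits(ans, "error")) {
      last_msg <- conditionMessage(ans)
      next
    }
    if (ans$info %in% 1:4) {
      ans$n_starts <- i
      return(ans)
    }
    last_msg <- ans$message
  }
  stop(
    "fit error: nonlinear least squares failed to converge after ", n_try,
    " start(s); last optimizer message: ", last_msg,
    call. = FALSE
  )
}

# Optimize over the free subset of the full internal parameter vector,
# holding the remaining entries at their values in `theta_full` (a fixed
# intercept, a fixed exponent, or -Inf for a coefficient on its zero bound).
masked_lm <- function(theta_full, free, resid_fn, jac_fn, control) {
  idx <- which(free)
  if (length(idx) == 0L) {
    stop("fit error: no free parameters", call. = FALSE)
  }
  fill <- function(th) {
    out <- theta_full
    out[idx] <- th
    out
  }
  ans <- lm_fit(
    theta_full[idx],
    function(th) resid_fn(fill(th)),
    function(th) jac_fn(fill(th))[, idx, drop = FALSE],
    control
  )
  ans$par <- fill(ans$par)
  ans$jac_at <- jac_fn(ans$par)[, idx, drop = FALSE]
  ans
}

# Covariance of the internal estimates from the model Jacobian at the
# optimum, scaled by the residual variance. J here is d(residual)/d(theta);
# J'J equals the information of d(mu)/d(theta).
internal_vcov <- function(jac, sse, n, p) {
  if (qr(jac)$rank < p) {
    stop("rank-deficiency error: singular Jacobian at the optimum; ",
      "parameters are not identifiable from this design",
      call. = FALSE
    )
  }
  sigma2 <- sse / (n - p)
  v <- sigma2 * chol2inv(chol(crossprod(jac)))
  (v + t(v)) / 2
}

finish_fit <- function(ans, frame, kind, species, param_names, b_fixed,
                       call, free = rep(TRUE, 3L), wm_mode = "estimate") {
  theta <- ans$par
  res <- as.numeric(ans$fvec)
  jac <- ans$jac_at
  n <- nrow(frame)
  p <- sum(free)
  sse <- sum(res^2)
  vcov_free <- internal_vcov(jac, sse, n, p)
  vcov_int <- matrix(0, 3L, 3L)
  vcov_int[free, free] <- vcov_free
  est <- exp(theta)
  names(est) <- param_names
  grad <- diag(est, nrow = 3L)
  vcov_nat <- grad %*% vcov_int %*% grad
  dimnames(vcov_nat) <- list(param_names, param_names)
  dimnames(vcov_int) <- list(param_names, param_names)
  se <- sqrt(diag(vcov_nat))
  df <- n - p
  t_stat <- est / se
  p_val <- 2 * pt(-abs(t_stat), df = df)
  t_stat[!free] <- NA_real_
  p_val[!free] <- NA_real_
  fitted_log <- frame$log_w - res
  structure(
    list(
      kind = kind, species = species,
      coefficients = est,
      internal = setNames(theta, paste0("log_", param_names)),
      b = if (kind == "monoculture") est[["b"]] else b_fixed,
      b_fixed = kind == "biculture",
      degenerate_ridge = kind == "monoculture" && !free[3L],
      wm_mode = wm_mode,
      se = se, t = t_stat, p = p_val, df = df,
      vcov_internal = vcov_int, vcov_natural = vcov_nat,
      sigma = sqrt(sse / df), sse = sse,
      pseudo_r2 = pseudo_r2(frame$log_w, fitted_log),
      n = n, n_starts = ans$n_starts, optimizer_info = ans$info,
      fitted = fitted_log, residuals = res, frame = frame, call = call
    ),
    class = c(if (kind == "monoculture") "mono_fit" else "bi_fit", "yd_fit")
  )
}

take_species_frame <- function(frame, species) {
  if (!all(c("log_w", "n_self") %in% names(frame))) {
    stop("frame must come from prepare_log_response() ",
      "(columns log_w, n_self required)",
      call. = FALSE
    )
  }
  if (!is.null(species)) {
    frame <- frame[frame$species == species, , drop = FALSE]
  } else if ("species" %in% names(frame)) {
    sp <- unique(frame$species)
    if (length(sp) > 1L) {
      stop("frame contains several species; pass species = \"BRTE\" or ",
        "\"VEDU\"",
        call. = FALSE
      )
    }
    species <- sp
  }
  if (nrow(frame) == 0L) {
    stop("no records for the requested species", call. = FALSE)
  }
  list(frame = frame, species = species)
}

# Plug-in intercept: the natural log of the frame's mean raw biomass. This
# reproduces the convention of fixing wm at the observed group mean rather
# than estimating it (all four published intercepts equal the printed group
# means), and it anchors the model's overall scale.
plugin_lnwm <- function(frame, wm_mode) {
  if (wm_mode != "mean") {
    return(NULL)
  }
  if (!"biomass_g" %in% names(frame)) {
    stop("wm_mode = \"mean\" needs the biomass_g column in the frame",
      call. = FALSE
    )
  }
  log(mean(frame$biomass_g))
}

#' Fit the monoculture yield-density model
#'
#' Estimates the hyperbolic yield-density law by nonlinear least squares on
#' the natural-log scale, minimizing
#' `sum(log(w_i) - (log(wm) - b * log(1 + a * N_i)))^2` over the realized
#' harvest densities `N_i` (= `n_self` in the modelling frame). Parameters
#' are estimated on the log scale internally, which enforces positivity;
#' estimates, standard errors (delta method), Wald t statistics and
#' two-sided p-values (Student-t reference with residual df) are reported on
#' the natural scale. The optimizer starts from a profiled grid search (for
#' fixed `a` the log-scale model is linear in the rest), which locates the
#' global basin before the Levenberg-Marquardt polish; deterministic
#' jittered restarts are used on non-convergence.
#'
#' Two intercept conventions are supported. With `wm_mode = "estimate"`
#' (default) `wm` is a free parameter — the generative-model reading, under
#' which noise-free data are recovered exactly. With `wm_mode = "mean"` the
#' intercept is fixed at the frame's mean raw biomass (a plug-in, reported
#' with zero variance), the convention under which published intercepts
#' equal printed group means; it anchors the curve's scale, which matters
#' when all observed densities are strongly crowded.
#'
#' When the data do not resolve the hyperbola's curvature — common in
#' simulated experiments when the true crowding coefficient is small
#' relative to the noise — the sum of squares decreases monotonically along
#' the `a -> 0`, `b -> Inf` ridge (only the product `a * b` is identified)
#' and no interior optimum exists. The profiled grid start detects this. By
#' default the fit then fails with a rank-deficiency error; with
#' `on_degenerate = "fix_b"` it instead falls back to the reciprocal-yield
#' special case, re-fitting with the exponent held at `b_degenerate`
#' (default 1, the classical constant-final-yield value) and reporting `b`
#' with zero variance and a `degenerate_ridge` flag.
#'
#' @param frame modelling frame from [prepare_log_response()] (one species,
#'   or use `species` to subset).
#' @param species optional species code to subset the frame.
#' @param control a [yd_control()] list.
#' @param on_degenerate `"error"` (default) or `"fix_b"`: what to do when
#'   the exponent is unidentifiable (degenerate ridge).
#' @param b_degenerate exponent used by the `"fix_b"` fallback.
#' @param wm_mode `"estimate"` (free intercept) or `"mean"` (intercept fixed
#'   at the mean observed biomass).
#' @return an object of class `c("mono_fit", "yd_fit")`; see
#'   [summary.yd_fit()].
#' @examples
#' tab <- simulate_addition_series(seed = 3)
#' mono <- split_monoculture_biculture(tab)$monoculture
#' fit <- fit_monoculture(prepare_log_response(mono), species = "BRTE")
#' coef(fit)
#' @export
fit_monoculture <- function(frame, species = NULL, control = yd_control(),
                            on_degenerate = c("error", "fix_b"),
                            b_degenerate = 1,
                            wm_mode = c("estimate", "mean")) {
  on_degenerate <- match.arg(on_degenerate)
  wm_mode <- match.arg(wm_mode)
  sel <- take_species_frame(frame, species)
  frame <- sel$frame
  n_levels <- length(unique(frame$n_self))
  if (n_levels < 3L) {
    stop("fit_monoculture needs at least 3 distinct density levels; got ",
      n_levels,
      call. = FALSE
    )
  }
  if (nrow(frame) <= 3L) {
    stop("fit_monoculture needs more observations than parameters (3)",
      call. = FALSE
    )
  }
  log_w <- frame$log_w
  N <- frame$n_self
  lnwm_fix <- plugin_lnwm(frame, wm_mode)
  resid_fn <- function(theta) {
    log_w - (theta[1L] - exp(theta[3L]) * log1p(exp(theta[2L]) * N))
  }
  jac_fn <- function(theta) {
    a <- exp(theta[2L])
    b <- exp(theta[3L])
    denom <- 1 + a * N
    cbind(-1, b * a * N / denom, b * log1p(a * N))
  }
  start <- profile_start_mono(log_w, N, lnwm_fix)
  free <- c(is.null(lnwm_fix), TRUE, TRUE)
  if (start$degenerate) {
    if (on_degenerate == "error") {
      stop(
        "rank-deficiency error: the exponent b is not identifiable from ",
        "these data (sum of squares decreases monotonically along the ",
        "a -> 0, b -> Inf ridge; only a*b is determined); ",
        "consider on_degenerate = \"fix_b\"",
        call. = FALSE
      )
    }
    free[3L] <- FALSE
    # restart the crowding scan with the exponent pinned
    grid <- seq(-12, 8, by = 0.25)
    sses <- vapply(grid, function(la) {
      crowd <- b_degenerate * log1p(exp(la) * N)
      intercept <- if (is.null(lnwm_fix)) mean(log_w + crowd) else lnwm_fix
      sum((log_w - intercept + crowd)^2)
    }, numeric(1L))
    la0 <- grid[which.min(sses)]
    crowd0 <- b_degenerate * log1p(exp(la0) * N)
    int0 <- if (is.null(lnwm_fix)) mean(log_w + crowd0) else lnwm_fix
    start$theta <- c(int0, la0, log(b_degenerate))
  }
  ans <- masked_lm(start$theta, free, resid_fn, jac_fn, control)
  finish_fit(ans, frame,
    kind = "monoculture", species = sel$species,
    param_names = c("wm", "a", "b"), b_fixed = NULL, call = match.call(),
    free = free, wm_mode = wm_mode
  )
}

#' Fit the biculture competition model with a fixed exponent
#'
#' Estimates the two-species competition model by nonlinear least squares on
#' the natural-log scale, minimizing
#' `sum(log(w_i) - (log(wm) - b * log(1 + beta * n_self_i +
#' alpha * n_other_i)))^2` with the exponent `b` held at the value estimated
#' from the focal species' monoculture fit — the two-stage scheme standard
#' for addition-series analyses, which keeps the density-response shape
#' common to both stand types. `beta` measures intraspecific (conspecific)
#' and `alpha` interspecific (allospecific) per-plant competition. Inference
#' is as in [fit_monoculture()] (Wald, residual df), and the same two
#' intercept conventions (`wm_mode`) are available.
#'
#' The fit is bounded: a coefficient whose profiled optimum runs to zero is
#' held on the boundary (reported as exactly 0 with `NA` inference and
#' listed in the fit's `boundary` field) and the remaining parameters are
#' re-estimated. With a free intercept the likelihood can also degenerate
#' along the joint scale ridge (`wm`, `beta`, `alpha` growing without bound
#' with only their ratios identified); that raises a rank-deficiency error.
#'
#' @inheritParams fit_monoculture
#' @param b fixed positive exponent, normally `coef(mono_fit)[["b"]]` of the
#'   focal species.
#' @return an object of class `c("bi_fit", "yd_fit")`.
#' @examples
#' tab <- simulate_addition_series(seed = 3)
#' parts <- split_monoculture_biculture(tab)
#' mono <- fit_monoculture(prepare_log_response(parts$monoculture), "BRTE")
#' bi <- fit_biculture(prepare_log_response(parts$biculture), "BRTE",
#'   b = coef(mono)[["b"]]
#' )
#' summary(bi)
#' @export
fit_biculture <- function(frame, species = NULL, b, control = yd_control(),
                          wm_mode = c("estimate", "mean")) {
  if (!is.numeric(b) || length(b) != 1L || b <= 0) {
    stop("b must be a single positive number (from the monoculture fit)",
      call. = FALSE
    )
  }
  wm_mode <- match.arg(wm_mode)
  sel <- take_species_frame(frame, species)
  frame <- sel$frame
  if (!"n_other" %in% names(frame)) {
    stop("frame must contain n_other (allospecific realized density)",
      call. = FALSE
    )
  }
  if (all(frame$n_other == 0)) {
    stop("degenerate-design error: all allospecific densities are zero; ",
      "alpha is unidentifiable",
      call. = FALSE
    )
  }
  if (nrow(frame) <= 3L) {
    stop("fit_biculture needs more observations than parameters (3)",
      call. = FALSE
    )
  }
  log_w <- frame$log_w
  ns <- frame$n_self
  no <- frame$n_other
  lnwm_fix <- plugin_lnwm(frame, wm_mode)
  resid_fn <- function(theta) {
    log_w - (theta[1L] -
      b * log1p(exp(theta[2L]) * ns + exp(theta[3L]) * no))
  }
  jac_fn <- function(theta) {
    beta <- exp(theta[2L])
    alpha <- exp(theta[3L])
    denom <- 1 + beta * ns + alpha * no
    cbind(-1, b * beta * ns / denom, b * alpha * no / denom)
  }
  start <- profile_start_bi(log_w, ns, no, b, lnwm_fix)
  if (start$scale_ridge) {
    stop(
      "rank-deficiency error: the overall scale of (wm, beta, alpha) is ",
      "not identifiable from these data (the sum of squares decreases ",
      "monotonically as the coefficients grow jointly toward the power-law ",
      "limit; only coefficient ratios are determined)",
      call. = FALSE
    )
  }
  fixed_zero <- c(FALSE, start$beta_zero, start$alpha_zero)
  free <- c(is.null(lnwm_fix), !fixed_zero[2:3])
  theta_full <- start$theta
  theta_full[fixed_zero] <- -Inf
  if (!is.null(lnwm_fix)) theta_full[1L] <- lnwm_fix
  ans <- masked_lm(theta_full, free, resid_fn, jac_fn, control)
  fit <- finish_fit(ans, frame,
    kind = "biculture", species = sel$species,
    param_names = c("wm", "beta", "alpha"), b_fixed = b, call = match.call(),
    free = free, wm_mode = wm_mode
  )
  if (any(fixed_zero)) {
    fit$boundary <- c("beta", "alpha")[fixed_zero[2:3]]
  }
  fit
}

#' Coefficient report for biculture fits
#'
#' Lays out the intraspecific (`beta`) and interspecific (`alpha`)
#' competition coefficients of one or more biculture fits as report rows —
#' estimate, standard error, Wald t and two-sided p, each rounded to 4
#' decimal places (t is estimate/SE at full precision before rounding).
#'
#' @param fits a `bi_fit` or a list of them.
#' @param digits decimal places for rounding (default 4).
#' @return data frame with columns `species`, `parameter`, `estimate`,
#'   `std_error`, `t_value`, `p_value`.
#' @export
coefficient_table <- function(fits, digits = 4L) {
  if (inherits(fits, "yd_fit")) fits <- list(fits)
  rows <- lapply(fits, function(fit) {
    stopifnot(inherits(fit, "bi_fit"))
    idx <- c("beta", "alpha")
    data.frame(
      species = fit$species,
      parameter = paste0(idx, "_", fit$species),
      estimate = round(unname(fit$coefficients[idx]), digits),
      std_error = round(unname(fit$se[idx]), digits),
      t_value = round(unname(fit$t[idx]), digits),
      p_value = round(unname(fit$p[idx]), digits)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
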