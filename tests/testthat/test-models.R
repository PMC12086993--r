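test_that("hyperbolic predictions match hand-computed values", {
  expect_equal(predict_monoculture(0.5, 2, 1, 0), 0.5)
  expect_equal(predict_monoculture(0.1, 1, 1, 1), 0.05)
  # published monoculture curve evaluated at N = 4 (frozen hand computation)
  expect_equal(
    predict_monoculture(0.113, 9.18040, 0.96848, 4),
    0.0033587869575156942,
    tolerance = 1e-12
  )
  expect_equal(predict_biculture(1, 0, 1, 1, 5, 1), 0.5)
  expect_equal(predict_biculture(0.2, 0.3, 0.7, 1.1, 0, 0), 0.2)
  # published biculture curve at two plants of each species (frozen)
  expect_equal(
    predict_biculture(0.10768, 0.13090, 5.6387, 0.96848, 2, 2),
    0.009299994302272666,
    tolerance = 1e-12
  )
  expect_error(predict_monoculture(1, 1, 1, -1), "domain error")
  expect_error(predict_biculture(1, 1, 1, 1, -1, 0), "domain error")
})

test_that("biculture prediction reduces to monoculture and is monotone", {
  grid <- expand.grid(wm = c(0.05, 0.2), c1 = c(0.1, 2), b = c(0.5, 1.3))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    N <- 0:16
    expect_equal(
      predict_biculture(g$wm, g$c1, 0.7, g$b, N, 0),
      predict_monoculture(g$wm, g$c1, g$b, N)
    )
    w <- predict_biculture(g$wm, g$c1, 0.7, g$b, N, 2)
    expect_true(all(diff(w) < 0))
    w2 <- predict_biculture(g$wm, g$c1, 0.7, g$b, 3, N)
    expect_true(all(diff(w2) < 0))
  }
})

test_that("pseudo-r2 is 1 minus SSE/SST on the log scale", {
  obs <- log(c(0.1, 0.2, 0.05, 0.08))
  expect_equal(pseudo_r2(obs, obs), 1)
  expect_equal(pseudo_r2(obs, rep(mean(obs), 4)), 0)
  expect_true(is.na(pseudo_r2(rep(1, 4), rep(1, 4))))
  # worse than the mean goes negative
  expect_lt(pseudo_r2(obs, rev(obs)), 0)
})

test_that("noise-free monoculture data are recovered exactly", {
  N <- rep(c(1, 2, 4, 8, 16), each = 3)
  frame <- data.frame(
    log_w = log(predict_monoculture(0.1, 1, 1, N)),
    n_self = N, biomass_g = predict_monoculture(0.1, 1, 1, N),
    species = "BRTE"
  )
  fit <- fit_monoculture(frame)
  expect_lt(relative_error(coef(fit)[["wm"]], 0.1), 1e-6)
  expect_lt(relative_error(coef(fit)[["a"]], 1), 1e-6)
  expect_lt(relative_error(coef(fit)[["b"]], 1), 1e-6)
  expect_equal(fit$pseudo_r2, 1, tolerance = 1e-9)
})

test_that("fitted optima beat a dense local parameter grid", {
  # brute-force oracle on small noisy datasets: no grid point near the truth
  # may have a smaller SSE than the optimizer's solution
  for (s in 1:3) {
    pars <- list(
      BRTE = species_params(0.113, 0.96848, 0.6, 2.5, sigma_log = 0.2),
      VEDU = species_params(0.028, 0.9673, 0.57514, 1.88184, sigma_log = 0.2)
    )
    tab <- simulate_addition_series(
      mono_densities = c(1, 2, 4, 8, 16), bi_densities = c(2, 4, 8),
      replicates = 1, params = pars, seed = 400 + s
    )
    parts <- split_monoculture_biculture(tab)
    frame <- prepare_log_response(parts$monoculture)
    fr <- frame[frame$species == "BRTE", ]
    fit <- fit_monoculture(fr)
    mult <- exp(seq(-0.7, 0.7, length.out = 15))
    grid_sse <- Inf
    for (wm in 0.113 * mult) {
      for (a in 0.6 * mult) {
        for (b in 0.96848 * mult) {
          sse <- sum((fr$log_w - log(predict_monoculture(wm, a, b, fr$n_self)))^2)
          grid_sse <- min(grid_sse, sse)
        }
      }
    }
    expect_lte(fit$sse, grid_sse + 1e-9)
  }
})

test_that("biculture stage holds b fixed and reports Wald inference", {
  pars <- exact_params()
  tab <- simulate_addition_series(
    params = default_species_params(
      sigma_log_brte = 0.3, sigma_log_vedu = 0.3
    ),
    seed = 15
  )
  frame <- prepare_log_response(split_monoculture_biculture(tab)$biculture)
  fit <- fit_biculture(frame, "VEDU", b = 0.9673)
  expect_s3_class(fit, "bi_fit")
  expect_true(fit$b_fixed)
  expect_equal(fit$b, 0.9673)
  expect_equal(fit$df, fit$n - 3L)
  # t is estimate/SE at full precision
  expect_equal(fit$t[["beta"]], coef(fit)[["beta"]] / fit$se[["beta"]])
  expect_equal(
    fit$p[["alpha"]],
    2 * pt(-abs(fit$t[["alpha"]]), df = fit$df)
  )
  tab_rows <- coefficient_table(fit)
  expect_equal(nrow(tab_rows), 2L)
  expect_equal(
    tab_rows$estimate,
    round(unname(coef(fit)[c("beta", "alpha")]), 4)
  )
  expect_equal(round(2.49603, 4), 2.4960)
})

test_that("degenerate designs and inputs raise informative fit errors", {
  frame <- data.frame(
    log_w = log(c(0.1, 0.09, 0.05, 0.04)), n_self = c(1, 1, 4, 4),
    biomass_g = c(0.1, 0.09, 0.05, 0.04), species = "BRTE"
  )
  expect_error(fit_monoculture(frame), "3 distinct density levels")

  bi_frame <- data.frame(
    log_w = log(c(0.1, 0.05, 0.04, 0.03, 0.02)),
    n_self = c(1, 2, 4, 8, 16), n_other = 0,
    species = "BRTE"
  )
  expect_error(fit_biculture(bi_frame, b = 1), "degenerate-design")
  expect_error(fit_biculture(bi_frame, b = -1), "positive")
})

test_that("the log-linear ridge is detected, with an optional b=1 fallback", {
  # data generated from pure exponential decline: the hyperbola's optimum
  # runs along a -> 0, b -> Inf and the exponent is unidentifiable
  withr::with_seed(8, {
    N <- rep(c(1, 2, 4, 8, 16), each = 8)
    log_w <- log(0.1) - 0.05 * N + rnorm(length(N), sd = 0.05)
    frame <- data.frame(
      log_w = log_w, n_self = N, biomass_g = exp(log_w), species = "BRTE"
    )
    expect_error(fit_monoculture(frame), "rank-deficiency")
    fit <- fit_monoculture(frame, on_degenerate = "fix_b")
    expect_true(fit$degenerate_ridge)
    expect_equal(coef(fit)[["b"]], 1)
    expect_equal(fit$se[["b"]], 0)
    expect_equal(fit$df, fit$n - 2L)
    # a*b ~ local slope is still estimated sensibly
    expect_equal(coef(fit)[["a"]], 0.05, tolerance = 0.3)
  })
})

test_that("a coefficient preferring zero is reported as a bounded fit", {
  pars <- list(
    BRTE = species_params(0.113, 0.96848, 0, 3, sigma_log = 0.1),
    VEDU = species_params(0.028, 0.9673, 0.5, 1.8, sigma_log = 0.1)
  )
  tab <- simulate_addition_series(params = pars, seed = 21)
  frame <- prepare_log_response(split_monoculture_biculture(tab)$biculture)
  fit <- fit_biculture(frame, "BRTE", b = 0.96848)
  expect_equal(fit$boundary, "beta")
  expect_equal(coef(fit)[["beta"]], 0)
  expect_true(is.na(fit$t[["beta"]]))
  # the free coefficients are still estimated
  expect_gt(coef(fit)[["alpha"]], 0)
  expect_lt(relative_error(coef(fit)[["alpha"]], 3), 0.5)
})

test_that("model-object methods are coherent", {
  pars <- exact_params()
  tab <- simulate_addition_series(params = pars, seed = 2)
  parts <- split_monoculture_biculture(tab)
  fit <- fit_monoculture(prepare_log_response(parts$monoculture), "VEDU")
  expect_equal(unname(coef(fit)), unname(exp(fit$internal)))
  expect_equal(dim(vcov(fit)), c(3L, 3L))
  v <- vcov(fit, scale = "internal")
  expect_true(all(abs(v - t(v)) < 1e-12))
  expect_true(all(eigen(v, only.values = TRUE)$values > -1e-12))
  expect_equal(fitted(fit) + residuals(fit), fit$frame$log_w)
  nd <- data.frame(n_self = c(0, 4))
  expect_equal(predict(fit, nd)[1], coef(fit)[["wm"]], ignore_attr = TRUE)
  expect_equal(
    predict(fit, nd, type = "link"), log(predict(fit, nd)),
    ignore_attr = TRUE
  )
  ci <- confint(fit)
  expect_true(all(ci[, 1] > 0))
  expect_true(all(ci[, 1] <= coef(fit) & coef(fit) <= ci[, 2]))
  sims <- simulate(fit, nsim = 3, seed = 5)
  expect_equal(dim(sims), c(fit$n, 3L))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 5))
  expect_output(print(fit), "Monoculture yield-density fit")
  expect_output(print(summary(fit)), "pseudo-r2")
})
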