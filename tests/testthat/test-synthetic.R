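test_that("design enumeration matches the addition-series layout", {
  d <- addition_series_design()
  expect_equal(nrow(d), 76L) # (5 + 5 + 9) compositions x 4 replicates
  mono <- xor(d$planted_n_brte > 0, d$planted_n_vedu > 0)
  expect_equal(sum(mono), 40L)
  expect_equal(sum(!mono), 36L)

  expect_equal(nrow(addition_series_design(1, integer(0), 1)), 2L)
  d2 <- addition_series_design(integer(0), 2, 1)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$planted_n_brte, 2L)
  expect_equal(d2$planted_n_vedu, 2L)
  expect_error(
    addition_series_design(integer(0), integer(0)),
    "configuration error"
  )
  expect_error(addition_series_design(c(0, 2)), "positive")
})

test_that("survival is binomial per plant and degenerate at p = 1", {
  params <- exact_params()
  d <- addition_series_design(replicates = 1)
  out <- withr::with_seed(1, simulate_survival(d, params))
  expect_equal(out$realized_n_brte, d$planted_n_brte)
  expect_equal(out$realized_n_vedu, d$planted_n_vedu)

  # binomial moments: planted 16, p = 0.9 over many pots
  many <- data.frame(
    pot_id = "x", replicate = 1L,
    planted_n_brte = rep(16L, 10000L), planted_n_vedu = 0L
  )
  p9 <- default_species_params(survival_p_brte = 0.9)
  r <- withr::with_seed(2, simulate_survival(many, p9))
  se <- sqrt(16 * 0.9 * 0.1) / sqrt(10000)
  expect_lt(abs(mean(r$realized_n_brte) - 14.4), 3 * se)

  # determinism under a fixed seed
  r1 <- withr::with_seed(3, simulate_survival(d, p9))
  r2 <- withr::with_seed(3, simulate_survival(d, p9))
  expect_identical(r1, r2)
})

test_that("biomass draws follow the competition mean with lognormal noise", {
  # noise-free values are the model mean exactly
  p <- species_params(wm = 0.1, b = 1, beta = 0, alpha = 1, sigma_log = 0)
  expect_equal(simulate_biomass(1L, 1L, p), 0.05)
  p2 <- species_params(
    wm = 0.113, b = 0.96848, beta = 0.1309, alpha = 5.6387, sigma_log = 0
  )
  expect_equal(
    simulate_biomass(1L, 0L, p2),
    0.113 * (1 + 0.1309)^(-0.96848)
  )
  # zero realized focal density emits no records
  expect_length(simulate_biomass(0L, 4L, p2), 0L)

  # lognormal moments: mean of log draws matches log of the model mean
  p3 <- species_params(
    wm = 0.1, b = 1, beta = 0.2, alpha = 0.5, sigma_log = 0.5
  )
  draws <- withr::with_seed(4, {
    replicate(2500, simulate_biomass(4L, 2L, p3))
  })
  expected <- log(0.1 * (1 + 0.2 * 4 + 0.5 * 2)^(-1))
  se <- 0.5 / sqrt(length(draws))
  expect_lt(abs(mean(log(draws)) - expected), 3 * se)
  expect_true(all(draws > 0))
})

test_that("generated datasets have the expected structure and metadata", {
  tab <- simulate_addition_series(params = exact_params(), seed = 11)
  # survival 1: every planted plant yields one record
  d <- addition_series_design()
  expect_equal(nrow(tab), sum(d$planted_n_brte) + sum(d$planted_n_vedu))
  expect_silent(validate_plant_table(tab))
  parts <- split_monoculture_biculture(tab)
  expect_equal(length(unique(parts$monoculture$pot_id)), 40L)
  expect_equal(length(unique(parts$biculture$pot_id)), 36L)
  meta <- experiment_metadata(tab)
  expect_equal(meta$seed, 11)
  expect_equal(meta$true_params$BRTE$wm, 0.113)
})

test_that("generation is reproducible: same seed, byte-identical CSV", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_plant_table(simulate_addition_series(seed = 42), f1)
  write_plant_table(simulate_addition_series(seed = 42), f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_plant_table(simulate_addition_series(seed = 43), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("noise-free generation is exactly invertible by the fitters", {
  # the generator and the fitters must share the density convention
  # (N includes the focal plant); any mismatch breaks exact recovery
  draws <- withr::with_seed(99, data.frame(
    wm = runif(20, 0.02, 0.2),
    b = runif(20, 0.6, 1.4),
    beta = runif(20, 0.1, 1),
    alpha = runif(20, 0.5, 4)
  ))
  for (i in seq_len(nrow(draws))) {
    th <- draws[i, ]
    pars <- list(
      BRTE = species_params(th$wm, th$b, th$beta, th$alpha,
        sigma_log = 0, survival_p = 1
      ),
      VEDU = species_params(0.03, 0.9, 0.5, 1.8,
        sigma_log = 0, survival_p = 1
      )
    )
    tab <- simulate_addition_series(
      replicates = 2, params = pars, seed = 1000 + i
    )
    parts <- split_monoculture_biculture(tab)
    mono <- fit_monoculture(
      prepare_log_response(parts$monoculture), "BRTE"
    )
    expect_lt(relative_error(coef(mono)[["wm"]], th$wm), 1e-6)
    expect_lt(relative_error(coef(mono)[["a"]], th$beta), 1e-6)
    expect_lt(relative_error(coef(mono)[["b"]], th$b), 1e-6)
    bi <- fit_biculture(
      prepare_log_response(parts$biculture), "BRTE",
      b = coef(mono)[["b"]]
    )
    expect_lt(relative_error(coef(bi)[["wm"]], th$wm), 1e-6)
    expect_lt(relative_error(coef(bi)[["beta"]], th$beta), 1e-6)
    expect_lt(relative_error(coef(bi)[["alpha"]], th$alpha), 1e-6)
  }
})
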