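# Shared fixtures, all built in code.

# A minimal hand-written table: one BRTE monoculture pot (density 2) and one
# 2:2 biculture pot, replicate 1.
toy_table <- function() {
  as_experiment_table(data.frame(
    pot_id = c("m1", "m1", "b1", "b1", "b1", "b1"),
    replicate = 1L,
    species = c("BRTE", "BRTE", "BRTE", "BRTE", "VEDU", "VEDU"),
    planted_n_brte = c(2L, 2L, 2L, 2L, 2L, 2L),
    planted_n_vedu = c(0L, 0L, 2L, 2L, 2L, 2L),
    realized_n_brte = c(2L, 2L, 2L, 2L, 2L, 2L),
    realized_n_vedu = c(0L, 0L, 2L, 2L, 2L, 2L),
    biomass_g = c(0.12, 0.1, 0.05, 0.06, 0.02, 0.025)
  ))
}

# Noise-free, mortality-free parameter set at published magnitudes.
exact_params <- function() {
  default_species_params(
    sigma_log_brte = 0, sigma_log_vedu = 0,
    survival_p_brte = 1, survival_p_vedu = 1
  )
}

# Random but valid per-plant records for round-trip tests.
random_records <- function(n, seed) {
  withr::with_seed(seed, {
    planted <- sample(c(1L, 2L, 4L, 8L, 16L), n, replace = TRUE)
    species <- sample(c("BRTE", "VEDU"), n, replace = TRUE)
    data.frame(
      pot_id = sprintf("p%03d", seq_len(n)),
      replicate = sample(1:4, n, replace = TRUE),
      species = species,
      planted_n_brte = ifelse(species == "BRTE", planted, 0L),
      planted_n_vedu = ifelse(species == "VEDU", planted, 0L),
      realized_n_brte = ifelse(species == "BRTE", pmax(1L, planted - 1L), 0L),
      realized_n_vedu = ifelse(species == "VEDU", pmax(1L, planted - 1L), 0L),
      biomass_g = round(runif(n, 0.001, 0.4), 3)
    )
  })
}

relative_error <- function(est, truth) {
  abs(est - truth) / abs(truth)
}
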