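#' Addition-series design matrix
#'
#' Enumerates the pots of an addition series: monocultures of each species at
#' every density in `mono_densities`, plus bicultures at every ordered pair of
#' densities from `bi_densities`, each composition repeated `replicates`
#' times. With the defaults (monocultures at 1, 2, 4, 8, 16; biculture pairs
#' from 2, 4, 8; 4 replicates) that is (5 + 5 + 9) x 4 = 76 pots.
#'
#' @param mono_densities integer vector of monoculture planting densities
#'   (plants per pot) used for each species.
#' @param bi_densities integer vector of densities crossed pairwise for the
#'   two-species pots.
#' @param replicates number of replicates of the full matrix.
#' @return data frame with one row per pot: `pot_id`, `replicate`,
#'   `planted_n_brte`, `planted_n_vedu`.
#' @examples
#' nrow(addition_series_design()) # 76
#' @export
addition_series_design <- function(mono_densities = c(1, 2, 4, 8, 16),
                                   bi_densities = c(2, 4, 8),
                                   replicates = 4) {
  mono_densities <- sort(unique(as.integer(mono_densities)))
  bi_densities <- sort(unique(as.integer(bi_densities)))
  if (length(mono_densities) + length(bi_densities) == 0L) {
    stop("configuration error: both density sets are empty", call. = FALSE)
  }
  if (any(c(mono_densities, bi_densities) < 1L)) {
    stop("configuration error: densities must be positive integers",
      call. = FALSE
    )
  }
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L) {
    stop("configuration error: replicates must be >= 1", call. = FALSE)
  }
  comps <- rbind(
    if (length(mono_densities) > 0L) {
      data.frame(planted_n_brte = mono_densities, planted_n_vedu = 0L)
    },
    if (length(mono_densities) > 0L) {
      data.frame(planted_n_brte = 0L, planted_n_vedu = mono_densities)
    },
    if (length(bi_densities) > 0L) {
      expand.grid(
        planted_n_brte = bi_densities,
        planted_n_vedu = bi_densities
      )
    }
  )
  design <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    cbind(replicate = r, comps)
  }))
  design$pot_id <- sprintf(
    "R%d_B%d_V%d",
    design$replicate, design$planted_n_brte, design$planted_n_vedu
  )
  rownames(design) <- NULL
  design[, c("pot_id", "replicate", "planted_n_brte", "planted_n_vedu")]
}

#' Species-level simulation parameters
#'
#' Bundles the generative parameters of one species for the yield-density
#' model: `wm`, the mean biomass (g) of an isolated plant; `b`, the
#' dimensionless exponent of the hyperbolic decline (interpreted in the field
#' as a species' mean resource-use efficiency); `beta`, the per-conspecific
#' intraspecific crowding coefficient; `alpha`, the per-allospecific
#' interspecific coefficient; `sigma_log`, the standard deviation of the
#' additive Gaussian noise on the natural-log biomass scale (so biomass noise
#' is multiplicative lognormal; 0 gives deterministic biomass); and
#' `survival_p`, the per-plant probability of surviving to harvest.
#'
#' `default_species_params()` returns parameters for both species at
#' magnitudes matching published greenhouse fits for *Bromus tectorum* and
#' *Ventenata dubia*, with `sigma_log = 0.5` and `survival_p = 0.9`.
#'
#' @param wm mean isolated-plant biomass, grams, > 0.
#' @param b hyperbolic exponent, dimensionless, > 0.
#' @param beta intraspecific competition coefficient per plant, >= 0.
#' @param alpha interspecific competition coefficient per plant, >= 0.
#' @param sigma_log SD of log-scale noise, >= 0.
#' @param survival_p per-plant survival probability in (0, 1].
#' @return an object of class `"species_params"`.
#' @export
species_params <- function(wm, b, beta, alpha, sigma_log = 0.5,
                           survival_p = 0.9) {
  stopifnot(
    is.numeric(wm), length(wm) == 1L, wm > 0,
    is.numeric(b), length(b) == 1L, b > 0,
    is.numeric(beta), length(beta) == 1L, beta >= 0,
    is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
    is.numeric(sigma_log), length(sigma_log) == 1L, sigma_log >= 0,
    is.numeric(survival_p), length(survival_p) == 1L,
    survival_p > 0, survival_p <= 1
  )
  structure(
    list(
      wm = wm, b = b, beta = beta, alpha = alpha,
      sigma_log = sigma_log, survival_p = survival_p
    ),
    class = "species_params"
  )
}

#' @rdname species_params
#' @param sigma_log_brte,sigma_log_vedu log-scale noise SD per species.
#' @param survival_p_brte,survival_p_vedu survival probability per species.
#' @export
default_species_params <- function(sigma_log_brte = 0.5,
                                   sigma_log_vedu = 0.5,
                                   survival_p_brte = 0.9,
                                   survival_p_vedu = 0.9) {
  list(
    BRTE = species_params(
      wm = 0.113, b = 0.96848, beta = 0.1309, alpha = 5.6387,
      sigma_log = sigma_log_brte, survival_p = survival_p_brte
    ),
    VEDU = species_params(
      wm = 0.02808, b = 0.96730, beta = 0.57514, alpha = 1.88184,
      sigma_log = sigma_log_vedu, survival_p = survival_p_vedu
    )
  )
}

check_params_pair <- function(params) {
  if (!is.list(params) || !all(SPECIES_CODES %in% names(params))) {
    stop("params must be a list with elements 'BRTE' and 'VEDU'",
      call. = FALSE
    )
  }
  for (sp in SPECIES_CODES) {
    if (!inherits(params[[sp]], "species_params")) {
      params[[sp]] <- do.call(species_params, as.list(params[[sp]]))
    }
  }
  params
}

#' Simulate plant survival to harvest
#'
#' Each planted plant survives to harvest independently with its species'
#' `survival_p`, so the realized density of species X in a pot is
#' Binomial(planted_n_X, survival_p_X). This reproduces the routine
#' observation that high-density pots rarely hold their full planted count at
#' harvest. Draws use the current RNG state; seed the caller for
#' reproducibility.
#'
#' @param design a design data frame from [addition_series_design()].
#' @param params list with `species_params` for `BRTE` and `VEDU`.
#' @return `design` with `realized_n_brte` and `realized_n_vedu` columns.
#' @export
simulate_survival <- function(design, params) {
  params <- check_params_pair(params)
  n <- nrow(design)
  design$realized_n_brte <- rbinom(
    n, design$planted_n_brte, params$BRTE$survival_p
  )
  design$realized_n_vedu <- rbinom(
    n, design$planted_n_vedu, params$VEDU$survival_p
  )
  design
}

#' Simulate per-plant biomass in one pot
#'
#' Each surviving plant of the focal species receives biomass
#' `mean * exp(eps)` with `eps ~ Normal(0, sigma_log^2)`, where `mean` is the
#' hyperbolic competition model
#' `wm * (1 + beta * n_self + alpha * n_other)^(-b)` evaluated at the pot's
#' realized densities. `n_self` is the total realized density of the focal
#' species at harvest and *includes* the focal plant itself — the same
#' density convention the fitting functions use. A zero realized density of
#' the focal species yields a zero-length result, not an error.
#'
#' @param n_self realized density of the focal species (plants per pot).
#' @param n_other realized density of the other species.
#' @param params a [species_params()] object for the focal species.
#' @return numeric vector of `n_self` biomass values (grams), all > 0.
#' @export
simulate_biomass <- function(n_self, n_other, params) {
  stopifnot(inherits(params, "species_params"))
  n_self <- as.integer(n_self)
  n_other <- as.integer(n_other)
  stopifnot(length(n_self) == 1L, length(n_other) == 1L,
    n_self >= 0L, n_other >= 0L)
  if (n_self == 0L) {
    return(numeric(0L))
  }
  mean_w <- predict_biculture(
    wm = params$wm, beta = params$beta, alpha = params$alpha, b = params$b,
    n_self = n_self, n_other = n_other
  )
  mean_w * exp(rnorm(n_self, mean = 0, sd = params$sigma_log))
}

#' Generate a synthetic addition-series experiment
#'
#' Composes [addition_series_design()], [simulate_survival()] and
#' [simulate_biomass()] into a complete per-plant table that passes all
#' validation, for parameter-recovery and coverage studies. The table's
#' metadata records the true parameters, the design and the seed.
#'
#' @inheritParams addition_series_design
#' @param params list with `species_params` for `BRTE` and `VEDU`; defaults
#'   to [default_species_params()].
#' @param seed integer seed; the caller's RNG state is restored afterwards.
#' @return an [as_experiment_table()] object, one row per harvested plant.
#' @examples
#' tab <- simulate_addition_series(seed = 42)
#' table(tab$species)
#' @export
simulate_addition_series <- function(mono_densities = c(1, 2, 4, 8, 16),
                                     bi_densities = c(2, 4, 8),
                                     replicates = 4,
                                     params = default_species_params(),
                                     seed = NULL) {
  params <- check_params_pair(params)
  design <- addition_series_design(mono_densities, bi_densities, replicates)
  with_seed(seed, {
    pots <- simulate_survival(design, params)
    # Pots where every plant died are dropped: nothing was harvested there.
    rows <- lapply(seq_len(nrow(pots)), function(i) {
      pot <- pots[i, ]
      per_species <- lapply(SPECIES_CODES, function(sp) {
        n_self <- if (sp == "BRTE") pot$realized_n_brte else pot$realized_n_vedu
        n_other <- if (sp == "BRTE") pot$realized_n_vedu else pot$realized_n_brte
        w <- simulate_biomass(n_self, n_other, params[[sp]])
        if (length(w) == 0L) {
          return(NULL)
        }
        data.frame(
          pot_id = pot$pot_id, replicate = pot$replicate, species = sp,
          planted_n_brte = pot$planted_n_brte,
          planted_n_vedu = pot$planted_n_vedu,
          realized_n_brte = pot$realized_n_brte,
          realized_n_vedu = pot$realized_n_vedu,
          biomass_g = w
        )
      })
      do.call(rbind, per_species)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    as_experiment_table(out, metadata = list(
      generator = "simulate_addition_series",
      seed = seed,
      design = list(
        mono_densities = mono_densities, bi_densities = bi_densities,
        replicates = replicates
      ),
      true_params = lapply(params, unclass)
    ))
  })
}
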