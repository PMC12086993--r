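#' Run the full addition-series analysis pipeline
#'
#' Orchestrates the whole analysis as one reproducible run:
#' load (or simulate) the per-plant table, validate it, filter extreme
#' outliers per species x experiment group, split monoculture from biculture
#' pots, fit each species' monoculture yield-density model, fit each
#' species' biculture competition model with the exponent fixed from its
#' monoculture stage, and derive decline-density thresholds (with bootstrap
#' intervals) and relative competitive abilities. Any failure is re-raised
#' with the stage it occurred in. All randomness flows from one master seed,
#' split deterministically per stage, so the same config always yields an
#' identical bundle.
#'
#' @param config a named list, or path to a YAML file holding one. Fields:
#'   \describe{
#'     \item{input}{path to a per-plant CSV (exclusive with `simulation`).}
#'     \item{dialect}{optional column-name mapping for `input`.}
#'     \item{simulation}{list with optional `design` (`mono_densities`,
#'       `bi_densities`, `replicates`) and `params` (per-species lists
#'       accepted by [species_params()]); exclusive with `input`.}
#'     \item{filter}{list; `k` fence multiplier (default 1.5) and `enabled`
#'       (default `TRUE`; disable for synthetic data, which contain no
#'       recording errors — on deterministic or low-noise data the pooled
#'       fences can remove entire density classes).}
#'     \item{fit}{list: [yd_control()] fields plus `on_degenerate` (default
#'       `"fix_b"`, so pipeline runs complete on ridge-degenerate
#'       monoculture data), `b_degenerate` and `wm_mode` (default
#'       `"estimate"`).}
#'     \item{thresholds}{list; `declines` (default `c(0.5, 0.75)`), `n_boot`
#'       (default 10000), `level` (default 0.95).}
#'     \item{seed}{master integer seed (required when simulating).}
#'   }
#' @return object of class `"addseries_bundle"`: list with `table`
#'   (filtered data), `filter_report`, `monoculture_fits`, `biculture_fits`
#'   (per-species lists), `thresholds` (data frame), `rca` (per-species
#'   list), `provenance`.
#' @examples
#' cfg <- list(
#'   simulation = list(params = default_species_params()),
#'   thresholds = list(n_boot = 1000),
#'   seed = 11
#' )
#' bundle <- run_pipeline(cfg)
#' bundle$thresholds
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop("config must be a list or a path to a YAML file", call. = FALSE)
  }
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulation)
  if (has_input == has_sim) {
    stop("config must contain exactly one of 'input' or 'simulation'",
      call. = FALSE
    )
  }
  seed <- config$seed
  if (has_sim && is.null(seed)) {
    stop("config$seed is required when simulating", call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "': ", conditionMessage(e),
        call. = FALSE
      )
    })
  }
  # Deterministic per-stage seed split from the master seed.
  stage_seed <- function(offset) {
    if (is.null(seed)) NULL else (as.integer(seed) + offset) %% 2147483647L
  }

  table <- stage("load", {
    if (has_input) {
      read_plant_table(config$input, dialect = config$dialect)
    } else {
      sim <- config$simulation
      design <- sim$design
      if (is.null(design)) design <- list()
      params <- if (is.null(sim$params)) {
        default_species_params()
      } else {
        check_params_pair(sim$params)
      }
      simulate_addition_series(
        mono_densities = design$mono_densities %||% c(1, 2, 4, 8, 16),
        bi_densities = design$bi_densities %||% c(2, 4, 8),
        replicates = design$replicates %||% 4,
        params = params,
        seed = stage_seed(0L)
      )
    }
  })
  stage("validate", validate_plant_table(table))

  filter_enabled <- config$filter$enabled %||% TRUE
  # k = Inf turns the fences off while keeping the per-group accounting.
  k <- if (filter_enabled) (config$filter$k) %||% 1.5 else Inf
  filtered <- stage("filter", filter_outliers(table, k = k))

  parts <- stage("split", split_monoculture_biculture(filtered$table))

  fit_cfg <- config$fit %||% list()
  # Pipeline runs must complete on weakly curved data: default to the
  # reciprocal-yield fallback when the monoculture exponent is
  # unidentifiable (flagged per fit in the bundle).
  on_degenerate <- fit_cfg$on_degenerate %||% "fix_b"
  b_degenerate <- fit_cfg$b_degenerate %||% 1
  wm_mode <- fit_cfg$wm_mode %||% "estimate"
  control <- do.call(
    yd_control,
    fit_cfg[intersect(names(fit_cfg), names(formals(yd_control)))]
  )
  mono_frame <- stage("prepare", prepare_log_response(parts$monoculture))
  bi_frame <- stage("prepare", prepare_log_response(parts$biculture))

  mono_fits <- stage("fit_monoculture", {
    fits <- lapply(SPECIES_CODES, function(sp) {
      fit_monoculture(mono_frame,
        species = sp, control = control,
        on_degenerate = on_degenerate, b_degenerate = b_degenerate,
        wm_mode = wm_mode
      )
    })
    setNames(fits, SPECIES_CODES)
  })
  bi_fits <- stage("fit_biculture", {
    fits <- lapply(SPECIES_CODES, function(sp) {
      fit_biculture(bi_frame,
        species = sp,
        b = coef(mono_fits[[sp]])[["b"]], control = control,
        wm_mode = wm_mode
      )
    })
    setNames(fits, SPECIES_CODES)
  })

  thr_cfg <- config$thresholds %||% list()
  declines <- thr_cfg$declines %||% c(0.5, 0.75)
  n_boot <- thr_cfg$n_boot %||% 10000L
  level <- thr_cfg$level %||% 0.95
  thresholds <- stage("thresholds", {
    rows <- list()
    i <- 0L
    for (sp in SPECIES_CODES) {
      for (mode in c("intraspecific", "interspecific")) {
        est <- lapply(declines, function(f) {
          i <<- i + 1L
          threshold_ci(bi_fits[[sp]],
            mode = mode, f = f, n_boot = n_boot,
            seed = stage_seed(i), level = level
          )
        })
        row <- data.frame(species = sp, experiment = mode)
        for (j in seq_along(declines)) {
          pct <- round(100 * declines[j])
          row[[sprintf("decline_%d", pct)]] <- est[[j]]$n_star
          row[[sprintf("ci%d_low", pct)]] <- est[[j]]$ci_low
          row[[sprintf("ci%d_high", pct)]] <- est[[j]]$ci_high
        }
        rows[[paste(sp, mode)]] <- row
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })

  rca_results <- stage("rca", {
    setNames(lapply(SPECIES_CODES, function(sp) {
      est <- coef(bi_fits[[sp]])
      rca(est[["beta"]], est[["alpha"]], species = sp)
    }), SPECIES_CODES)
  })

  structure(
    list(
      table = filtered$table,
      filter_report = filtered$report,
      monoculture_fits = mono_fits,
      biculture_fits = bi_fits,
      thresholds = thresholds,
      rca = rca_results,
      provenance = list(
        config = config, seed = seed,
        package_version = as.character(utils::packageVersion("addseries"))
      )
    ),
    class = "addseries_bundle"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.addseries_bundle <- function(x, ...) {
  cat("Addition-series analysis bundle\n")
  cat(sprintf("  records after filtering: %d\n", nrow(x$table)))
  for (sp in names(x$biculture_fits)) {
    fit <- x$biculture_fits[[sp]]
    cat(sprintf(
      "  %s: beta = %.4f, alpha = %.4f, RCA = %.3f\n",
      sp, coef(fit)[["beta"]], coef(fit)[["alpha"]], x$rca[[sp]]$rca
    ))
  }
  invisible(x)
}

#' Write the report tables of an analysis bundle
#'
#' Serializes a bundle into the conventional report layout: per-group
#' outlier accounting, monoculture model estimates, biculture coefficient
#' table, decline-density thresholds with confidence intervals, and a
#' plain-text summary including the relative competitive abilities — four
#' CSVs plus one text file.
#'
#' @param bundle an `"addseries_bundle"` from [run_pipeline()].
#' @param outdir output directory (created if missing).
#' @return character vector of the five file paths written.
#' @export
report_tables <- function(bundle, outdir) {
  required <- c(
    "filter_report", "monoculture_fits", "biculture_fits",
    "thresholds", "rca"
  )
  missing_parts <- required[vapply(
    required,
    function(nm) is.null(bundle[[nm]]), logical(1L)
  )]
  if (length(missing_parts) > 0L) {
    stop("incomplete bundle; missing section(s): ",
      paste(missing_parts, collapse = ", "),
      call. = FALSE
    )
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0L)
  wr <- function(df, name) {
    p <- file.path(outdir, name)
    write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(bundle$filter_report, "outlier_counts.csv")
  mono <- do.call(rbind, lapply(bundle$monoculture_fits, function(fit) {
    est <- coef(fit)
    data.frame(
      species = fit$species, wm = est[["wm"]], a = est[["a"]],
      b = est[["b"]], pseudo_r2 = fit$pseudo_r2, n = fit$n
    )
  }))
  rownames(mono) <- NULL
  wr(mono, "monoculture_models.csv")
  wr(coefficient_table(bundle$biculture_fits), "biculture_coefficients.csv")
  wr(bundle$thresholds, "decline_thresholds.csv")

  summary_path <- file.path(outdir, "summary.txt")
  lines <- c("Addition-series competition analysis", "")
  for (sp in names(bundle$biculture_fits)) {
    fit <- bundle$biculture_fits[[sp]]
    r <- bundle$rca[[sp]]
    lines <- c(lines, sprintf(
      paste0(
        "%s: wm = %.5f g, b = %.5f (fixed), beta = %.4f, alpha = %.4f, ",
        "pseudo-r2 = %.3f, n = %d; RCA = %.3f ",
        "(density equivalence %.2f allospecific per conspecific)"
      ),
      sp, coef(fit)[["wm"]], fit$b, coef(fit)[["beta"]],
      coef(fit)[["alpha"]], fit$pseudo_r2, fit$n, r$rca,
      r$density_equivalence
    ))
  }
  writeLines(lines, summary_path)
  c(paths, summary_path)
}

#' Serialize a bundle to a single JSON file
#'
#' Writes every numeric result of the bundle (filter report, model
#' estimates with standard errors and covariances, thresholds, RCA,
#' provenance) to one structured text file.
#'
#' @inheritParams report_tables
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_bundle <- function(bundle, path) {
  fit_json <- function(fit) {
    list(
      kind = fit$kind, species = fit$species,
      estimates = as.list(fit$coefficients),
      b = fit$b, b_fixed = fit$b_fixed,
      std_errors = as.list(fit$se), t = as.list(fit$t), p = as.list(fit$p),
      vcov_internal = fit$vcov_internal,
      pseudo_r2 = fit$pseudo_r2, n = fit$n
    )
  }
  strip_classes <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip_classes)
      attributes(x) <- list(names = names(x))
    }
    x
  }
  out <- list(
    filter_report = bundle$filter_report,
    monoculture_fits = lapply(bundle$monoculture_fits, fit_json),
    biculture_fits = lapply(bundle$biculture_fits, fit_json),
    thresholds = bundle$thresholds,
    rca = lapply(bundle$rca, unclass),
    provenance = strip_classes(bundle$provenance)
  )
  jsonlite::write_json(out, path,
    auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor", null = "null"
  )
  invisible(path)
}
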