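#' Tukey fences for outlier screening
#'
#' Computes the interval `[Q1 - k * IQR, Q3 + k * IQR]`; values outside it are
#' treated as extreme outliers (likely recording or collection mistakes)
#' before model fitting. Quartiles use linear interpolation between order
#' statistics at positions `p * (n - 1)` (the common default in scientific
#' software, [stats::quantile()] type 7).
#'
#' @param values numeric vector, at least 4 values.
#' @param k fence multiplier, > 0; the conventional 1.5 by default.
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' tukey_fences(c(1, 2, 3, 4, 100)) # c(-1, 7): 100 is an outlier
#' @export
tukey_fences <- function(values, k = 1.5) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) {
    stop("insufficient data: tukey_fences needs at least 4 values",
      call. = FALSE
    )
  }
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("k must be a single positive number", call. = FALSE)
  }
  if (!is.finite(k)) {
    return(c(lower = -Inf, upper = Inf))
  }
  q <- quantile(values, probs = c(0.25, 0.75), names = FALSE, type = 7L)
  iqr <- q[2L] - q[1L]
  c(lower = q[1L] - k * iqr, upper = q[2L] + k * iqr)
}

#' Filter extreme biomass outliers
#'
#' Removes records whose raw biomass falls outside the Tukey fences of their
#' group, where groups are species crossed with experiment type (monoculture
#' vs biculture, by planted composition) — the grouping under which outlier
#' accounting is conventionally reported for these designs. Fences are
#' computed on the raw gram scale, pooled across densities within each group;
#' filtering only drops rows, never alters values, and the pipeline applies
#' it exactly once. A group with fewer than 4 records is passed through
#' unfiltered with a warning.
#'
#' @param table an `experiment_table`.
#' @param k fence multiplier passed to [tukey_fences()].
#' @return list with `table` (the retained records, an `experiment_table`)
#'   and `report`, a data frame with one row per group: `species`,
#'   `experiment`, `n_total`, `n_removed`, `n_final`, `lower`, `upper` and
#'   the quantile convention used.
#' @export
filter_outliers <- function(table, k = 1.5) {
  validate_plant_table(table)
  meta <- experiment_metadata(table)
  if (is.null(meta)) meta <- list()
  df <- as.data.frame(table)
  experiment <- ifelse(
    xor(df$planted_n_brte > 0L, df$planted_n_vedu > 0L),
    "monoculture", "biculture"
  )
  keep <- rep(TRUE, nrow(df))
  report <- list()
  for (sp in SPECIES_CODES) {
    for (exp_type in c("monoculture", "biculture")) {
      idx <- which(df$species == sp & experiment == exp_type)
      if (length(idx) == 0L) next
      if (length(idx) < 4L) {
        warning(
          "group ", sp, "/", exp_type, " has fewer than 4 records; ",
          "passed through unfiltered",
          call. = FALSE
        )
        fences <- c(lower = NA_real_, upper = NA_real_)
        removed <- integer(0L)
      } else {
        fences <- tukey_fences(df$biomass_g[idx], k = k)
        removed <- idx[df$biomass_g[idx] < fences[["lower"]] |
          df$biomass_g[idx] > fences[["upper"]]]
        keep[removed] <- FALSE
      }
      report[[paste(sp, exp_type)]] <- data.frame(
        species = sp, experiment = exp_type,
        n_total = length(idx), n_removed = length(removed),
        n_final = length(idx) - length(removed),
        lower = fences[["lower"]], upper = fences[["upper"]],
        quantile_type = 7L, k = k
      )
    }
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  meta$outlier_filter <- list(k = k, quantile_type = 7L)
  attr(out, "metadata") <- meta
  class(out) <- c("experiment_table", "data.frame")
  list(table = out, report = report)
}

#' Build the log-scale modelling frame
#'
#' All models are fit on the natural-log biomass scale, with realized
#' harvest densities as covariates. For each record, `n_self` is the realized
#' density of the record's own species (including the focal plant) and
#' `n_other` that of the other species; monoculture records have
#' `n_other = 0`.
#'
#' @param table an `experiment_table` (all biomass > 0).
#' @return data frame with columns `pot_id`, `replicate`, `species`,
#'   `biomass_g`, `log_w`, `n_self`, `n_other`.
#' @examples
#' tab <- simulate_addition_series(replicates = 1, seed = 7)
#' head(prepare_log_response(tab))
#' @export
prepare_log_response <- function(table) {
  df <- as.data.frame(table)
  if (nrow(df) == 0L) {
    return(data.frame(
      pot_id = character(0L), replicate = integer(0L),
      species = character(0L), biomass_g = numeric(0L), log_w = numeric(0L),
      n_self = integer(0L), n_other = integer(0L)
    ))
  }
  validate_plant_table(df)
  if (any(df$biomass_g <= 0)) {
    stop("biomass must be > 0 to take logs", call. = FALSE)
  }
  is_brte <- df$species == "BRTE"
  data.frame(
    pot_id = df$pot_id,
    replicate = df$replicate,
    species = df$species,
    biomass_g = df$biomass_g,
    log_w = log(df$biomass_g),
    n_self = ifelse(is_brte, df$realized_n_brte, df$realized_n_vedu),
    n_other = ifelse(is_brte, df$realized_n_vedu, df$realized_n_brte)
  )
}
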