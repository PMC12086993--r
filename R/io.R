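#' Per-plant experiment tables
#'
#' An experiment table holds one row per harvested plant: the pot it grew in,
#' the replicate, its species (`"BRTE"` for *Bromus tectorum*, `"VEDU"` for
#' *Ventenata dubia*), the planted and realized (at-harvest) densities of both
#' species in that pot, and its aboveground dry biomass in grams. Densities
#' are plants per pot; the realized density of a record's own species includes
#' the focal plant itself, so it is at least 1.
#'
#' `as_experiment_table()` validates a plain data frame and attaches free-form
#' metadata (study id, simulation truth, seeds, ...); `experiment_metadata()`
#' retrieves it.
#'
#' @param data data frame with columns `pot_id`, `replicate`, `species`,
#'   `planted_n_brte`, `planted_n_vedu`, `realized_n_brte`, `realized_n_vedu`,
#'   `biomass_g`.
#' @param metadata named list of free-form metadata.
#' @param check_design if `TRUE` (default) warn when planted compositions fall
#'   outside the standard addition-series design (monocultures at 1, 2, 4, 8,
#'   16; biculture pairs from 2, 4, 8).
#' @return `as_experiment_table()` returns the validated data frame with class
#'   `"experiment_table"`; `experiment_metadata()` returns the metadata list.
#' @seealso [read_plant_table()], [split_monoculture_biculture()],
#'   [simulate_addition_series()]
#' @export
as_experiment_table <- function(data, metadata = list(), check_design = TRUE) {
  data <- as.data.frame(data)
  validate_plant_table(data, check_design = check_design)
  attr(data, "metadata") <- metadata
  class(data) <- c("experiment_table", "data.frame")
  data
}

#' @rdname as_experiment_table
#' @param table an `experiment_table`.
#' @export
experiment_metadata <- function(table) {
  attr(table, "metadata", exact = TRUE)
}

#' @export
print.experiment_table <- function(x, ...) {
  cat(sprintf(
    "Addition-series experiment table: %d plants in %d pots\n",
    nrow(x), length(unique(x$pot_id))
  ))
  print.data.frame(head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

PLANT_TABLE_COLUMNS <- c(
  "pot_id", "replicate", "species",
  "planted_n_brte", "planted_n_vedu",
  "realized_n_brte", "realized_n_vedu", "biomass_g"
)

DESIGN_MONO_DENSITIES <- c(1L, 2L, 4L, 8L, 16L)
DESIGN_BI_DENSITIES <- c(2L, 4L, 8L)

row_label <- function(rows) paste(rows, collapse = ", ")

#' Validate a per-plant table
#'
#' Checks the structural invariants every downstream step relies on: all
#' required columns present; biomass strictly positive (the models are fit on
#' the natural-log scale); realized densities no greater than planted; the
#' focal plant's own species alive at harvest; all records within a pot
#' agreeing on that pot's densities; and no pot planted with zero plants of
#' both species. Violations are reported with the offending row numbers or
#' pot ids.
#'
#' @inheritParams as_experiment_table
#' @return invisibly `TRUE`; errors describe all offending rows.
#' @export
validate_plant_table <- function(data, check_design = TRUE) {
  data <- as.data.frame(data)
  missing_cols <- setdiff(PLANT_TABLE_COLUMNS, names(data))
  if (length(missing_cols) > 0L) {
    stop(
      "schema error: missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(data) == 0L) {
    return(invisible(TRUE))
  }
  bad_species <- which(!data$species %in% SPECIES_CODES)
  if (length(bad_species) > 0L) {
    stop(
      "validation error: species must be one of ",
      paste(SPECIES_CODES, collapse = "/"),
      "; offending row(s): ", row_label(bad_species),
      call. = FALSE
    )
  }
  num_cols <- c(
    "planted_n_brte", "planted_n_vedu",
    "realized_n_brte", "realized_n_vedu", "biomass_g"
  )
  for (col in num_cols) {
    if (!is.numeric(data[[col]]) || anyNA(data[[col]])) {
      stop(
        "parse error: column '", col, "' must be numeric with no missing ",
        "values; offending row(s): ",
        row_label(which(!is.finite(suppressWarnings(as.numeric(data[[col]]))))),
        call. = FALSE
      )
    }
  }
  bad_biomass <- which(data$biomass_g <= 0)
  if (length(bad_biomass) > 0L) {
    stop(
      "validation error: biomass_g must be > 0 (log-transform must be ",
      "defined); offending row(s): ", row_label(bad_biomass),
      call. = FALSE
    )
  }
  counts <- data[, c(
    "planted_n_brte", "planted_n_vedu",
    "realized_n_brte", "realized_n_vedu"
  )]
  bad_counts <- which(apply(counts < 0 | counts != round(counts), 1L, any))
  if (length(bad_counts) > 0L) {
    stop(
      "validation error: densities must be non-negative integers; ",
      "offending row(s): ", row_label(bad_counts),
      call. = FALSE
    )
  }
  over <- which(data$realized_n_brte > data$planted_n_brte |
    data$realized_n_vedu > data$planted_n_vedu)
  if (length(over) > 0L) {
    stop(
      "validation error: realized density exceeds planted density; ",
      "offending row(s): ", row_label(over),
      call. = FALSE
    )
  }
  empty_pot <- which(data$planted_n_brte + data$planted_n_vedu == 0L)
  if (length(empty_pot) > 0L) {
    stop(
      "validation error: pot planted with zero plants of both species; ",
      "offending row(s): ", row_label(empty_pot),
      call. = FALSE
    )
  }
  focal_realized <- ifelse(data$species == "BRTE",
    data$realized_n_brte, data$realized_n_vedu
  )
  dead_focal <- which(focal_realized < 1L)
  if (length(dead_focal) > 0L) {
    stop(
      "validation error: a record's own species must have realized density ",
      ">= 1 (the harvested plant exists); offending row(s): ",
      row_label(dead_focal),
      call. = FALSE
    )
  }
  dens_cols <- c(
    "planted_n_brte", "planted_n_vedu",
    "realized_n_brte", "realized_n_vedu"
  )
  for (pot in unique(data$pot_id)) {
    rows <- data[data$pot_id == pot, dens_cols, drop = FALSE]
    if (nrow(unique(rows)) > 1L) {
      stop(
        "validation error: records within pot '", pot,
        "' disagree on planted/realized densities",
        call. = FALSE
      )
    }
  }
  if (check_design) {
    pots <- unique(data[, c("pot_id", "planted_n_brte", "planted_n_vedu")])
    mono <- xor(pots$planted_n_brte > 0L, pots$planted_n_vedu > 0L)
    mono_n <- pmax(pots$planted_n_brte, pots$planted_n_vedu)
    off_design <- (mono & !(mono_n %in% DESIGN_MONO_DENSITIES)) |
      (!mono & !(pots$planted_n_brte %in% DESIGN_BI_DENSITIES &
        pots$planted_n_vedu %in% DESIGN_BI_DENSITIES))
    if (any(off_design)) {
      warning(
        "planted densities outside the standard addition-series design in ",
        "pot(s): ", paste(pots$pot_id[off_design], collapse = ", "),
        call. = FALSE
      )
    }
  }
  invisible(TRUE)
}

#' Read and write per-plant biomass tables
#'
#' CSV round-trip for experiment tables. The canonical header is
#' `pot_id,replicate,species,planted_n_brte,planted_n_vedu,realized_n_brte,
#' realized_n_vedu,biomass_g`; a `dialect` mapping lets files with other
#' column names be read without editing them. On write, biomass is quantized
#' to the balance accuracy of 0.001 g (3 decimal places, floored at 0.001 so
#' a positive plant never rounds to an unloggable zero); in-memory values keep
#' full precision.
#'
#' @param path file path.
#' @param dialect named character vector mapping canonical column names to the
#'   names used in the file, e.g. `c(biomass_g = "dry_wt")`. Unmapped columns
#'   are expected under their canonical names.
#' @inheritParams as_experiment_table
#' @return `read_plant_table()` returns an [as_experiment_table()] object;
#'   `write_plant_table()` invisibly returns `path`.
#' @examples
#' tab <- simulate_addition_series(replicates = 1, seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_plant_table(tab, f)
#' nrow(read_plant_table(f)) == nrow(tab)
#' @export
read_plant_table <- function(path, dialect = NULL, check_design = TRUE) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(dialect)) {
    if (is.null(names(dialect)) || any(names(dialect) == "")) {
      stop("dialect must be a named character vector (canonical = source)",
        call. = FALSE
      )
    }
    for (canonical in names(dialect)) {
      src <- dialect[[canonical]]
      if (!src %in% names(raw)) {
        stop("schema error: dialect column '", src, "' (for '", canonical,
          "') not found in ", path,
          call. = FALSE
        )
      }
      names(raw)[names(raw) == src] <- canonical
    }
  }
  missing_cols <- setdiff(PLANT_TABLE_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop(
      "schema error: missing required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  raw <- raw[, PLANT_TABLE_COLUMNS]
  num_cols <- c(
    "replicate", "planted_n_brte", "planted_n_vedu",
    "realized_n_brte", "realized_n_vedu", "biomass_g"
  )
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) | (!is.na(raw[[col]]) & raw[[col]] == ""))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))
      stop(
        "parse error: non-numeric '", col, "' at data row(s) ",
        row_label(bad), " (file line(s) ", row_label(bad + 1L), ")",
        call. = FALSE
      )
    }
    raw[[col]] <- vals
  }
  raw$pot_id <- as.character(raw$pot_id)
  raw$species <- as.character(raw$species)
  as_experiment_table(raw,
    metadata = list(source = path),
    check_design = check_design
  )
}

#' @rdname read_plant_table
#' @param table an `experiment_table` (or validatable data frame).
#' @export
write_plant_table <- function(table, path) {
  validate_plant_table(table)
  out <- as.data.frame(table)[, PLANT_TABLE_COLUMNS, drop = FALSE]
  out$biomass_g <- sprintf("%.3f", pmax(round(out$biomass_g, 3L), 0.001))
  status <- tryCatch(
    write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) {
      stop("I/O error writing '", path, "': ", conditionMessage(e),
        call. = FALSE
      )
    }
  )
  invisible(path)
}

#' Split an experiment table into monoculture and biculture pots
#'
#' Classification is by *planted* composition: a pot sown with exactly one
#' species is a monoculture, a pot sown with both is a biculture — even if one
#' species later died out entirely, since the models use realized densities as
#' covariates and tolerate a zero there. The two partitions are disjoint and
#' cover the input exactly.
#'
#' @param table an `experiment_table`.
#' @return list with elements `monoculture` and `biculture`, both
#'   `experiment_table`s inheriting the input's metadata.
#' @export
split_monoculture_biculture <- function(table) {
  validate_plant_table(table)
  meta <- experiment_metadata(table)
  if (is.null(meta)) meta <- list()
  df <- as.data.frame(table)
  is_mono <- xor(df$planted_n_brte > 0L, df$planted_n_vedu > 0L)
  mk <- function(rows) {
    out <- df[rows, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "metadata") <- meta
    class(out) <- c("experiment_table", "data.frame")
    out
  }
  list(monoculture = mk(is_mono), biculture = mk(!is_mono))
}
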