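test_that("write then read is the identity on validated tables", {
  tab <- as_experiment_table(random_records(50, seed = 101))
  path <- withr::local_tempfile(fileext = ".csv")
  write_plant_table(tab, path)
  back <- read_plant_table(path)
  expect_equal(nrow(back), 50L)
  for (col in c(
    "pot_id", "replicate", "species", "planted_n_brte", "planted_n_vedu",
    "realized_n_brte", "realized_n_vedu"
  )) {
    expect_equal(back[[col]], tab[[col]], ignore_attr = TRUE)
  }
  # biomass is compared at the 0.001 g export resolution
  expect_equal(back$biomass_g, round(tab$biomass_g, 3), tolerance = 1e-12)
})

test_that("writing quantizes biomass to 0.001 g with a positive floor", {
  tab <- toy_table()
  tab$biomass_g[1] <- 0.0004   # would round to zero without the floor
  tab$biomass_g[2] <- 0.12345
  path <- withr::local_tempfile(fileext = ".csv")
  write_plant_table(tab, path)
  back <- read_plant_table(path)
  expect_equal(back$biomass_g[1], 0.001)
  expect_equal(back$biomass_g[2], 0.123)
})

test_that("an empty table writes a header-only file", {
  tab <- as_experiment_table(random_records(1, seed = 1)[0, ])
  path <- withr::local_tempfile(fileext = ".csv")
  write_plant_table(tab, path)
  lines <- readLines(path)
  expect_length(lines, 1L)
  expect_match(lines, "^pot_id,replicate,species,planted_n_brte")
  one <- as_experiment_table(random_records(1, seed = 2))
  write_plant_table(one, path)
  expect_length(readLines(path), 2L)
})

test_that("read errors are specific: schema, parse and validation", {
  path <- withr::local_tempfile(fileext = ".csv")
  header <- paste(
    "pot_id,replicate,species,planted_n_brte,planted_n_vedu,",
    "realized_n_brte,realized_n_vedu,biomass_g",
    sep = ""
  )
  writeLines(c("pot_id,replicate,species", "a,1,BRTE"), path)
  expect_error(read_plant_table(path), "schema error")

  writeLines(c(header, "a,1,BRTE,2,0,2,0,abc"), path)
  expect_error(read_plant_table(path), "non-numeric 'biomass_g'.*row\\(s\\) 1")

  writeLines(
    c(header, "a,1,BRTE,2,0,2,0,0.100", "b,1,BRTE,2,0,2,0,0.000"),
    path
  )
  expect_error(read_plant_table(path), "biomass_g must be > 0.*2")
})

test_that("dialect mapping reads files with foreign column names", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(
    c(
      "pot,rep,sp,pB,pV,rB,rV,dry_wt",
      "a,1,BRTE,2,0,2,0,0.120"
    ),
    path
  )
  dialect <- c(
    pot_id = "pot", replicate = "rep", species = "sp",
    planted_n_brte = "pB", planted_n_vedu = "pV",
    realized_n_brte = "rB", realized_n_vedu = "rV", biomass_g = "dry_wt"
  )
  tab <- read_plant_table(path, dialect = dialect)
  expect_equal(tab$biomass_g, 0.12)
  expect_error(
    read_plant_table(path, dialect = c(biomass_g = "nope")),
    "dialect column 'nope'"
  )
})

test_that("structural invariants are enforced with row or pot labels", {
  base <- as.data.frame(toy_table())
  over <- base
  over$realized_n_brte[1] <- 5L
  expect_error(validate_plant_table(over), "realized.*exceeds planted")

  dead <- base
  dead$realized_n_brte[1:2] <- 0L
  expect_error(validate_plant_table(dead), "realized density\\s*>= 1")

  inconsistent <- base
  inconsistent$realized_n_vedu[3] <- 1L
  expect_error(validate_plant_table(inconsistent), "pot 'b1'")

  empty_pot <- base
  empty_pot$planted_n_brte[1:2] <- 0L
  empty_pot$realized_n_brte[1:2] <- 0L
  expect_error(validate_plant_table(empty_pot), "zero plants of both")

  off_design <- base
  off_design$planted_n_brte[1:2] <- 3L
  off_design$realized_n_brte[1:2] <- 3L
  expect_warning(validate_plant_table(off_design), "outside the standard")
})

test_that("split by planted composition is disjoint and exhaustive", {
  parts <- split_monoculture_biculture(toy_table())
  expect_equal(unique(parts$monoculture$pot_id), "m1")
  expect_equal(unique(parts$biculture$pot_id), "b1")
  expect_equal(nrow(parts$monoculture) + nrow(parts$biculture), 6L)

  # all-monoculture input: biculture partition is empty
  mono_only <- as_experiment_table(random_records(12, seed = 5))
  parts2 <- split_monoculture_biculture(mono_only)
  expect_equal(nrow(parts2$biculture), 0L)
  expect_equal(nrow(parts2$monoculture), 12L)

  # random design: pot counts sum to the total
  tab <- simulate_addition_series(replicates = 2, seed = 30)
  parts3 <- split_monoculture_biculture(tab)
  n_pots <- length(unique(tab$pot_id))
  expect_equal(
    length(unique(parts3$monoculture$pot_id)) +
      length(unique(parts3$biculture$pot_id)),
    n_pots
  )
  expect_length(
    intersect(parts3$monoculture$pot_id, parts3$biculture$pot_id), 0L
  )
})

test_that("a biculture pot with one species extinct stays biculture", {
  df <- data.frame(
    pot_id = "b9", replicate = 1L, species = "BRTE",
    planted_n_brte = 4L, planted_n_vedu = 4L,
    realized_n_brte = 3L, realized_n_vedu = 0L,
    biomass_g = c(0.1, 0.11, 0.09)
  )
  tab <- as_experiment_table(df)
  parts <- split_monoculture_biculture(tab)
  expect_equal(nrow(parts$biculture), 3L)
  expect_equal(nrow(parts$monoculture), 0L)
})
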