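test_that("well addresses parse to letter row and 1-based column", {
  rc <- parse_well_address(c("A1", "p24", "H12"))
  expect_equal(rc$row, c("A", "P", "H"))
  expect_equal(rc$col, c(1L, 24L, 12L))
})

test_that("malformed well addresses raise located errors", {
  expect_error(parse_well_address(c("A1", "Q1")), "row\\(s\\) 2")
  expect_error(parse_well_address("A25"), "malformed well address")
  expect_error(parse_well_address("11"), "malformed well address")
})

test_that("quadrants follow row/column parity of the interleaved grid", {
  expect_equal(well_quadrant("A", 1), 1L)
  expect_equal(well_quadrant("B", 1), 2L)
  expect_equal(well_quadrant("A", 2), 3L)
  expect_equal(well_quadrant("B", 2), 4L)
  # every 2x2 block contains all four quadrants
  g <- expand.grid(row = LETTERS[1:16], col = 1:24, stringsAsFactors = FALSE)
  q <- well_quadrant(g$row, g$col)
  expect_equal(sort(unique(q)), 1:4)
  expect_equal(as.vector(table(q)), rep(96L, 4))
})

test_that("a one-row background file reads into a valid dataset", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate_id,well,role,compound_id,concentration_M,luminescence_cps",
               "P1,A1,background,,,105.2"), f)
  ds <- read_plate_csv(f)
  expect_s3_class(ds, "screen_dataset")
  expect_equal(nrow(ds$wells), 1L)
  expect_equal(ds$wells$role, "background")
  expect_equal(ds$wells$luminescence_cps, 105.2)
})

test_that("validation rejects malformed datasets with clear messages", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plate_id,well,role,compound_id,concentration_M,luminescence_cps",
               "P1,Q1,background,,,105.2"), f)
  expect_error(read_plate_csv(f), "malformed well address")

  base <- tibble::tibble(plate_id = "P1", row = "A", col = 1L, role = "background",
                         compound_id = NA_character_, concentration_M = NA_real_,
                         luminescence_cps = 100)
  expect_error(screen_dataset(rbind(base, base)), "duplicate well")
  bad <- base; bad$luminescence_cps <- -5
  expect_error(screen_dataset(bad), "negative luminescence")
  bad <- base; bad$role <- "test"
  expect_error(screen_dataset(bad), "compound_id")
  bad <- base; bad$compound_id <- "X"
  expect_error(screen_dataset(bad), "background wells")
  bad <- base; bad$role <- "mystery"
  expect_error(screen_dataset(bad), "unknown well role")
})

test_that("write/read round trip is the identity on a synthetic plate", {
  scr <- make_screen(n_compounds = 160, seed = 42)
  f <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(scr$dataset, f)
  back <- read_plate_csv(f, check_design = TRUE)
  cols <- c("plate_id", "row", "col", "role", "compound_id",
            "concentration_M", "luminescence_cps")
  expect_equal(as.data.frame(back$wells[cols]),
               as.data.frame(scr$dataset$wells[cols]))
})

test_that("result tables round-trip through TSV including flags", {
  hits <- tibble::tibble(compound_id = c("A", "B"),
                         mean_pct_inhibition = c(85.2, 12.000001),
                         pct_of_control_effect = c(91.6, 12.9),
                         threshold_pct_inhibition = 81, is_hit = c(TRUE, FALSE))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_table(hits, f)
  back <- read_table(f)
  expect_equal(as.data.frame(back), as.data.frame(hits))

  empty <- hits[0, ]
  write_table(empty, f)
  expect_equal(names(read_table(f)), names(hits))

  write_table(tibble::tibble(potency_M = 2.37123e-7), f,
              report_signif = c(potency_M = "potency_report_M"))
  expect_equal(read_table(f)$potency_report_M, 2.4e-7)
})

test_that("run configuration reads from YAML and rejects unknown keys", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("k_sd: 3", "censor_limit: 1.0e-5", "rng_seed: 7"), f)
  cfg <- read_run_config(f)
  expect_equal(cfg$k_sd, 3)
  expect_equal(cfg$censor_limit, 1e-5)
  expect_equal(cfg$rng_seed, 7L)

  writeLines(c("k_sd: 3", "k_ds: 6"), f)
  expect_error(read_run_config(f), "k_ds")
  expect_error(run_config(k_sd = -1))
  expect_error(run_config(censor_limit = 0))
})

test_that("compound annotations enforce the closed class vocabulary", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,name,hit_class",
               "C1,clozapine,dopamine_receptor_antagonist",
               "C2,whatever,novel_class"), f)
  expect_error(read_compound_csv(f), "C2")
})
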