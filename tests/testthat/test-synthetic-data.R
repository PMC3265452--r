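test_that("fixing the seed fixes every generated value", {
  a <- make_screen(n_compounds = 160, seed = 3)
  b <- make_screen(n_compounds = 160, seed = 3)
  expect_identical(a$dataset$wells, b$dataset$wells)
  expect_identical(a$truth, b$truth)
  expect_identical(make_bioassay(78, 185, seed = 9), make_bioassay(78, 185, seed = 9))
  c1 <- make_dose_response(1e-7, concentrations = 10^seq(-10, -5, 0.5), seed = 4)
  c2 <- make_dose_response(1e-7, concentrations = 10^seq(-10, -5, 0.5), seed = 4)
  expect_identical(c1$points, c2$points)
  # and the generator restores the caller's RNG stream
  set.seed(123); before <- .Random.seed
  invisible(make_screen(n_compounds = 160, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("noiseless screens collapse to their mean model", {
  noise0 <- assay_noise_model(well_noise_cv = 0, plate_effect_sd = 0,
                              control_inhibition_sd = 0)
  scr <- make_screen(n_compounds = 160,
                     truth = truth_spec(frac_antagonist = 0, frac_off_target = 0),
                     noise = noise0, seed = 1)
  w <- scr$dataset$wells
  # inactive compounds: test wells equal maximal-stimulation wells exactly
  expect_equal(unique(w$luminescence_cps[w$role == "test"]),
               unique(w$luminescence_cps[w$role == "max_stim"]))
  # a planted full blocker: test wells equal background wells
  full <- truth_spec(frac_antagonist = 1, frac_off_target = 0,
                     ic50_range = c(1e-15, 1.0000001e-15))
  scr2 <- make_screen(n_compounds = 160, truth = full, noise = noise0, seed = 1)
  w2 <- scr2$dataset$wells
  expect_equal(w2$luminescence_cps[w2$role == "test"],
               rep(noise0$background_mean, sum(w2$role == "test")),
               tolerance = 1e-6)
})

test_that("screen layout respects the quadruplicate two-plate quadrant design", {
  scr <- make_screen(n_compounds = 320, seed = 2)
  tw <- scr$dataset$wells[scr$dataset$wells$role == "test", ]
  tw$quadrant <- well_quadrant(tw$row, tw$col)
  per <- dplyr::summarise(dplyr::group_by(tw, compound_id),
                          n = dplyr::n(),
                          n_plates = dplyr::n_distinct(plate_id),
                          n_quad_plate = dplyr::n_distinct(paste(plate_id, quadrant)),
                          .groups = "drop")
  expect_true(all(per$n == 4))
  expect_true(all(per$n_plates == 2))
  expect_true(all(per$n_quad_plate == 4))
  expect_error(make_screen(n_compounds = 320, n_plate_pairs = 1),
               "capacity exceeded")
})

test_that("generated wells match their mean model in expectation", {
  noise <- assay_noise_model()
  scr <- make_screen(n_compounds = 1280,
                     truth = truth_spec(frac_antagonist = 0, frac_off_target = 0),
                     noise = assay_noise_model(plate_effect_sd = 0), seed = 7)
  w <- scr$dataset$wells
  tl <- w$luminescence_cps[w$role == "test"]
  mu <- noise$background_mean + noise$max_net_signal
  se <- stats::sd(tl) / sqrt(length(tl))
  expect_lt(abs(mean(tl) - mu), 3 * se)
  bg <- w$luminescence_cps[w$role == "background"]
  expect_lt(abs(mean(bg) - noise$background_mean),
            3 * stats::sd(bg) / sqrt(length(bg)))
  expect_true(all(w$luminescence_cps >= 0))
})

test_that("noise-free dose-response points lie exactly on the 4PL", {
  conc <- 10^seq(-10, -5, length.out = 8)
  crv <- make_dose_response(1e-7, hill = 1, top = 100, bottom = 0,
                            concentrations = conc, n_experiments = 2,
                            noise_cv = 0, seed = 1)
  expected <- 100 / (1 + 1e-7 / conc)
  for (e in unique(crv$points$experiment_id)) {
    expect_equal(crv$points$response[crv$points$experiment_id == e], expected,
                 tolerance = 1e-12)
  }
  expect_error(make_dose_response(1e-7, concentrations = c(0, 1e-7)),
               "strictly positive")
})

test_that("dose-response generation is scale-equivariant", {
  conc <- 10^seq(-10, -5, length.out = 8)
  a <- make_dose_response(1e-7, concentrations = conc, noise_cv = 0.1, seed = 5)
  b <- make_dose_response(1e-6, concentrations = conc * 10, noise_cv = 0.1, seed = 5)
  expect_equal(a$points$response, b$points$response, tolerance = 1e-12)
})

test_that("bioassay mortality matches the log-logistic at the LC anchors", {
  # at dose = LC50 expected mortality is 50%, at LC90 it is 90%
  rec50 <- make_bioassay(78, 185, doses_uM = c(78, 185, 400), n_per_well = 10,
                         wells_per_dose = 400, n_assays = 1, seed = 11,
                         include_controls = FALSE)
  p <- tapply(rec50$n_dead / rec50$n_larvae, rec50$dose_uM, mean)
  n_tot <- 400 * 10
  expect_lt(abs(p[["78"]] - 0.5), 3 * sqrt(0.5 * 0.5 / n_tot))
  expect_lt(abs(p[["185"]] - 0.9), 3 * sqrt(0.9 * 0.1 / n_tot))
  expect_true(all(rec50$n_dead <= rec50$n_larvae & rec50$n_dead >= 0))
  expect_error(make_bioassay(185, 78), "truth_lc90 > truth_lc50")
})
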