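test_that("noise-free 4PL data recover all four parameters to optimizer tolerance", {
  conc <- 10^seq(-10, -5, length.out = 10)
  crv <- make_dose_response(1e-7, hill = 1.3, top = 120, bottom = 10,
                            concentrations = conc, n_experiments = 1,
                            noise_cv = 0, seed = 1)
  f <- fit_4pl(crv)
  expect_true(f$converged)
  expect_lt(abs(f$log10_potency - (-7)), 1e-6)
  expect_lt(abs(f$hill - 1.3), 1e-5)
  expect_lt(abs(f$top - 120), 1e-4)
  expect_lt(abs(f$bottom - 10), 1e-4)
})

test_that("fits match an independent dense grid-search oracle on noisy data", {
  conc <- 10^seq(-10, -5, length.out = 10)
  for (s in c(2, 3)) {
    crv <- make_dose_response(3e-8, hill = 1, top = 100, bottom = 0,
                              concentrations = conc, n_experiments = 1,
                              noise_cv = 0.1, seed = s)
    f <- fit_4pl(crv)
    o <- oracle_fit_4pl_grid(crv$points$concentration_M, crv$points$response)
    expect_lt(abs(f$log10_potency - o$logp), 0.02 + 1e-9)  # grid resolution
    expect_lte(f$rss, o$rss + 1e-9)  # LM should do at least as well as the grid
  }
})

test_that("fitting is scale-equivariant in concentration", {
  conc <- 10^seq(-10, -5, length.out = 8)
  crv <- make_dose_response(1e-7, concentrations = conc, noise_cv = 0.1, seed = 6)
  f1 <- fit_4pl(crv)
  shifted <- crv
  shifted$points$concentration_M <- shifted$points$concentration_M * 10
  f2 <- fit_4pl(shifted)
  expect_equal(f2$log10_potency, f1$log10_potency + 1, tolerance = 1e-6)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-6)
  expect_equal(f2$top, f1$top, tolerance = 1e-4)
})

test_that("an antagonist curve mirrors its agonist counterpart", {
  conc <- 10^seq(-10, -5, length.out = 8)
  up <- make_dose_response(1e-7, concentrations = conc, n_experiments = 1,
                           noise_cv = 0.08, seed = 8, mode = "agonist")
  down <- up
  down$points$response <- 100 - up$points$response  # vertical mirror
  fu <- fit_4pl(up); fd <- fit_4pl(down)
  expect_equal(abs(fd$hill), abs(fu$hill), tolerance = 1e-5)
  expect_equal(fd$log10_potency, fu$log10_potency, tolerance = 1e-6)
  expect_lt(fd$hill, 0)
})

test_that("aggregation uses the geometric mean with log-scale SEM", {
  fits <- tibble::tibble(experiment_id = c("E1", "E2", "E3"),
                         top = 100, bottom = 0,
                         log10_potency = log10(c(100e-9, 200e-9, 400e-9)),
                         potency_M = c(100e-9, 200e-9, 400e-9),
                         hill = 1, rss = 0, sigma = 0,
                         converged = TRUE, at_bound = FALSE)
  est <- summarize_experiments(fits)
  expect_equal(est$potency_M, 200e-9, tolerance = 1e-12)
  expect_false(est$censored)
  same <- fits; same$log10_potency <- log10(2.4e-7); same$potency_M <- 2.4e-7
  est2 <- summarize_experiments(same)
  expect_equal(est2$sem_M, 0)
  expect_equal(est2$potency_M, 2.4e-7)
})

test_that("potencies at or above 10 uM are censored after aggregation", {
  fits <- tibble::tibble(experiment_id = c("E1", "E2"), top = 100, bottom = 0,
                         log10_potency = log10(c(8e-6, 1.6e-5)),
                         potency_M = c(8e-6, 1.6e-5), hill = 1, rss = 0,
                         sigma = 0, converged = TRUE, at_bound = FALSE)
  est <- summarize_experiments(fits, censor_limit = 1e-5)
  expect_true(est$censored)  # geometric mean ~1.13e-5 >= limit
  expect_match(est$display, ">= 1e-05")
  none <- fits; none$converged <- FALSE
  est2 <- summarize_experiments(none)
  expect_true(est2$censored); expect_true(est2$all_failed)
})

test_that("recovery error stays small over many seeded noisy replicates", {
  conc <- 10^seq(-11, -4, length.out = 10)
  errs <- vapply(1:200, function(s) {
    crv <- make_dose_response(2.4e-7, concentrations = conc, n_experiments = 1,
                              noise_cv = 0.1, seed = s)
    abs(fit_4pl(crv)$log10_potency - log10(2.4e-7))
  }, numeric(1))
  expect_lt(median(errs), 0.1)
})

test_that("degenerate curves are rejected or flagged, not mis-fit", {
  pts <- tibble::tibble(concentration_M = 10^seq(-9, -6, length.out = 3),
                        response = c(1, 2, 3), experiment_id = "E1")
  expect_error(fit_4pl(as_dose_response(pts)), "fewer than 4")
  flat <- tibble::tibble(concentration_M = 10^seq(-9, -5, length.out = 8),
                         response = rep(100, 8), experiment_id = "E1")
  f <- fit_4pl(as_dose_response(flat))
  est <- summarize_experiments(f)
  expect_true(est$censored || est$all_failed || is.na(est$potency_M) ||
                abs(f$top - f$bottom) < 1e-6)
})
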