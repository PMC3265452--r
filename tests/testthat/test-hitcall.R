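test_that("normalization arithmetic matches the defining formulas", {
  ds <- tiny_plate(bg = c(100, 100), mx = c(1100, 1100), test = c(600, 1100, 100))
  nw <- normalize_wells(ds)
  tw <- nw[nw$role == "test", ]
  expect_equal(tw$net_cps, c(500, 1000, 0))
  expect_equal(tw$pct_stimulation, c(50, 100, 0))
  expect_equal(tw$pct_inhibition, c(50, 0, 100))
  # max-stimulation wells average 100% stimulation per plate
  expect_equal(mean(nw$pct_stimulation[nw$role == "max_stim"]), 100)
})

test_that("normalization is strictly per-plate and errors name missing roles", {
  p1 <- tiny_plate("P1", bg = c(100, 100), mx = c(1100, 1100), test = 600)
  p2 <- tiny_plate("P2", bg = c(200, 200), mx = c(2200, 2200), test = 1200)
  both <- screen_dataset(rbind(p1$wells, p2$wells))
  nw <- normalize_wells(both)
  tw <- nw[nw$role == "test", ]
  # same fractional signal on both plates -> identical percent inhibition
  expect_equal(tw$pct_inhibition[tw$plate_id == "P1"],
               tw$pct_inhibition[tw$plate_id == "P2"])
  no_max <- screen_dataset(p1$wells[p1$wells$role != "max_stim", ])
  expect_error(normalize_wells(no_max), "max_stim")
  expect_error(normalize_wells(screen_dataset(p1$wells[p1$wells$role != "background", ])),
               "background")
})

test_that("replicate aggregation is an unweighted, order-invariant mean", {
  nw <- tibble::tibble(plate_id = "P1", row = "A", col = 1:4, role = "test",
                       compound_id = "C1", net_cps = NA_real_,
                       pct_stimulation = NA_real_,
                       pct_inhibition = c(80, 82, 84, 78))
  agg <- aggregate_replicates(nw)
  expect_equal(agg$mean_pct_inhibition, 81)
  expect_equal(agg$sd_pct_inhibition, sd(c(80, 82, 84, 78)))
  expect_equal(agg$n_replicates, 4L)
  shuffled <- nw[c(3, 1, 4, 2), ]
  expect_equal(aggregate_replicates(shuffled), agg)
  single <- aggregate_replicates(nw[1, ])
  expect_equal(single$mean_pct_inhibition, 80)
  expect_true(is.na(single$sd_pct_inhibition))
})

test_that("threshold derivation widens the band below the control mean", {
  # control mean 93, SD 4: the campaign's two printed cutoffs
  ctrl <- c(89, 97, 93, 93)  # mean 93
  ctrl <- 93 + (ctrl - 93) * 4 / sd(ctrl)
  thr3 <- derive_threshold(ctrl, k_sd = 3)
  expect_equal(thr3$control_mean, 93)
  expect_equal(thr3$control_sd, 4)
  expect_equal(thr3$threshold_pct_inhibition, 81)
  expect_equal(derive_threshold(ctrl, 6)$threshold_pct_inhibition, 69)
  expect_equal(derive_threshold(ctrl, 0)$threshold_pct_inhibition, 93)
  expect_error(derive_threshold(93, 3), "at least 2")
})

test_that("hit calling uses a closed bound and scores against the control", {
  agg <- tibble::tibble(compound_id = c("at", "above", "below", "ctrl_like"),
                        mean_pct_inhibition = c(81, 90, 80.999, 93),
                        sd_pct_inhibition = 1, n_replicates = 4L)
  calls <- call_hits(agg, list(threshold_pct_inhibition = 81, control_mean = 93,
                               control_sd = 4, k_sd = 3))
  expect_equal(calls$hits$is_hit, c(TRUE, TRUE, FALSE, TRUE))
  # a compound at the control mean scores 100% of the control effect
  expect_equal(calls$hits$pct_of_control_effect[4], 100)
  expect_equal(calls$n_hits, 3L)
})

test_that("hits are partitioned into the seven annotation classes", {
  ref <- reference_screen_hits()
  agg <- tibble::tibble(compound_id = ref$compound,
                        mean_pct_inhibition = 90,
                        sd_pct_inhibition = 1, n_replicates = 4L)
  ann <- tibble::tibble(compound_id = ref$compound, hit_class = ref$hit_class)
  calls <- call_hits(agg, 81, annotations = ann)
  expect_equal(calls$n_hits, 51L)
  counts <- calls$class_counts
  expect_equal(sort(counts$n_hits[order(counts$hit_class)]),
               sort(c(20L, 6L, 2L, 1L, 9L, 6L, 7L)))
  bad <- ann; bad$hit_class[1] <- "not_a_class"
  expect_error(call_hits(agg, 81, annotations = bad), bad$compound_id[1],
               fixed = TRUE)
})

test_that("hit set is monotone non-decreasing in k_sd", {
  for (s in 1:3) {
    scr <- make_screen(n_compounds = 160, seed = s)
    nw <- normalize_wells(scr$dataset)
    ctrl <- nw$pct_inhibition[nw$role == "antagonist_control"]
    agg <- aggregate_replicates(nw)
    h3 <- call_hits(agg, derive_threshold(ctrl, 3))$hits
    h6 <- call_hits(agg, derive_threshold(ctrl, 6))$hits
    expect_true(all(h3$compound_id[h3$is_hit] %in% h6$compound_id[h6$is_hit]))
  }
})

test_that("per-plate normalization cancels multiplicative plate effects", {
  mk <- function(pe_sd) {
    make_screen(n_compounds = 160,
                truth = truth_spec(frac_antagonist = 0.1, frac_off_target = 0),
                noise = assay_noise_model(well_noise_cv = 0, plate_effect_sd = pe_sd,
                                          control_inhibition_sd = 0),
                seed = 10)
  }
  calls_for <- function(scr) {
    nw <- normalize_wells(scr$dataset)
    agg <- aggregate_replicates(nw)
    calls <- call_hits(agg, 81)
    calls$hits[order(calls$hits$compound_id), ]
  }
  a <- calls_for(mk(0)); b <- calls_for(mk(0.2))
  expect_equal(b$mean_pct_inhibition, a$mean_pct_inhibition, tolerance = 1e-8)
  expect_identical(b$is_hit, a$is_hit)
})

test_that("planted-truth scoring reports sensitivity and specificity", {
  scr <- make_screen(n_compounds = 320, seed = 21)
  nw <- normalize_wells(scr$dataset)
  ctrl <- nw$pct_inhibition[nw$role == "antagonist_control"]
  calls <- call_hits(aggregate_replicates(nw), derive_threshold(ctrl, 3))
  sc <- score_against_truth(calls, scr$truth)
  expect_equal(sc$tp + sc$fn, sum(scr$truth$mechanism != "inactive"))
  expect_equal(sc$tn + sc$fp, sum(scr$truth$mechanism == "inactive"))
  expect_gte(sc$specificity, 0.99)
  expect_gte(sc$sensitivity_detectable, 0.95)
})
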