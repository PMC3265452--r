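# Ground-truth simulators for every stage of the campaign: screen plates,
# checkerboard uniformity plates, dose-response experiments, and larval
# bioassays. Fixing the seed fixes every generated value.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state, so
#' generators are reproducible without clobbering the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Lognormal multiplier with mean 1 and coefficient of variation cv.
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Assay noise model for the synthetic screen
#'
#' Luminescence is positive and heteroscedastic, so well noise is
#' multiplicative lognormal on the net (above-background) signal, and a
#' per-plate multiplicative lognormal effect models day/automation drift.
#' The default signal window is 10-fold (background 1000 cps, maximal net
#' stimulation 9000 cps), matching the dopamine response window used to
#' qualify the screen. The default well-noise CV of 0.29 is the value at
#' which three checkerboard plates yield a replicate-adjusted (n = 4)
#' Z-factor of about 0.5; the real instrument's noise magnitude is not
#' published, so the model is calibrated to that printed figure of merit.
#' Antagonist-control wells draw their inhibition directly from a normal
#' distribution with mean `control_inhibition_mean` and SD
#' `control_inhibition_sd` (defaults 0.93 and 0.04, the pair that places
#' the mean-minus-3-SD hit threshold at 81 percent inhibition and the
#' mean-minus-6-SD threshold at 69 percent).
#'
#' @param background_mean Mean background luminescence (cps).
#' @param max_net_signal Mean net signal of fully stimulated wells (cps).
#' @param well_noise_cv Coefficient of variation of per-well lognormal noise.
#' @param plate_effect_sd SD of the multiplicative lognormal plate effect.
#' @param control_inhibition_mean Mean fractional inhibition of
#'   antagonist-control wells.
#' @param control_inhibition_sd SD of antagonist-control fractional inhibition.
#' @return A list of class `assay_noise_model`.
#' @export
assay_noise_model <- function(background_mean = 1000, max_net_signal = 9000,
                              well_noise_cv = 0.29, plate_effect_sd = 0.08,
                              control_inhibition_mean = 0.93,
                              control_inhibition_sd = 0.04) {
  stopifnot(background_mean > 0, max_net_signal > 0,
            well_noise_cv >= 0, well_noise_cv < 1, plate_effect_sd >= 0,
            control_inhibition_mean > 0, control_inhibition_mean <= 1,
            control_inhibition_sd >= 0)
  structure(list(background_mean = background_mean,
                 max_net_signal = max_net_signal,
                 well_noise_cv = well_noise_cv,
                 plate_effect_sd = plate_effect_sd,
                 control_inhibition_mean = control_inhibition_mean,
                 control_inhibition_sd = control_inhibition_sd),
            class = "assay_noise_model")
}

#' Fractional inhibition at a screening concentration implied by an IC50
#'
#' Single-site occupancy with Hill slope 1 unless overridden:
#' `conc^h / (conc^h + ic50^h)`.
#'
#' @param ic50 Molar IC50.
#' @param conc Molar screening concentration (default 10 uM).
#' @param hill Hill slope.
#' @return Fractional inhibition in `[0, 1]`.
#' @export
inhibition_at <- function(ic50, conc = 1e-5, hill = 1) {
  ch <- conc^hill
  ch / (ch + ic50^hill)
}

#' Specification of planted compound mechanisms
#'
#' Describes the ground-truth composition of a synthetic library:
#' a fraction of true AaDOP2 antagonists with log-uniform IC50s, a
#' fraction of off-target reporter inhibitors (chemistries that suppress
#' the CRE-luciferase readout without touching the receptor, which the
#' screen cannot distinguish from antagonists), and inactive filler.
#'
#' @param frac_antagonist Fraction of the library planted as true antagonists.
#' @param frac_off_target Fraction planted as off-target reporter inhibitors.
#' @param ic50_range Molar range over which antagonist IC50s are log-uniform.
#' @param off_target_effect_range Range of fractional signal suppression for
#'   off-target reporter inhibitors at the screening concentration.
#' @return A list of class `truth_spec`.
#' @export
truth_spec <- function(frac_antagonist = 0.04, frac_off_target = 0.01,
                       ic50_range = c(1e-8, 3e-6),
                       off_target_effect_range = c(0.82, 0.99)) {
  stopifnot(frac_antagonist >= 0, frac_off_target >= 0,
            frac_antagonist + frac_off_target <= 1,
            length(ic50_range) == 2, all(ic50_range > 0))
  structure(list(frac_antagonist = frac_antagonist,
                 frac_off_target = frac_off_target,
                 ic50_range = ic50_range,
                 off_target_effect_range = off_target_effect_range),
            class = "truth_spec")
}

# Draw the per-compound truth table.
draw_truth <- function(n_compounds, spec, screen_conc = 1e-5) {
  ids <- sprintf("CMP%04d", seq_len(n_compounds))
  n_ant <- round(spec$frac_antagonist * n_compounds)
  n_off <- round(spec$frac_off_target * n_compounds)
  mech <- rep("inactive", n_compounds)
  slots <- sample.int(n_compounds, n_ant + n_off)
  mech[slots[seq_len(n_ant)]] <- "true_antagonist"
  if (n_off > 0) mech[slots[n_ant + seq_len(n_off)]] <- "off_target_reporter_inhibitor"
  ic50 <- rep(NA_real_, n_compounds)
  is_ant <- mech == "true_antagonist"
  ic50[is_ant] <- 10^stats::runif(sum(is_ant), log10(spec$ic50_range[1]),
                                  log10(spec$ic50_range[2]))
  eff <- numeric(n_compounds)
  eff[is_ant] <- inhibition_at(ic50[is_ant], screen_conc)
  is_off <- mech == "off_target_reporter_inhibitor"
  eff[is_off] <- stats::runif(sum(is_off), spec$off_target_effect_range[1],
                              spec$off_target_effect_range[2])
  tibble::tibble(compound_id = ids, mechanism = mech,
                 true_ic50_M = ic50, true_effect_at_10uM = eff)
}

# 4PL fraction-of-maximum response, ascending in concentration for hill > 0.
four_pl_fraction <- function(conc, potency, hill = 1) {
  1 / (1 + 10^(hill * (log10(potency) - log10(conc))))
}

# Control-column layout shared by screen and checkerboard plates:
# col 1 background, col 2 maximal stimulation, col 23 antagonist control,
# col 24 dopamine reference curve; test wells occupy cols 3-22.
control_wells_for_plate <- function(plate_id, noise, plate_effect, dopamine_ec50 = 2.4e-7) {
  rows <- LETTERS[1:16]
  bg <- tibble::tibble(plate_id = plate_id, row = rows, col = 1L,
                       role = "background", compound_id = NA_character_,
                       concentration_M = NA_real_, expected_net = 0)
  mx <- tibble::tibble(plate_id = plate_id, row = rows, col = 2L,
                       role = "max_stim", compound_id = NA_character_,
                       concentration_M = 3e-7, expected_net = noise$max_net_signal)
  ctrl_inh <- pmin(pmax(stats::rnorm(16, noise$control_inhibition_mean,
                                     noise$control_inhibition_sd), 0), 1)
  ac <- tibble::tibble(plate_id = plate_id, row = rows, col = 23L,
                       role = "antagonist_control", compound_id = "SCH23390",
                       concentration_M = 1e-5,
                       expected_net = noise$max_net_signal * (1 - ctrl_inh))
  dc_conc <- 10^seq(log10(14e-9), log10(30e-6), length.out = 8)
  dc <- tibble::tibble(plate_id = plate_id, row = rows, col = 24L,
                       role = "dopamine_curve", compound_id = "dopamine",
                       concentration_M = rep(dc_conc, 2),
                       expected_net = noise$max_net_signal *
                         four_pl_fraction(rep(dc_conc, 2), dopamine_ec50))
  out <- dplyr::bind_rows(bg, mx, ac, dc)
  # antagonist-control spread is parameterized on the inhibition scale, so
  # well-level lognormal noise applies to every other role
  noisy <- out$role != "antagonist_control"
  mult <- rep(1, nrow(out))
  mult[noisy] <- rlnorm_cv(sum(noisy), noise$well_noise_cv)
  out$luminescence_cps <- ifelse(
    out$role == "background",
    noise$background_mean * rlnorm_cv(nrow(out), noise$well_noise_cv),
    noise$background_mean + out$expected_net * plate_effect * mult)
  out$expected_net <- NULL
  out
}

#' Simulate a full antagonist screen with planted ground truth
#'
#' Emulates the AaDOP2 campaign design: every compound is screened in
#' quadruplicate at 10 uM, with duplicate wells on each of two assay
#' plates placed in different quadrants to control for plate and
#' automation effects. Each plate carries background, maximal-stimulation
#' (300 nM dopamine), antagonist-control (10 uM SCH23390 + 300 nM
#' dopamine), and dopamine-reference-curve wells in fixed columns, with
#' 320 test wells in columns 3-22. The expected net signal of a test well
#' is `max_net_signal * (1 - true inhibition at 10 uM) * plate effect`,
#' then multiplied by lognormal well noise.
#'
#' @param n_compounds Number of library compounds (default 1280).
#' @param truth A [truth_spec()].
#' @param noise An [assay_noise_model()].
#' @param seed Integer seed.
#' @param screen_conc_M Screening concentration (molar).
#' @param n_plate_pairs Number of plate pairs; by default the minimum
#'   needed (160 compounds per pair). Supplying too few raises a capacity
#'   error.
#' @return A list with `dataset` (a [screen_dataset()]) and `truth`
#'   (the planted per-compound truth table).
#' @export
make_screen <- function(n_compounds = 1280, truth = truth_spec(),
                        noise = assay_noise_model(), seed = 1L,
                        screen_conc_M = 1e-5, n_plate_pairs = NULL) {
  stopifnot(n_compounds >= 1)
  per_pair <- 160L  # 320 test wells per plate, 2 wells per compound per plate
  need <- ceiling(n_compounds / per_pair)
  if (is.null(n_plate_pairs)) n_plate_pairs <- need
  if (n_plate_pairs < need) {
    stop(sprintf("layout capacity exceeded: %d compounds need %d plate pair(s), got %d",
                 n_compounds, need, n_plate_pairs), call. = FALSE)
  }
  with_seed(seed, {
    truth_tab <- draw_truth(n_compounds, truth, screen_conc_M)
    rows <- LETTERS[1:16]
    test_cols <- 3:22
    # positions grouped by quadrant (row parity x col parity)
    grid <- expand.grid(row = rows, col = test_cols, stringsAsFactors = FALSE)
    grid$quadrant <- well_quadrant(grid$row, grid$col)
    by_quad <- split(grid[order(grid$row, grid$col), c("row", "col")],
                     grid$quadrant[order(grid$row, grid$col)])
    wells <- vector("list", 2L * n_plate_pairs)
    for (pair in seq_len(n_plate_pairs)) {
      idx <- ((pair - 1L) * per_pair + 1L):min(pair * per_pair, n_compounds)
      cmp <- truth_tab[idx, ]
      k <- nrow(cmp)
      first_half <- seq_len(k) <= 80L
      for (side in 1:2) {
        plate_id <- sprintf("P%02d%s", pair, c("A", "B")[side])
        pe <- rlnorm_cv(1, noise$plate_effect_sd)
        ctrl <- control_wells_for_plate(plate_id, noise, pe)
        # each compound gets two diagonal quadrants per plate; the pair of
        # diagonals swaps between the two plates of the pair
        qsets <- if (side == 1) list(c(1L, 4L), c(2L, 3L)) else list(c(2L, 3L), c(1L, 4L))
        pos_in_quad <- integer(4)
        tw <- vector("list", k)
        for (j in seq_len(k)) {
          quads <- if (first_half[j]) qsets[[1]] else qsets[[2]]
          ww <- lapply(quads, function(q) {
            pos_in_quad[q] <<- pos_in_quad[q] + 1L
            by_quad[[q]][pos_in_quad[q], ]
          })
          ww <- dplyr::bind_rows(ww)
          ww$plate_id <- plate_id
          ww$role <- "test"
          ww$compound_id <- cmp$compound_id[j]
          ww$concentration_M <- screen_conc_M
          ww$expected_net <- noise$max_net_signal * (1 - cmp$true_effect_at_10uM[j])
          tw[[j]] <- ww
        }
        tw <- dplyr::bind_rows(tw)
        tw$luminescence_cps <- noise$background_mean +
          tw$expected_net * pe * rlnorm_cv(nrow(tw), noise$well_noise_cv)
        tw$expected_net <- NULL
        wells[[2L * (pair - 1L) + side]] <- dplyr::bind_rows(ctrl, tw)
      }
    }
    wells <- dplyr::bind_rows(wells)
    compounds <- tibble::tibble(
      compound_id = truth_tab$compound_id,
      name = truth_tab$compound_id,
      hit_class = "unknown",
      known_mode = truth_tab$mechanism)
    ds <- screen_dataset(wells[, c("plate_id", "row", "col", "role", "compound_id",
                                   "concentration_M", "luminescence_cps")],
                         compounds, check_design = TRUE)
    list(dataset = ds, truth = truth_tab)
  })
}

#' Simulate checkerboard plate-uniformity plates
#'
#' Alternates the minimum condition (300 nM dopamine + 10 uM SCH23390)
#' and the maximum condition (300 nM dopamine alone) over the full
#' 384-well grid of each plate, as in the pre-screen assay qualification.
#'
#' @param noise An [assay_noise_model()].
#' @param n_plates Number of plates (default 3).
#' @param seed Integer seed.
#' @return A [screen_dataset()] whose wells carry roles `max_stim` and
#'   `antagonist_control` in a checkerboard pattern.
#' @export
make_checkerboard <- function(noise = assay_noise_model(), n_plates = 3, seed = 1L) {
  stopifnot(n_plates >= 1)
  with_seed(seed, {
    grids <- lapply(seq_len(n_plates), function(p) {
      g <- expand.grid(row = LETTERS[1:16], col = 1:24, stringsAsFactors = FALSE)
      g$plate_id <- sprintf("CB%02d", p)
      ri <- match(g$row, LETTERS[1:16])
      is_min <- (ri + g$col) %% 2 == 0
      g$role <- ifelse(is_min, "antagonist_control", "max_stim")
      g$compound_id <- ifelse(is_min, "SCH23390", NA_character_)
      g$concentration_M <- ifelse(is_min, 1e-5, 3e-7)
      pe <- rlnorm_cv(1, noise$plate_effect_sd)
      net <- ifelse(is_min,
                    noise$max_net_signal * (1 - noise$control_inhibition_mean),
                    noise$max_net_signal)
      g$luminescence_cps <- noise$background_mean +
        net * pe * rlnorm_cv(nrow(g), noise$well_noise_cv)
      g
    })
    wells <- dplyr::bind_rows(grids)
    screen_dataset(wells[, c("plate_id", "row", "col", "role", "compound_id",
                             "concentration_M", "luminescence_cps")])
  })
}

#' Simulate dose-response experiments from a known 4PL
#'
#' Per-experiment responses are the four-parameter-logistic mean
#' multiplied by lognormal noise; the generating parameters are recorded
#' so downstream fits can be scored for parameter recovery.
#'
#' @param potency Molar EC50 (agonist mode) or IC50 (antagonist mode).
#' @param hill Hill slope magnitude (positive).
#' @param top,bottom Asymptotes in assay units.
#' @param concentrations Strictly positive molar concentrations (>= 5
#'   points recommended).
#' @param n_experiments Number of independent experiments (default 3).
#' @param noise_cv Lognormal noise CV on each response (default 0.1).
#' @param seed Integer seed.
#' @param mode `"agonist"` (ascending) or `"antagonist"` (descending).
#' @param compound_id,receptor Labels carried through to the output.
#' @return A list of class `dose_response_curve` with `points` (tibble of
#'   `concentration_M`, `response`, `experiment_id`) and `truth`.
#' @export
make_dose_response <- function(potency, hill = 1, top = 100, bottom = 0,
                               concentrations, n_experiments = 3,
                               noise_cv = 0.1, seed = 1L,
                               mode = c("agonist", "antagonist"),
                               compound_id = "compound", receptor = "AaDOP2") {
  mode <- match.arg(mode)
  if (any(concentrations <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  stopifnot(potency > 0, hill > 0, n_experiments >= 1)
  h <- if (mode == "antagonist") -hill else hill
  mu <- bottom + (top - bottom) * four_pl_fraction(concentrations, potency, h)
  pts <- with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_experiments), function(e) {
      tibble::tibble(concentration_M = concentrations,
                     response = mu * rlnorm_cv(length(mu), noise_cv),
                     experiment_id = sprintf("E%02d", e))
    }))
  })
  structure(list(points = pts, compound_id = compound_id, receptor = receptor,
                 mode = mode,
                 truth = list(potency = potency, hill = hill,
                              top = top, bottom = bottom, noise_cv = noise_cv)),
            class = "dose_response_curve")
}

#' Simulate a larval dose-mortality bioassay
#'
#' Deaths per well are binomial with mortality probability taken from the
#' two-parameter log-logistic implied by the (LC50, LC90) pair. The
#' default design matches the campaign's in vivo assay: five doses, five
#' technical-replicate wells of ten larvae per dose, repeated in three
#' independent assays, with untreated water controls at dose 0.
#'
#' @param truth_lc50,truth_lc90 Ground-truth LC50 and LC90 in uM
#'   (`truth_lc90 > truth_lc50 > 0`).
#' @param doses_uM Nonzero doses in uM (default 400/200/100/50/25).
#' @param n_per_well Larvae per well (default 10).
#' @param wells_per_dose Technical replicates per dose (default 5).
#' @param n_assays Independent assay repeats (default 3).
#' @param seed Integer seed.
#' @param compound_id Label carried through.
#' @param include_controls Add dose-0 water control wells (zero expected
#'   mortality).
#' @return A tibble of bioassay records: `compound_id`, `dose_uM`,
#'   `n_larvae`, `n_dead`, `technical_replicate`, `assay_replicate`.
#' @export
make_bioassay <- function(truth_lc50, truth_lc90,
                          doses_uM = c(400, 200, 100, 50, 25),
                          n_per_well = 10, wells_per_dose = 5, n_assays = 3,
                          seed = 1L, compound_id = "amitriptyline",
                          include_controls = TRUE) {
  if (!(truth_lc90 > truth_lc50 && truth_lc50 > 0)) {
    stop("require truth_lc90 > truth_lc50 > 0", call. = FALSE)
  }
  slope <- log(9) / (log10(truth_lc90) - log10(truth_lc50))  # logits per log10 dose
  p_dose <- stats::plogis(slope * (log10(doses_uM) - log10(truth_lc50)))
  with_seed(seed, {
    rec <- expand.grid(technical_replicate = seq_len(wells_per_dose),
                       dose_uM = doses_uM,
                       assay_replicate = seq_len(n_assays))
    rec$n_larvae <- n_per_well
    rec$n_dead <- stats::rbinom(nrow(rec), n_per_well,
                                rep(rep(p_dose, each = wells_per_dose), n_assays))
    if (include_controls) {
      ctrl <- expand.grid(technical_replicate = seq_len(wells_per_dose),
                          dose_uM = 0, assay_replicate = seq_len(n_assays))
      ctrl$n_larvae <- n_per_well
      ctrl$n_dead <- 0L
      rec <- rbind(rec, ctrl)
    }
    tibble::tibble(compound_id = compound_id,
                   dose_uM = rec$dose_uM, n_larvae = rec$n_larvae,
                   n_dead = rec$n_dead,
                   technical_replicate = rec$technical_replicate,
                   assay_replicate = rec$assay_replicate)
  })
}
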