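# Shared domain types, validation, and tabular IO for the screening campaign.

WELL_ROLES <- c("background", "max_stim", "antagonist_control",
                "dopamine_curve", "test", "empty")

#' Closed vocabulary of hit classes
#'
#' The seven mechanism classes used to partition confirmed screen hits
#' (dopamine-receptor antagonists, serotonin-receptor ligands,
#' histamine-receptor ligands, muscarinic acetylcholine-receptor ligands,
#' biogenic-amine uptake inhibitors, protein-kinase modulators, and
#' miscellaneous chemistries), plus `"unknown"` for unannotated compounds.
#'
#' @return Character vector of valid `hit_class` labels.
#' @export
hit_classes <- function() {
  c("dopamine_receptor_antagonist",
    "serotonin_receptor_ligand",
    "histamine_receptor_ligand",
    "machr_ligand",
    "uptake_inhibitor",
    "protein_kinase_modulator",
    "miscellaneous",
    "unknown")
}

#' Parse 384-well addresses
#'
#' Converts well addresses such as `"A1"` or `"P24"` into letter row and
#' 1-based column on the 16 x 24 grid.
#'
#' @param well Character vector of well addresses.
#' @return A tibble with columns `row` (letter `A`-`P`) and `col` (integer
#'   1-24).
#' @export
parse_well_address <- function(well) {
  well <- as.character(well)
  ok <- grepl("^[A-Pa-p][0-9]{1,2}$", well) & !is.na(well)
  row <- ifelse(ok, toupper(substr(well, 1, 1)), NA_character_)
  col <- suppressWarnings(as.integer(substring(well, 2)))
  col[!ok] <- NA_integer_
  bad <- !ok | is.na(col) | col < 1L | col > 24L
  if (any(bad)) {
    stop(sprintf("malformed well address at row(s) %s: %s",
                 paste(which(bad)[seq_len(min(5, sum(bad)))], collapse = ", "),
                 paste(unique(well[bad])[seq_len(min(5, sum(bad)))], collapse = ", ")),
         call. = FALSE)
  }
  tibble::tibble(row = row, col = col)
}

#' Quadrant of a 384-well position
#'
#' Quadrants are defined by the parity of row index and column index of the
#' interleaved 16 x 24 grid, matching the standard 4-up replication of a
#' 96-well layout into 384 wells. Used to verify that replicate wells of a
#' compound occupy different quadrants within a plate.
#'
#' @param row Letter row `A`-`P`.
#' @param col Integer column 1-24.
#' @return Integer quadrant 1-4.
#' @export
well_quadrant <- function(row, col) {
  ri <- match(toupper(row), LETTERS[1:16])
  1L + (ri - 1L) %% 2L + 2L * ((as.integer(col) - 1L) %% 2L)
}

#' Construct and validate a screen dataset
#'
#' Bundles well-level measurements with compound annotations and the
#' replication design (quadruplicate wells split across two plates in
#' different quadrants, as in the AaDOP2 campaign).
#'
#' @param wells Tibble with columns `plate_id`, `row`, `col`, `role`,
#'   `compound_id`, `concentration_M`, `luminescence_cps`.
#' @param compounds Optional tibble with columns `compound_id`, `name`,
#'   `hit_class`, `known_mode`.
#' @param design List with `n_replicates` (default 4) and
#'   `plates_per_compound` (default 2).
#' @param check_design If `TRUE`, enforce that every test compound appears
#'   exactly `n_replicates` times, on at least `plates_per_compound`
#'   plates, and in distinct quadrants within each plate.
#' @return An object of class `screen_dataset`.
#' @export
screen_dataset <- function(wells, compounds = NULL,
                           design = list(n_replicates = 4L, plates_per_compound = 2L),
                           check_design = FALSE) {
  wells <- tibble::as_tibble(wells)
  required <- c("plate_id", "row", "col", "role", "compound_id",
                "concentration_M", "luminescence_cps")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols)) {
    stop("wells table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  wells$col <- as.integer(wells$col)
  bad_role <- !wells$role %in% WELL_ROLES
  if (any(bad_role)) {
    stop("unknown well role(s): ", paste(unique(wells$role[bad_role]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(wells$luminescence_cps) & wells$luminescence_cps < 0)) {
    stop("negative luminescence values present", call. = FALSE)
  }
  if (any(!is.na(wells$concentration_M) & wells$concentration_M < 0)) {
    stop("negative concentrations present", call. = FALSE)
  }
  dup <- duplicated(wells[, c("plate_id", "row", "col")])
  if (any(dup)) {
    d <- wells[dup, ]
    stop(sprintf("duplicate well(s) within a plate: e.g. %s %s%d",
                 d$plate_id[1], d$row[1], d$col[1]), call. = FALSE)
  }
  is_test <- wells$role == "test"
  if (any(is_test & (is.na(wells$compound_id) | is.na(wells$concentration_M)))) {
    stop("test wells must carry both compound_id and concentration_M", call. = FALSE)
  }
  if (any(wells$role == "background" & !is.na(wells$compound_id))) {
    stop("background wells must not carry a compound", call. = FALSE)
  }
  if (!is.null(compounds)) {
    compounds <- tibble::as_tibble(compounds)
    if (anyDuplicated(compounds$compound_id)) {
      stop("compound_id must be unique in the annotation table", call. = FALSE)
    }
    bad_class <- !compounds$hit_class %in% hit_classes()
    if (any(bad_class)) {
      stop("unknown hit_class for compound(s): ",
           paste(compounds$compound_id[bad_class], collapse = ", "), call. = FALSE)
    }
  }
  obj <- structure(list(wells = wells, compounds = compounds, design = design),
                   class = "screen_dataset")
  if (check_design) validate_replication(obj)
  obj
}

# Enforces the quadruplicate / two-plate / distinct-quadrant replication.
validate_replication <- function(dataset) {
  tw <- dataset$wells[dataset$wells$role == "test", ]
  if (!nrow(tw)) return(invisible(dataset))
  tw$quadrant <- well_quadrant(tw$row, tw$col)
  per <- dplyr::summarise(
    dplyr::group_by(tw, .data$compound_id),
    n = dplyr::n(),
    n_plates = dplyr::n_distinct(.data$plate_id),
    max_quad_reuse = max(table(paste(.data$plate_id, .data$quadrant))),
    .groups = "drop")
  n_rep <- dataset$design$n_replicates %||% 4L
  n_pl <- dataset$design$plates_per_compound %||% 2L
  bad <- per$n != n_rep | per$n_plates < n_pl | per$max_quad_reuse > 1L
  if (any(bad)) {
    stop("replication design violated for compound(s): ",
         paste(utils::head(per$compound_id[bad], 5), collapse = ", "), call. = FALSE)
  }
  invisible(dataset)
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat(sprintf("<screen_dataset> %d wells on %d plate(s)",
              nrow(x$wells), length(unique(x$wells$plate_id))))
  if (!is.null(x$compounds)) cat(sprintf(", %d annotated compounds", nrow(x$compounds)))
  cat("\n")
  print(table(x$wells$role))
  invisible(x)
}

#' Read plate measurements from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row and columns
#' `plate_id`, `well`, `role`, `compound_id`, `concentration_M`,
#' `luminescence_cps`. Well addresses (`A1`-`P24`) are parsed into letter
#' row and integer column; every malformed row raises a located error
#' rather than being silently dropped.
#'
#' @param path Path to the CSV file.
#' @param compounds_path Optional path to a compound annotation CSV with
#'   columns `compound_id`, `name`, `hit_class`, `known_mode`.
#' @param check_design Passed to [screen_dataset()].
#' @return A validated [screen_dataset()].
#' @export
read_plate_csv <- function(path, compounds_path = NULL, check_design = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    plate_id = readr::col_character(),
    well = readr::col_character(),
    role = readr::col_character(),
    compound_id = readr::col_character(),
    concentration_M = readr::col_double(),
    luminescence_cps = readr::col_double()))
  missing_cols <- setdiff(c("plate_id", "well", "role", "compound_id",
                            "concentration_M", "luminescence_cps"), names(raw))
  if (length(missing_cols)) {
    stop("plate CSV is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  rc <- parse_well_address(raw$well)
  wells <- tibble::tibble(
    plate_id = raw$plate_id, row = rc$row, col = rc$col, role = raw$role,
    compound_id = raw$compound_id, concentration_M = raw$concentration_M,
    luminescence_cps = raw$luminescence_cps)
  compounds <- if (!is.null(compounds_path)) read_compound_csv(compounds_path)
  screen_dataset(wells, compounds, check_design = check_design)
}

#' Read a compound annotation CSV
#'
#' @param path CSV with columns `compound_id`, `name`, `hit_class`,
#'   `known_mode`; `hit_class` must come from [hit_classes()].
#' @return A tibble of compound records.
#' @export
read_compound_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(c("compound_id", "name", "hit_class"), names(x))
  if (length(missing_cols)) {
    stop("compound CSV is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"known_mode" %in% names(x)) x$known_mode <- NA_character_
  bad <- !x$hit_class %in% hit_classes()
  if (any(bad)) {
    stop("unknown hit_class for compound(s): ",
         paste(x$compound_id[bad], collapse = ", "), call. = FALSE)
  }
  x
}

#' Write a plate table back to CSV
#'
#' Inverse of [read_plate_csv()]: emits the documented CSV dialect with a
#' `well` address column reassembled from `row` and `col`. `write` then
#' `read` is the identity on the typed well table.
#'
#' @param dataset A [screen_dataset()].
#' @param path Output path.
#' @export
write_plate_csv <- function(dataset, path) {
  w <- dataset$wells
  out <- tibble::tibble(
    plate_id = w$plate_id,
    well = paste0(w$row, w$col),
    role = w$role,
    compound_id = w$compound_id,
    concentration_M = w$concentration_M,
    luminescence_cps = w$luminescence_cps)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write a result table as TSV
#'
#' Columns are written in their existing (stable) order. For potency
#' columns a human-readable companion rounded to 2 significant figures can
#' be added; machine columns keep full precision.
#'
#' @param records A data frame; zero rows allowed (header-only file).
#' @param path Output path.
#' @param report_signif Named character vector mapping machine column names
#'   to report column names to add, rounded to 2 significant figures.
#' @export
write_table <- function(records, path, report_signif = NULL) {
  records <- tibble::as_tibble(records)
  if (!is.null(report_signif)) {
    for (machine in names(report_signif)) {
      if (machine %in% names(records)) {
        records[[report_signif[[machine]]]] <- signif(records[[machine]], 2)
      }
    }
  }
  readr::write_tsv(records, path, na = "")
  invisible(path)
}

#' Read a result table written by [write_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}

#' Run configuration
#'
#' Campaign-level tunables: `k_sd` is the hit-threshold multiplier (the
#' antagonist-control criterion is mean inhibition minus `k_sd` standard
#' deviations; the campaign default is 3), `censor_limit` the molar
#' concentration at or above which a potency is reported as lacking
#' activity (default 1e-5 M, i.e. 10 uM), `rng_seed` the simulation seed,
#' and `noise_cv` / `plate_effect_sd` the synthetic noise magnitudes
#' (see [assay_noise_model()]).
#'
#' @param k_sd Positive threshold multiplier.
#' @param censor_limit Positive molar censoring limit.
#' @param rng_seed Integer seed.
#' @param noise_cv Lognormal well-noise coefficient of variation.
#' @param plate_effect_sd SD of the multiplicative lognormal plate effect.
#' @return A list of class `run_config`.
#' @export
run_config <- function(k_sd = 3, censor_limit = 1e-5, rng_seed = 1L,
                       noise_cv = 0.22, plate_effect_sd = 0.08) {
  stopifnot(is.numeric(k_sd), length(k_sd) == 1, k_sd > 0,
            is.numeric(censor_limit), length(censor_limit) == 1, censor_limit > 0,
            noise_cv >= 0, plate_effect_sd >= 0)
  structure(list(k_sd = k_sd, censor_limit = censor_limit,
                 rng_seed = as.integer(rng_seed), noise_cv = noise_cv,
                 plate_effect_sd = plate_effect_sd),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys raise an error naming the offending key so that a typo in
#' a campaign file cannot silently fall back to a default.
#'
#' @param path Path to a YAML file whose keys are the arguments of
#'   [run_config()].
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
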