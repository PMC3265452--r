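# Screen processing: background subtraction, per-plate normalization,
# antagonist-control scoring, replicate aggregation, threshold derivation,
# hit calling, and class partitioning.

#' Normalize screen wells per plate
#'
#' Within each plate, the mean background luminescence (wells without
#' dopamine or compound) is subtracted from every raw value, and the mean
#' net signal of the 300 nM dopamine maximal-stimulation wells defines
#' the plate's 100 percent stimulation level. Each well is then expressed
#' as percent stimulation and percent inhibition:
#' `pct_inhibition = 100 * (1 - net / plate max-stimulation net mean)`.
#' Normalization is strictly per-plate, which cancels multiplicative
#' plate effects.
#'
#' @param dataset A [screen_dataset()]; every plate must carry at least 2
#'   `background` and 2 `max_stim` wells.
#' @return A tibble of normalized wells: `plate_id`, `row`, `col`,
#'   `role`, `compound_id`, `net_cps`, `pct_stimulation`,
#'   `pct_inhibition`.
#' @export
normalize_wells <- function(dataset) {
  w <- dataset$wells
  counts <- dplyr::summarise(
    dplyr::group_by(w, .data$plate_id),
    n_bg = sum(.data$role == "background"),
    n_max = sum(.data$role == "max_stim"), .groups = "drop")
  bad <- counts[counts$n_bg < 2 | counts$n_max < 2, ]
  if (nrow(bad)) {
    miss <- vapply(seq_len(nrow(bad)), function(i) {
      roles <- c(if (bad$n_bg[i] < 2) "background", if (bad$n_max[i] < 2) "max_stim")
      sprintf("%s (missing %s)", bad$plate_id[i], paste(roles, collapse = ", "))
    }, "")
    stop("plate(s) lack required control wells: ", paste(miss, collapse = "; "),
         call. = FALSE)
  }
  plate_stats <- dplyr::summarise(
    dplyr::group_by(w, .data$plate_id),
    bg_mean = mean(.data$luminescence_cps[.data$role == "background"]),
    .groups = "drop")
  out <- dplyr::left_join(w, plate_stats, by = "plate_id")
  out$net_cps <- out$luminescence_cps - out$bg_mean
  max_stats <- dplyr::summarise(
    dplyr::group_by(out[out$role == "max_stim", ], .data$plate_id),
    max_net_mean = mean(.data$net_cps), .groups = "drop")
  out <- dplyr::left_join(out, max_stats, by = "plate_id")
  out$pct_stimulation <- 100 * out$net_cps / out$max_net_mean
  out$pct_inhibition <- 100 * (1 - out$net_cps / out$max_net_mean)
  tibble::as_tibble(out[, c("plate_id", "row", "col", "role", "compound_id",
                            "net_cps", "pct_stimulation", "pct_inhibition")])
}

#' Aggregate replicate wells per compound
#'
#' Unweighted mean of percent inhibition over all replicate test wells of
#' each compound (after per-plate normalization), with the replicate
#' count and sample SD retained. A single-replicate compound keeps its
#' value with an `NA` SD.
#'
#' @param normalized Output of [normalize_wells()].
#' @return A tibble with `compound_id`, `mean_pct_inhibition`,
#'   `sd_pct_inhibition`, `n_replicates`.
#' @export
aggregate_replicates <- function(normalized) {
  tw <- normalized[normalized$role == "test", ]
  if (!nrow(tw)) stop("no test wells to aggregate", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(tw, .data$compound_id),
    mean_pct_inhibition = mean(.data$pct_inhibition),
    sd_pct_inhibition = if (dplyr::n() > 1) stats::sd(.data$pct_inhibition) else NA_real_,
    n_replicates = dplyr::n(),
    .groups = "drop")
}

#' Derive the hit threshold from antagonist-control wells
#'
#' The hit criterion is the percent inhibition achieved by the SCH23390
#' antagonist control widened by `k_sd` standard deviations:
#' `threshold = mean(control inhibition) - k_sd * sd(control inhibition)`.
#' Larger `k_sd` lowers the threshold (more permissive). Control wells
#' are pooled across all plates of the run, yielding one campaign-wide
#' cutoff, while signal normalization stays per-plate.
#'
#' @param control_inhibition Percent-inhibition values of normalized
#'   antagonist-control wells (>= 2), e.g.
#'   `normalized$pct_inhibition[normalized$role == "antagonist_control"]`.
#' @param k_sd Positive multiplier (campaign default 3).
#' @return A list with `threshold_pct_inhibition`, `control_mean`,
#'   `control_sd`, `k_sd`, `n_control_wells`.
#' @export
derive_threshold <- function(control_inhibition, k_sd = 3) {
  control_inhibition <- control_inhibition[!is.na(control_inhibition)]
  if (length(control_inhibition) < 2) {
    stop("need at least 2 antagonist-control wells to derive a threshold",
         call. = FALSE)
  }
  stopifnot(k_sd >= 0)
  m <- mean(control_inhibition); s <- stats::sd(control_inhibition)
  list(threshold_pct_inhibition = m - k_sd * s,
       control_mean = m, control_sd = s, k_sd = k_sd,
       n_control_wells = length(control_inhibition))
}

#' Call hits against a threshold and partition them by class
#'
#' A compound is a hit when its mean percent inhibition is at least the
#' threshold (closed bound). Each compound's effect is also expressed
#' relative to the antagonist control
#' (`pct_of_control_effect = 100 * mean inhibition / control mean
#' inhibition`). Hits are partitioned into the seven annotation classes
#' of [hit_classes()].
#'
#' @param aggregated Output of [aggregate_replicates()].
#' @param threshold Either the list returned by [derive_threshold()] or a
#'   bare numeric threshold (percent inhibition).
#' @param annotations Optional compound annotation tibble
#'   (`compound_id`, `hit_class`, ...); classes are validated against
#'   [hit_classes()].
#' @param control_mean Mean control inhibition used for
#'   `pct_of_control_effect`; taken from `threshold` when that is a
#'   [derive_threshold()] result.
#' @return A list with `hits` (the per-compound hit table) and
#'   `class_counts` (hits per class).
#' @export
call_hits <- function(aggregated, threshold, annotations = NULL,
                      control_mean = NULL) {
  if (is.list(threshold)) {
    control_mean <- control_mean %||% threshold$control_mean
    k_sd <- threshold$k_sd
    threshold <- threshold$threshold_pct_inhibition
  } else {
    k_sd <- NA_real_
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  out <- aggregated
  out$pct_of_control_effect <- if (!is.null(control_mean))
    100 * out$mean_pct_inhibition / control_mean else NA_real_
  out$threshold_pct_inhibition <- threshold
  out$k_sd <- k_sd
  out$is_hit <- out$mean_pct_inhibition >= threshold
  if (!is.null(annotations)) {
    bad <- !annotations$hit_class %in% hit_classes()
    if (any(bad)) {
      stop("unknown hit_class for compound(s): ",
           paste(annotations$compound_id[bad], collapse = ", "), call. = FALSE)
    }
    out <- dplyr::left_join(out, annotations[, c("compound_id", "hit_class")],
                            by = "compound_id")
    out$hit_class[is.na(out$hit_class)] <- "unknown"
  } else {
    out$hit_class <- "unknown"
  }
  counts <- dplyr::count(out[out$is_hit, ], .data$hit_class, name = "n_hits")
  list(hits = out, class_counts = counts, n_hits = sum(out$is_hit))
}

#' Score hit calls against planted truth
#'
#' On synthetic screens the planted truth table is the oracle: a compound
#' is truly positive when its mechanism suppresses the reporter signal
#' (true antagonist or off-target reporter inhibitor). Sensitivity is
#' also reported restricted to "detectable" positives whose true
#' inhibition exceeds the threshold by a margin, since a positive planted
#' right at the cutoff is a coin flip by construction. By default the
#' margin is three standard errors of that compound's own replicate mean.
#'
#' @param hits Hit table from [call_hits()].
#' @param truth Truth table from [make_screen()].
#' @param detect_margin_pct Margin (percent inhibition) above the
#'   threshold defining the detectable subset; `NULL` (default) uses
#'   `3 * sd_pct_inhibition / sqrt(n_replicates)` per compound.
#' @return A list with confusion counts, `sensitivity`, `specificity`,
#'   and `sensitivity_detectable`.
#' @export
score_against_truth <- function(hits, truth, detect_margin_pct = NULL) {
  m <- dplyr::inner_join(hits$hits, truth, by = "compound_id")
  pos <- m$mechanism != "inactive"
  tp <- sum(pos & m$is_hit); fn <- sum(pos & !m$is_hit)
  fp <- sum(!pos & m$is_hit); tn <- sum(!pos & !m$is_hit)
  thr <- m$threshold_pct_inhibition[1]
  margin <- if (is.null(detect_margin_pct)) {
    se <- m$sd_pct_inhibition / sqrt(m$n_replicates)
    ifelse(is.finite(se), 3 * se, Inf)
  } else {
    detect_margin_pct
  }
  detectable <- pos & 100 * m$true_effect_at_10uM >= thr + margin
  sens_det <- if (any(detectable)) mean(m$is_hit[detectable]) else NA_real_
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       sensitivity_detectable = sens_det,
       n_detectable = sum(detectable))
}
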