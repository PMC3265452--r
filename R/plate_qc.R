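# Checkerboard analysis: Z-factor assay quality control.

#' Z-factor quality-control report
#'
#' Computes the screening-window statistic of Zhang, Chung and Oldenburg
#' from maximum- and minimum-condition signals:
#' `z_standard = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|`.
#' Screens run with replicate wells per compound average away part of the
#' well-level noise, so a replicate-adjusted form (the NIH assay-guidance
#' plate-uniformity recommendation) is reported alongside, with each
#' condition SD shrunk by the square root of the planned replicate count:
#' `z_replicate_adjusted = 1 - 3 (sd_pos + sd_neg) / (sqrt(n) |mean_pos - mean_neg|)`.
#' Sample SDs use the n-1 denominator. When the two condition means are
#' equal both statistics are undefined and flagged rather than thrown.
#'
#' @param pos Numeric signals of the maximum-stimulation condition (>= 2).
#' @param neg Numeric signals of the minimum condition (>= 2).
#' @param n_replicates_planned Planned replicates per compound in the
#'   screen the assay is being qualified for (default 4).
#' @return A list of class `qc_report` with the condition means/SDs,
#'   counts, both Z statistics, and `undefined` flag.
#' @export
compute_z <- function(pos, neg, n_replicates_planned = 4) {
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (length(pos) < 2 || length(neg) < 2) {
    stop("need at least 2 signals per condition", call. = FALSE)
  }
  stopifnot(n_replicates_planned >= 1)
  mu_p <- mean(pos); mu_n <- mean(neg)
  sd_p <- stats::sd(pos); sd_n <- stats::sd(neg)
  delta <- abs(mu_p - mu_n)
  undefined <- delta == 0
  z_std <- if (undefined) NA_real_ else 1 - 3 * (sd_p + sd_n) / delta
  z_adj <- if (undefined) NA_real_ else
    1 - 3 * (sd_p + sd_n) / (sqrt(n_replicates_planned) * delta)
  structure(list(mu_pos = mu_p, sigma_pos = sd_p, n_pos = length(pos),
                 mu_neg = mu_n, sigma_neg = sd_n, n_neg = length(neg),
                 n_replicates_planned = n_replicates_planned,
                 z_standard = z_std, z_replicate_adjusted = z_adj,
                 undefined = undefined),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> max: %.1f +/- %.1f (n=%d); min: %.1f +/- %.1f (n=%d)\n",
              x$mu_pos, x$sigma_pos, x$n_pos, x$mu_neg, x$sigma_neg, x$n_neg))
  if (x$undefined) {
    cat("Z undefined: condition means are equal\n")
  } else {
    cat(sprintf("Z = %.3f; replicate-adjusted Z (n=%d) = %.3f\n",
                x$z_standard, x$n_replicates_planned, x$z_replicate_adjusted))
  }
  invisible(x)
}

#' Checkerboard QC over a plate set
#'
#' Runs [compute_z()] per plate on a checkerboard dataset (roles
#' `max_stim` vs `antagonist_control`) and summarizes the per-plate
#' replicate-adjusted Z-factors.
#'
#' @param dataset A [screen_dataset()] from [make_checkerboard()] or
#'   [read_plate_csv()].
#' @param n_replicates_planned Planned replicate count (default 4).
#' @return A list with `per_plate` (tibble of per-plate statistics) and
#'   `mean_z_replicate_adjusted` / `sd_z_replicate_adjusted`.
#' @export
checkerboard_qc <- function(dataset, n_replicates_planned = 4) {
  w <- dataset$wells
  plates <- unique(w$plate_id)
  per <- lapply(plates, function(p) {
    wp <- w[w$plate_id == p, ]
    z <- compute_z(wp$luminescence_cps[wp$role == "max_stim"],
                   wp$luminescence_cps[wp$role == "antagonist_control"],
                   n_replicates_planned)
    tibble::tibble(plate_id = p, mu_pos = z$mu_pos, sigma_pos = z$sigma_pos,
                   mu_neg = z$mu_neg, sigma_neg = z$sigma_neg,
                   z_standard = z$z_standard,
                   z_replicate_adjusted = z$z_replicate_adjusted)
  })
  per <- dplyr::bind_rows(per)
  list(per_plate = per,
       mean_z_replicate_adjusted = mean(per$z_replicate_adjusted),
       sd_z_replicate_adjusted = stats::sd(per$z_replicate_adjusted),
       mean_z_standard = mean(per$z_standard))
}
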