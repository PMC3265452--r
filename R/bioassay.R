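# Larval bioassay analysis: single-dose mortality significance and
# dose-mortality LC50/LC90 estimation.

#' One-sample t-test of single-dose larval mortality
#'
#' Tests the per-replicate percent mortality of a treated condition
#' against the observed control mortality (0 percent for water controls)
#' with a two-tailed one-sample t-test on the biological-replicate means
#' (`df = replicates - 1`). Zero-variance data with a nonzero difference
#' cannot produce a finite t statistic; the p-value is then reported as
#' below the machine floor with a flag instead of an exception.
#'
#' @param treated Percent mortality per biological replicate (>= 2).
#' @param control_mean Control mortality to test against (default 0).
#' @return A list with `mean_mortality`, `sd`, `n`, `t`, `df`,
#'   `p_value`, and `zero_variance`.
#' @export
single_dose_test <- function(treated, control_mean = 0) {
  treated <- treated[!is.na(treated)]
  if (length(treated) < 2) {
    stop("need at least 2 biological replicates", call. = FALSE)
  }
  s <- stats::sd(treated)
  if (s == 0) {
    diff0 <- mean(treated) - control_mean
    return(list(mean_mortality = mean(treated), sd = 0, n = length(treated),
                t = if (diff0 == 0) 0 else Inf * sign(diff0),
                df = length(treated) - 1,
                p_value = if (diff0 == 0) 1 else .Machine$double.xmin,
                zero_variance = TRUE))
  }
  tt <- stats::t.test(treated, mu = control_mean)
  list(mean_mortality = mean(treated), sd = s, n = length(treated),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, zero_variance = FALSE)
}

#' Fit a dose-mortality model and derive LC50/LC90
#'
#' Binomial regression of per-well deaths on log10 dose with a logistic
#' link (log-logistic tolerance model; probit available). The LC50 is
#' the root of the fitted linear predictor; the LC90 follows from the
#' slope in closed form: for the logit link
#' `log10(LC90) = log10(LC50) + log10(9) / slope_base10`, where
#' `slope_base10` is the fitted slope in logits per log10 dose divided
#' by ln(10). Control (dose 0) wells are excluded from the regression;
#' if control mortality is nonzero, Abbott's correction of treated
#' proportions is available but off by default. Confidence intervals are
#' percentile bootstrap over wells (the technical-replicate resampling
#' unit).
#'
#' @param records Bioassay tibble (see [make_bioassay()]): `dose_uM`,
#'   `n_larvae`, `n_dead` per well.
#' @param link `"logit"` (default) or `"probit"`.
#' @param abbott Apply Abbott's correction using observed control
#'   mortality (default `FALSE`).
#' @param n_boot Bootstrap resamples for the 95 percent CIs (default
#'   500; 0 skips the bootstrap).
#' @param seed Seed for the bootstrap.
#' @return A list of class `lc_fit` with `lc50`, `lc90` (uM),
#'   `slope` (logits or probits per log10 dose), `lc50_ci`, `lc90_ci`,
#'   `deviance`, `df_residual`, `link`, and `n_wells`.
#' @export
fit_lc <- function(records, link = c("logit", "probit"), abbott = FALSE,
                   n_boot = 500, seed = 1L) {
  link <- match.arg(link)
  records <- tibble::as_tibble(records)
  stopifnot(all(c("dose_uM", "n_larvae", "n_dead") %in% names(records)))
  if (any(records$n_dead > records$n_larvae | records$n_dead < 0)) {
    stop("death counts must lie in [0, n_larvae]", call. = FALSE)
  }
  ctrl <- records[records$dose_uM == 0, ]
  trt <- records[records$dose_uM > 0, ]
  doses <- sort(unique(trt$dose_uM))
  if (length(doses) < 3) {
    stop("need at least 3 distinct nonzero doses", call. = FALSE)
  }
  if (abbott && nrow(ctrl)) {
    c0 <- sum(ctrl$n_dead) / sum(ctrl$n_larvae)
    if (c0 > 0) {
      # Abbott: p' = (p - c) / (1 - c), applied to expected counts
      p_raw <- trt$n_dead / trt$n_larvae
      p_adj <- pmax((p_raw - c0) / (1 - c0), 0)
      trt$n_dead <- round(p_adj * trt$n_larvae)
    }
  }
  per_dose <- tapply(trt$n_dead / trt$n_larvae, trt$dose_uM, mean)
  if (all(per_dose == 0) || all(per_dose == 1) ||
      all(per_dose %in% c(0, 1))) {
    stop("complete separation: every dose is all-or-nothing; the slope is unidentified",
         call. = FALSE)
  }
  fit_once <- function(d) {
    g <- stats::glm(cbind(n_dead, n_larvae - n_dead) ~ log10(dose_uM),
                    family = stats::binomial(link = link), data = d)
    b <- stats::coef(g)
    lc50 <- 10^(-b[1] / b[2])
    q90 <- if (link == "logit") stats::qlogis(0.9) else stats::qnorm(0.9)
    lc90 <- 10^((q90 - b[1]) / b[2])
    list(lc50 = unname(lc50), lc90 = unname(lc90), slope = unname(b[2]),
         intercept = unname(b[1]), deviance = g$deviance,
         df_residual = g$df.residual)
  }
  f <- fit_once(trt)
  ci <- list(lc50 = c(NA_real_, NA_real_), lc90 = c(NA_real_, NA_real_))
  if (n_boot > 0) {
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(nrow(trt), replace = TRUE)
        bf <- tryCatch(fit_once(trt[idx, ]), error = function(e) NULL)
        if (is.null(bf) || !is.finite(bf$lc50) || bf$slope <= 0)
          c(NA_real_, NA_real_)
        else c(bf$lc50, bf$lc90)
      }, numeric(2))
    })
    ok <- stats::complete.cases(t(boot))
    if (sum(ok) >= 50) {
      ci$lc50 <- unname(stats::quantile(boot[1, ok], c(0.025, 0.975)))
      ci$lc90 <- unname(stats::quantile(boot[2, ok], c(0.025, 0.975)))
    }
  }
  structure(list(lc50 = f$lc50, lc90 = f$lc90, slope = f$slope,
                 intercept = f$intercept, lc50_ci = ci$lc50, lc90_ci = ci$lc90,
                 deviance = f$deviance, df_residual = f$df_residual,
                 link = link, n_wells = nrow(trt),
                 control_mortality = if (nrow(ctrl))
                   sum(ctrl$n_dead) / sum(ctrl$n_larvae) else NA_real_),
            class = "lc_fit")
}

#' @export
print.lc_fit <- function(x, ...) {
  cat(sprintf("<lc_fit> %s link, %d wells\n", x$link, x$n_wells))
  cat(sprintf("LC50 = %.3g uM (95%% CI %.3g-%.3g)\n", x$lc50, x$lc50_ci[1], x$lc50_ci[2]))
  cat(sprintf("LC90 = %.3g uM (95%% CI %.3g-%.3g)\n", x$lc90, x$lc90_ci[1], x$lc90_ci[2]))
  cat(sprintf("slope = %.3g per log10 dose; residual deviance %.2f on %d df\n",
              x$slope, x$deviance, x$df_residual))
  invisible(x)
}
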