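# Four-parameter logistic potency estimation: per-experiment fits,
# geometric-mean aggregation to a potency +/- SEM, and activity censoring.

# Predicted response of the 4PL at log10 concentration lc.
pred_4pl <- function(par, lc) {
  # par: top, bottom, log10 potency, hill
  par[2] + (par[1] - par[2]) / (1 + 10^(par[4] * (par[3] - lc)))
}

# One multi-start bounded Levenberg-Marquardt fit on a single experiment.
fit_4pl_one <- function(conc, resp) {
  lc <- log10(conc)
  rng <- range(lc)
  lo <- c(top = -Inf, bottom = -Inf, logp = rng[1] - 1, hill = -10)
  hi <- c(top = Inf, bottom = Inf, logp = rng[2] + 1, hill = 10)
  # midpoint start: log-concentration where the response crosses half-range
  half <- (max(resp) + min(resp)) / 2
  ord <- order(lc)
  cross <- lc[ord][which.min(abs(resp[ord] - half))]
  starts <- list()
  for (h in c(1, -1, 0.5, -0.5)) {
    starts[[length(starts) + 1]] <-
      c(top = max(resp), bottom = min(resp), logp = cross, hill = h)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st,
        fn = function(p) resp - pred_4pl(p, lc),
        lower = lo, upper = hi,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      best <- list(par = fit$par, rss = rss, info = fit$info)
    }
  }
  if (is.null(best)) {
    return(list(converged = FALSE, top = NA_real_, bottom = NA_real_,
                log10_potency = NA_real_, hill = NA_real_, rss = NA_real_,
                at_bound = NA))
  }
  p <- best$par
  list(converged = TRUE, top = unname(p[1]), bottom = unname(p[2]),
       log10_potency = unname(p[3]), hill = unname(p[4]), rss = best$rss,
       at_bound = unname(p[3]) >= hi["logp"] - 1e-6 ||
         unname(p[3]) <= lo["logp"] + 1e-6)
}

#' Fit a four-parameter logistic per experiment
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + 10^(hill * (log10(potency) - log10(conc))))`
#' separately for each experiment of a dose-response curve, using
#' bounded Levenberg-Marquardt with multiple starts (Hill slope seeded at
#' +/-1 and +/-0.5; midpoint seeded at the half-range crossing; potency
#' bounded one decade beyond the tested range). The Hill slope is free,
#' and its sign carries the orientation: positive for ascending
#' (agonist) curves, negative for descending (antagonist/IC50) curves.
#'
#' @param curve A `dose_response_curve` (from [make_dose_response()] or
#'   [as_dose_response()]); needs >= 4 distinct concentrations per
#'   experiment (>= 5 recommended).
#' @return A tibble with one row per experiment: `experiment_id`, `top`,
#'   `bottom`, `log10_potency`, `potency_M`, `hill`, `rss`, `sigma`
#'   (residual SD), `converged`, `at_bound`.
#' @export
fit_4pl <- function(curve) {
  pts <- curve$points
  stopifnot(all(pts$concentration_M > 0))
  by_exp <- split(pts, pts$experiment_id)
  rows <- lapply(names(by_exp), function(e) {
    d <- by_exp[[e]]
    if (length(unique(d$concentration_M)) < 4) {
      stop(sprintf("experiment %s has fewer than 4 distinct concentrations", e),
           call. = FALSE)
    }
    f <- fit_4pl_one(d$concentration_M, d$response)
    dof <- nrow(d) - 4
    tibble::tibble(experiment_id = e, top = f$top, bottom = f$bottom,
                   log10_potency = f$log10_potency,
                   potency_M = 10^f$log10_potency, hill = f$hill,
                   rss = f$rss,
                   sigma = if (f$converged && dof > 0) sqrt(f$rss / dof) else NA_real_,
                   converged = f$converged, at_bound = isTRUE(f$at_bound))
  })
  dplyr::bind_rows(rows)
}

#' Wrap a points table as a dose-response curve
#'
#' @param points Tibble with `concentration_M`, `response`,
#'   `experiment_id`.
#' @param compound_id,receptor,mode Labels.
#' @return A `dose_response_curve`.
#' @export
as_dose_response <- function(points, compound_id = "compound",
                             receptor = "AaDOP2",
                             mode = c("agonist", "antagonist")) {
  mode <- match.arg(mode)
  points <- tibble::as_tibble(points)
  stopifnot(all(c("concentration_M", "response", "experiment_id") %in% names(points)))
  if (any(points$concentration_M <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  structure(list(points = points, compound_id = compound_id,
                 receptor = receptor, mode = mode, truth = NULL),
            class = "dose_response_curve")
}

#' Aggregate per-experiment fits into a potency estimate
#'
#' Potencies are log-normally distributed across experiments, so the
#' summary potency is the geometric mean of per-experiment potencies;
#' its SEM is computed on the log10 scale and mapped back to the linear
#' scale by the delta method (`sem = potency * ln(10) * sem_log10`).
#' Estimates at or above the censoring limit are flagged and rendered as
#' lacking intrinsic activity (">= 10 uM" at the default limit);
#' censoring is applied after aggregation. Fits that failed or pinned
#' the potency at the search bound are dropped; if none survive the
#' result is censored-with-failure.
#'
#' @param fits Per-experiment fit table from [fit_4pl()].
#' @param censor_limit Molar activity-censoring limit (default 1e-5).
#' @param compound_id,receptor Labels carried into the estimate.
#' @return A one-row tibble: `compound_id`, `receptor`, `potency_M`,
#'   `sem_M`, `hill`, `top`, `bottom`, `n_experiments`, `censored`,
#'   `all_failed`, `display` (e.g. `"2.4e-07 M"` or `">= 1e-05 M"`).
#' @export
summarize_experiments <- function(fits, censor_limit = 1e-5,
                                  compound_id = "compound", receptor = "AaDOP2") {
  ok <- fits[fits$converged & !fits$at_bound & is.finite(fits$log10_potency), ]
  if (!nrow(ok)) {
    return(tibble::tibble(compound_id = compound_id, receptor = receptor,
                          potency_M = NA_real_, sem_M = NA_real_,
                          hill = NA_real_, top = NA_real_, bottom = NA_real_,
                          n_experiments = 0L, censored = TRUE, all_failed = TRUE,
                          display = sprintf(">= %g M", censor_limit)))
  }
  lp <- ok$log10_potency
  gm <- 10^mean(lp)
  sem_log <- if (nrow(ok) > 1) stats::sd(lp) / sqrt(nrow(ok)) else 0
  sem_lin <- gm * log(10) * sem_log
  censored <- gm >= censor_limit
  tibble::tibble(
    compound_id = compound_id, receptor = receptor,
    potency_M = gm, sem_M = sem_lin,
    hill = mean(ok$hill), top = mean(ok$top), bottom = mean(ok$bottom),
    n_experiments = nrow(ok), censored = censored, all_failed = FALSE,
    display = if (censored) sprintf(">= %g M", censor_limit)
              else sprintf("%.3g M", gm))
}

#' Fit and summarize a dose-response curve in one call
#'
#' @param curve A `dose_response_curve`.
#' @param censor_limit Molar censoring limit.
#' @return The [summarize_experiments()] estimate, with the per-experiment
#'   fit table attached as attribute `"fits"`.
#' @export
fit_dose_response <- function(curve, censor_limit = 1e-5) {
  fits <- fit_4pl(curve)
  est <- summarize_experiments(fits, censor_limit,
                               compound_id = curve$compound_id,
                               receptor = curve$receptor)
  attr(est, "fits") <- fits
  est
}
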