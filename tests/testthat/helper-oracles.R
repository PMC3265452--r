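# Independent oracles and small fixture builders used across the suite.

# Brute-force 4PL fit: dense grid over (log10 potency, hill) with top and
# bottom profiled out by closed-form linear least squares. Independent of
# the package's Levenberg-Marquardt path.
oracle_fit_4pl_grid <- function(conc, resp,
                                logp_grid = NULL, hill_grid = NULL) {
  lc <- log10(conc)
  if (is.null(logp_grid)) {
    logp_grid <- seq(min(lc) - 1, max(lc) + 1, by = 0.02)
  }
  if (is.null(hill_grid)) hill_grid <- seq(-3, 3, by = 0.05)
  hill_grid <- hill_grid[hill_grid != 0]
  best <- list(rss = Inf)
  for (h in hill_grid) {
    for (lp in logp_grid) {
      f <- 1 / (1 + 10^(h * (lp - lc)))
      # resp ~ bottom + (top - bottom) * f, linear in (bottom, span)
      vf <- stats::var(f)
      if (vf < 1e-12) next
      span <- stats::cov(f, resp) / vf
      bottom <- mean(resp) - span * mean(f)
      rss <- sum((resp - bottom - span * f)^2)
      if (rss < best$rss) {
        best <- list(rss = rss, logp = lp, hill = h,
                     bottom = bottom, top = bottom + span)
      }
    }
  }
  best
}

# Minimal valid two-control plate with explicit luminescence values.
tiny_plate <- function(plate_id = "P1", bg = c(100, 100), mx = c(1100, 1100),
                       test = NULL) {
  rows <- LETTERS[seq_len(length(bg) + length(mx) + length(test))]
  w <- tibble::tibble(
    plate_id = plate_id,
    row = rows,
    col = seq_along(rows),
    role = c(rep("background", length(bg)), rep("max_stim", length(mx)),
             rep("test", length(test))),
    compound_id = c(rep(NA_character_, length(bg) + length(mx)),
                    if (length(test)) sprintf("C%02d", seq_along(test))),
    concentration_M = c(rep(NA_real_, length(bg)), rep(3e-7, length(mx)),
                        rep(1e-5, length(test))),
    luminescence_cps = c(bg, mx, test))
  screen_dataset(w)
}

# The eight confirmation compounds with uncensored IC50s at both
# receptors (nM), used for selectivity oracles.
confirmation_pairs_nM <- function() {
  ref <- reference_confirmation_potencies()
  ref[!ref$censored_aadop2, ]
}
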