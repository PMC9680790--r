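#' Default ATP concentration grid
#'
#' Five logarithmically spaced concentrations spanning 0.05-5 mM, the
#' physiologically interesting range for CFTR gating.
#'
#' @param from,to endpoints in molar.
#' @param length.out number of grid points.
#' @return Numeric vector of molar concentrations.
#' @export
atp_grid <- function(from = 5e-5, to = 5e-3, length.out = 5) {
  10^seq(log10(from), log10(to), length.out = length.out)
}

# per-(condition, run) seeds derived from one user seed, all below 2^31
run_seed <- function(seed, i) (as.numeric(seed) + 7919 * i) %% 2147483647

#' Prevalence of nonpermissive closings across ATP concentrations
#'
#' For each concentration and run, simulates a ground-truth state sequence (no
#' noise, no inference), extracts and classifies all complete closings, and
#' reports closing rates. The ratio of nonpermissive to total closings is
#' nearly independent of ATP concentration: concentration only stretches the
#' dwell in C1a between openings, not the branching at the open/closed
#' boundary.
#'
#' @param scheme a [kinetic_scheme()]; default [cftr_scheme()].
#' @param atp vector of ATP concentrations (molar).
#' @param dt sampling interval, seconds (default 0.01 s = 100 Hz).
#' @param n samples per run.
#' @param runs simulation runs per concentration.
#' @param seed integer seed; the whole table is reproducible from it.
#' @return Data frame, one row per (atp, run): closing counts, rates per
#'   second, and the nonpermissive/total ratio.
#' @export
sweep_prevalence <- function(scheme = cftr_scheme(), atp = atp_grid(),
                             dt = 0.01, n = 1e6, runs = 10, seed = 1) {
  stopifnot(length(atp) >= 1)
  rows <- list()
  idx <- 0L
  for (a in atp) {
    Q <- discretize(rate_matrix(scheme, a), dt)
    for (r in seq_len(runs)) {
      idx <- idx + 1L
      s <- sample_states(Q, n, seed = run_seed(seed, idx))
      ev <- extract_closings(s, scheme)
      np <- sum(ev$label == "nonpermissive")
      secs <- n * dt
      rows[[idx]] <- data.frame(
        atp = a, run = r, seed = run_seed(seed, idx), n = n, dt = dt,
        n_closings = nrow(ev), n_nonpermissive = np,
        closing_rate = nrow(ev) / secs, nonpermissive_rate = np / secs,
        ratio = if (nrow(ev) > 0) np / nrow(ev) else NaN
      )
    }
  }
  do.call(rbind, rows)
}

#' Detection error rates across ATP concentrations and thresholds
#'
#' The full simulated benchmark: for each concentration and run, simulate a
#' noisy trace, fit the gating model by EM (amplitude held at the true value;
#' noise variance and the transition matrix estimated from scratch), compute
#' posteriors under the fitted parameters, take confidence-thresholded MAP
#' states, extract and classify closings, and score them against the
#' ground-truth closings. One row is emitted per (atp, run, threshold).
#'
#' @param scheme a [kinetic_scheme()]; default [cftr_scheme()].
#' @param atp vector of ATP concentrations (molar).
#' @param dt sampling interval, seconds.
#' @param n samples per trace.
#' @param sigma2 simulation noise variance.
#' @param amplitude simulation (and fixed fitting) amplitude.
#' @param iterations EM iterations per fit.
#' @param thresholds confidence thresholds C to evaluate.
#' @param runs runs per concentration.
#' @param seed integer seed.
#' @param estimate_amplitude also estimate A during fitting (off in benchmark
#'   mode, where A is held at the simulation truth).
#' @return Data frame with columns `atp`, `run`, `threshold`, the detection
#'   counts, `P_FA`, `P_MD`, definedness flags and the fitted `sigma2_hat`.
#' @export
sweep_detection <- function(scheme = cftr_scheme(), atp = atp_grid(),
                            dt = 0.01, n = 20000, sigma2 = 0.02,
                            amplitude = 1, iterations = 400,
                            thresholds = c(0, 0.8), runs = 2, seed = 1,
                            estimate_amplitude = FALSE) {
  stopifnot(length(atp) >= 1)
  rows <- list()
  idx <- 0L; cond <- 0L
  for (a in atp) {
    for (r in seq_len(runs)) {
      cond <- cond + 1L
      rs <- run_seed(seed, cond)
      sim <- simulate_trace(scheme, atp = a, dt = dt, n = n,
                            amplitude = amplitude, sigma2 = sigma2,
                            seed = rs)
      fit <- cftr_fit(sim$trace, scheme, iterations = iterations,
                      estimate_amplitude = estimate_amplitude,
                      amplitude = amplitude, seed = rs)
      gt <- extract_closings(sim$states, scheme)
      est <- map_threshold(fit$posterior, 0)
      for (C in thresholds) {
        ev <- extract_closings(est, scheme, threshold = C)
        met <- score_closings(gt, ev, confident_only = TRUE)
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          atp = a, run = r, threshold = C, seed = rs, n = n, dt = dt,
          sigma2 = sigma2, amplitude = amplitude, iterations = iterations,
          n_FA = met$n_FA, n_MD = met$n_MD,
          n_est_np = met$n_est_np, n_gt_np = met$n_gt_np,
          n_est_total = met$n_est_total, n_gt_total = met$n_gt_total,
          P_FA = met$P_FA, P_MD = met$P_MD,
          P_FA_defined = met$P_FA_defined, P_MD_defined = met$P_MD_defined,
          sigma2_hat = fit$sigma2, amplitude_hat = fit$amplitude
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Quick plot of a sweep table
#'
#' Plots per-run points and per-concentration means of one column of a sweep
#' table against ATP concentration (log axis).
#'
#' @param table a data frame from [sweep_prevalence()] or [sweep_detection()].
#' @param column column to plot.
#' @param ... passed to [plot()].
#' @export
plot_sweep <- function(table, column = "ratio", ...) {
  stopifnot(column %in% names(table))
  v <- table[[column]]
  ok <- is.finite(v)
  plot(table$atp[ok], v[ok], log = "x", xlab = "[ATP] (M)", ylab = column,
       col = "grey50", ...)
  mu <- tapply(v[ok], table$atp[ok], mean)
  lines(as.numeric(names(mu)), mu, type = "b", pch = 19)
  invisible(table)
}
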