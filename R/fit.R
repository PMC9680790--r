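#' Initialize EM from a two-level split of the trace
#'
#' Splits the samples at the midpoint of their range into a lower (closed) and
#' upper (open) cluster. The initial amplitude is the difference of cluster
#' means, the initial noise variance the pooled within-cluster variance, and
#' the initial transition matrix puts probability `0.05 * (1 + u)`,
#' `u ~ Uniform(-0.5, 0.5)`, on every allowed off-diagonal transition, with
#' the self-transition absorbing the remainder. A trace with no discernible
#' openings — the split separates the cluster means by less than three pooled
#' within-cluster standard deviations, which is what a single noisy level
#' produces — is rejected.
#'
#' @param trace a [cftr_trace()].
#' @param scheme the [kinetic_scheme()] whose edges form the topology mask.
#' @param seed optional integer seed for the initialization jitter.
#' @param min_sigma2 floor on the noise variance estimate.
#' @return List with `Q0` (transition matrix), `amplitude0`, `sigma20`,
#'   `baseline0` (lower-cluster mean) and `init0` (stationary distribution of
#'   `Q0`).
#' @export
em_initialize <- function(trace, scheme, seed = NULL, min_sigma2 = 1e-8) {
  stopifnot(inherits(trace, "cftr_trace"), inherits(scheme, "kinetic_scheme"))
  y <- trace$current
  if (length(y) < 2L) stop("need at least two samples to initialize")
  mid <- (min(y) + max(y)) / 2
  lo <- y[y <= mid]; hi <- y[y > mid]
  if (length(hi) == 0L || length(lo) == 0L)
    stop("no openings detected: trace does not separate into two levels")
  amplitude0 <- mean(hi) - mean(lo)
  pooled <- (sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) / length(y)
  sigma20 <- max(pooled, min_sigma2)
  # a single Gaussian level split at its midpoint yields a mean separation of
  # ~2.65 within-cluster sds regardless of the variance; a genuine two-level
  # signal separates much more
  if (amplitude0 < 3 * sqrt(pooled))
    stop("no openings detected: level separation is below the noise resolution")

  S <- length(scheme$states)
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(FALSE, S, S, dimnames = list(scheme$states, scheme$states))
  mask[cbind(match(scheme$edges$from, scheme$states),
             match(scheme$edges$to, scheme$states))] <- TRUE
  Q0 <- matrix(0, S, S, dimnames = dimnames(mask))
  ne <- sum(mask)
  Q0[mask] <- 0.05 * (1 + runif(ne, -0.5, 0.5))
  diag(Q0) <- 0
  diag(Q0) <- 1 - rowSums(Q0)
  if (any(diag(Q0) <= 0)) {  # very high out-degree schemes: renormalize rows
    Q0 <- Q0 / rowSums(Q0)
  }
  Q0 <- structure(Q0, class = c("transition_matrix", "matrix"),
                  dt = trace$dt)
  list(Q0 = Q0, amplitude0 = amplitude0, sigma20 = sigma20,
       baseline0 = mean(lo), init0 = stationary_distribution(Q0))
}

#' Fit the hidden gating model to a patch-clamp trace by EM
#'
#' Estimates the discrete-time transition matrix Q, the noise variance, and
#' optionally the open-channel amplitude from an observed current trace by
#' expectation-maximization on the chain factor graph. Each iteration runs a
#' sum-product E-step ([forward_backward()]) and closed-form M-steps:
#'
#' * `Q[i, j] <- sum_k xi[k, i, j] / sum_k gamma[k, i]`, masked to the scheme
#'   edges plus self-transitions and row-renormalized. The topology mask is a
#'   hard constraint — it is what makes the electrically identical closed
#'   states identifiable — and off-topology entries are exactly zero after
#'   every iteration.
#' * `sigma2 <- sum_k sum_i gamma[k, i] (y_k - A m(i))^2 / n`, floored at
#'   `min_sigma2`.
#' * if `estimate_amplitude`, `A <-` posterior-weighted mean of the samples
#'   attributed to open states.
#'
#' A fixed number of iterations is run rather than a convergence tolerance
#' (an optional `early_stop_tol` on the relative log-likelihood change is
#' available but off by default). The initial distribution of each E-step is
#' the stationary distribution of the current Q, matching a channel observed
#' in steady state.
#'
#' @param trace a [cftr_trace()].
#' @param scheme the [kinetic_scheme()]; default [cftr_scheme()].
#' @param iterations number of EM iterations (default 400).
#' @param estimate_amplitude estimate A (`TRUE`, default, for real
#'   recordings) or hold it fixed at `amplitude` (benchmark mode).
#' @param amplitude fixed amplitude when `estimate_amplitude = FALSE`;
#'   defaults to the trace's stored amplitude.
#' @param seed integer seed for the initialization jitter.
#' @param min_sigma2 floor on the variance estimate (guards the likelihood
#'   against collapse on noiseless signals).
#' @param Q0 optional starting transition matrix overriding the random
#'   initialization.
#' @param early_stop_tol optional relative log-likelihood improvement below
#'   which iteration stops early; `NULL` (default) runs all iterations.
#' @param verbose print the log-likelihood every 50 iterations.
#' @return An object of class `"cftr_fit"`; see [predict.cftr_fit()],
#'   [coef.cftr_fit()], [closings()].
#' @export
#' @examples
#' sim <- simulate_trace(atp = 5e-4, dt = 0.01, n = 4000, seed = 2)
#' fit <- cftr_fit(sim$trace, iterations = 50, estimate_amplitude = FALSE,
#'                 seed = 2)
#' fit
cftr_fit <- function(trace, scheme = cftr_scheme(), iterations = 400,
                     estimate_amplitude = TRUE, amplitude = NULL, seed = NULL,
                     min_sigma2 = 1e-8, Q0 = NULL, early_stop_tol = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(trace, "cftr_trace"), inherits(scheme, "kinetic_scheme"))
  if (iterations < 1) stop("`iterations` must be at least 1")
  y <- trace$current
  n <- length(y)
  S <- length(scheme$states)

  ini <- em_initialize(trace, scheme, seed = seed, min_sigma2 = min_sigma2)
  Q <- if (is.null(Q0)) unclass(ini$Q0) else {
    Q0m <- unclass(Q0)
    if (!identical(rownames(Q0m), scheme$states))
      stop("`Q0` state order must match the scheme")
    Q0m
  }
  A <- if (estimate_amplitude) ini$amplitude0 else {
    if (is.null(amplitude)) amplitude <- trace$amplitude
    if (!is.finite(amplitude))
      stop("`estimate_amplitude = FALSE` needs a fixed `amplitude`")
    amplitude
  }
  sigma2 <- max(ini$sigma20, min_sigma2)

  mask <- matrix(FALSE, S, S)
  mask[cbind(match(scheme$edges$from, scheme$states),
             match(scheme$edges$to, scheme$states))] <- TRUE
  diag(mask) <- TRUE

  m_open <- scheme$conductance == 1
  loglik <- numeric(0)
  warned_empty <- FALSE

  for (it in seq_len(iterations)) {
    init <- stationary_distribution(Q)
    B <- emission_likelihoods(y, scheme, A, sigma2)
    e <- fb_core(B, Q, init, keep_messages = FALSE)
    loglik <- c(loglik, e$loglik)
    if (verbose && (it == 1L || it %% 50L == 0L))
      message(sprintf("iteration %d: log-likelihood %.6f", it, e$loglik))

    gamma <- e$gamma
    xi <- e$xi_sum
    xi[!mask] <- 0
    denom <- rowSums(xi)
    Qnew <- Q
    ok <- denom > 0
    if (any(!ok) && !warned_empty) {
      warning("state(s) with zero expected occupancy: ",
              paste(scheme$states[!ok], collapse = ", "),
              "; their transition rows were kept at previous values")
      warned_empty <- TRUE
    }
    Qnew[ok, ] <- xi[ok, , drop = FALSE] / denom[ok]
    Q <- Qnew

    # expected squared residual; states in a class share a level, so only the
    # posterior open-class mass enters
    p_open <- rowSums(gamma[, m_open, drop = FALSE])
    sigma2 <- sum(y^2 * (1 - p_open) + (y - A)^2 * p_open) / n
    sigma2 <- max(sigma2, min_sigma2)

    if (estimate_amplitude) {
      w <- sum(p_open)
      if (w > 0) A <- sum(p_open * y) / w
    }

    if (!is.null(early_stop_tol) && it > 1L) {
      rel <- (loglik[it] - loglik[it - 1L]) / max(abs(loglik[it - 1L]), 1)
      if (abs(rel) < early_stop_tol) break
    }
  }

  Qfit <- structure(Q, class = c("transition_matrix", "matrix"),
                    dt = trace$dt,
                    dimnames = list(scheme$states, scheme$states))
  post <- forward_backward(trace, Qfit, scheme, amplitude = A,
                           sigma2 = sigma2)
  structure(list(Q = Qfit, sigma2 = sigma2, amplitude = A,
                 init = post$init, loglik = loglik, posterior = post,
                 scheme = scheme, trace = trace,
                 iterations = length(loglik),
                 estimate_amplitude = estimate_amplitude,
                 min_sigma2 = min_sigma2, seed = seed,
                 call = match.call()),
            class = "cftr_fit")
}

#' @export
print.cftr_fit <- function(x, ...) {
  cat("Hidden-Markov gating model fit (factor-graph EM)\n")
  cat(sprintf("  %d samples at dt = %g s, %d EM iterations\n",
              length(x$trace$current), x$trace$dt, x$iterations))
  cat(sprintf("  amplitude = %.4f%s, noise variance = %.5f\n", x$amplitude,
              if (x$estimate_amplitude) " (estimated)" else " (fixed)",
              x$sigma2))
  cat(sprintf("  final log-likelihood: %.4f\n",
              x$posterior$log_likelihood))
  invisible(x)
}

#' @export
summary.cftr_fit <- function(object, ...) {
  occ <- colMeans(object$posterior$marginals)
  out <- list(fit = object, occupancy = occ,
              Q = unclass(object$Q),
              loglik_first = object$loglik[1],
              loglik_last = object$posterior$log_likelihood)
  class(out) <- "summary.cftr_fit"
  out
}

#' @export
print.summary.cftr_fit <- function(x, ...) {
  print(x$fit)
  cat("\nEstimated transition matrix (per sampling interval):\n")
  print(round(x$Q, 4))
  cat("\nPosterior mean state occupancy:\n")
  print(round(x$occupancy, 4))
  cat(sprintf("\nLog-likelihood: %.4f (first iteration) -> %.4f (final)\n",
              x$loglik_first, x$loglik_last))
  invisible(x)
}

#' Extract estimated parameters from a gating-model fit
#'
#' @param object a [cftr_fit()] object.
#' @param ... unused.
#' @return List with `transition` (the estimated Q), `sigma2` and `amplitude`.
#' @export
coef.cftr_fit <- function(object, ...) {
  list(transition = object$Q, sigma2 = object$sigma2,
       amplitude = object$amplitude)
}

#' @export
logLik.cftr_fit <- function(object, ...) {
  df <- nrow(object$scheme$edges) + 1L + as.integer(object$estimate_amplitude)
  structure(object$posterior$log_likelihood, df = df,
            nobs = length(object$trace$current), class = "logLik")
}

#' Posterior marginals or thresholded MAP states from a fit
#'
#' @param object a [cftr_fit()].
#' @param type `"posterior"` returns the n x S marginal matrix; `"map"`
#'   returns the confidence-thresholded MAP state estimates (see
#'   [map_threshold()]).
#' @param threshold confidence threshold C in `[0, 1)` for `type = "map"`.
#' @param ... unused.
#' @export
predict.cftr_fit <- function(object, type = c("posterior", "map"),
                             threshold = 0, ...) {
  type <- match.arg(type)
  if (type == "posterior") return(object$posterior$marginals)
  map_threshold(object$posterior, threshold)
}

#' @export
fitted.cftr_fit <- function(object, ...) {
  map <- map_threshold(object$posterior, 0)
  object$amplitude *
    as.numeric(object$scheme$conductance[map$map_state])
}

#' @export
residuals.cftr_fit <- function(object, ...) {
  object$trace$current - fitted(object)
}

#' Simulate new traces from a fitted gating model
#'
#' Draws state sequences from the estimated transition matrix (starting from
#' its stationary distribution) and currents from the estimated emission
#' model.
#'
#' @param object a [cftr_fit()].
#' @param nsim number of traces.
#' @param seed optional integer seed.
#' @param n samples per trace; defaults to the length of the fitted trace.
#' @param ... unused.
#' @return A list of `nsim` elements, each with `states` and `trace`.
#' @export
simulate.cftr_fit <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  if (is.null(n)) n <- length(object$trace$current)
  seeds <- if (is.null(seed)) rep(list(NULL), 2 * nsim)
           else as.list(derive_seeds(seed, 2 * nsim))
  out <- vector("list", nsim)
  for (i in seq_len(nsim)) {
    st <- sample_states(object$Q, n, init = object$init,
                        seed = seeds[[2 * i - 1]])
    tr <- emit_current(st, object$scheme, amplitude = object$amplitude,
                       sigma2 = object$sigma2, seed = seeds[[2 * i]])
    out[[i]] <- list(states = st, trace = tr)
  }
  if (nsim == 1L) out[[1]] else out
}

#' Diagnostic plots for a gating-model fit
#'
#' `which = 1` plots the EM log-likelihood trajectory; `which = 2` overlays
#' the fitted two-level signal (amplitude times the MAP conductance class) on
#' the observed trace.
#'
#' @param x a [cftr_fit()].
#' @param which which plot (1 or 2).
#' @param ... passed to [plot()].
#' @export
plot.cftr_fit <- function(x, which = 1, ...) {
  if (which == 1) {
    plot(seq_along(x$loglik), x$loglik, type = "l",
         xlab = "EM iteration", ylab = "log-likelihood", ...)
  } else {
    tt <- seq_along(x$trace$current) * x$trace$dt
    plot(tt, x$trace$current, type = "l", col = "grey60",
         xlab = "time (s)", ylab = "current", ...)
    lines(tt, fitted(x), col = "red", lwd = 1.5)
  }
  invisible(x)
}
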