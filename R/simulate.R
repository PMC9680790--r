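#' Construct a patch-clamp trace object
#'
#' A trace is the sampled current signal together with its sampling interval
#' and, when known, the emission parameters (open-channel amplitude and noise
#' variance) that generated or describe it.
#'
#' @param current numeric vector of current samples.
#' @param dt sampling interval, seconds.
#' @param amplitude open-channel current amplitude (same units as `current`);
#'   `NA` if unknown.
#' @param sigma2 Gaussian noise variance; `NA` if unknown.
#' @return An object of class `"cftr_trace"`.
#' @export
cftr_trace <- function(current, dt, amplitude = NA_real_, sigma2 = NA_real_) {
  current <- as.numeric(current)
  if (length(current) < 1L) stop("a trace needs at least one sample")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive sampling interval in seconds")
  structure(list(current = current, dt = dt,
                 amplitude = amplitude, sigma2 = sigma2),
            class = "cftr_trace")
}

#' @export
print.cftr_trace <- function(x, ...) {
  cat(sprintf("Patch-clamp trace: %d samples, dt = %g s (%.4g s total)\n",
              length(x$current), x$dt, length(x$current) * x$dt))
  if (is.finite(x$amplitude) || is.finite(x$sigma2))
    cat(sprintf("  emission: amplitude = %g, noise variance = %g\n",
                x$amplitude, x$sigma2))
  invisible(x)
}

# deterministic sub-stream seeds so that the state sequence produced by a
# given seed does not depend on whether noise is also drawn
derive_seeds <- function(seed, k) {
  (as.numeric(seed) + 1013904223 * (seq_len(k) - 1)) %% 2147483647
}

#' Simulate a hidden state sequence
#'
#' Draws a discrete-time Markov chain of length `n` from a transition matrix:
#' the first state from `init`, each subsequent state from the row of `Q`
#' indexed by its predecessor.
#'
#' @param Q a [discretize()]d transition matrix with state names.
#' @param n number of samples.
#' @param init initial distribution; defaults to [stationary_distribution()]
#'   of `Q` (a channel observed in steady state).
#' @param seed optional integer seed; the same seed reproduces the sequence.
#' @return An object of class `"state_sequence"`: list with `states`
#'   (character vector) and `dt`.
#' @export
sample_states <- function(Q, n, init = NULL, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive count")
  if (is.null(init)) init <- stationary_distribution(Q)
  Qm <- unclass(Q)
  if (length(init) != nrow(Qm) || any(init < 0) || abs(sum(init) - 1) > 1e-9)
    stop("`init` must be a probability distribution over the states of `Q`")
  if (!is.null(seed)) set.seed(seed)
  idx <- sample_states_cpp(Qm, as.integer(n), as.numeric(init))
  structure(list(states = rownames(Qm)[idx], dt = attr(Q, "dt")),
            class = "state_sequence")
}

#' @export
print.state_sequence <- function(x, ...) {
  cat(sprintf("State sequence: %d samples%s\n", length(x$states),
              if (!is.null(x$dt)) sprintf(", dt = %g s", x$dt) else ""))
  tab <- table(x$states)
  cat("  occupancy:", paste(sprintf("%s %.3f", names(tab),
                                    as.numeric(tab) / length(x$states)),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Emit a noisy current trace from a state sequence
#'
#' Applies the emission model y_k = A m(s_k) + n_k with n_k i.i.d. Gaussian,
#' zero mean, variance `sigma2`, where m() is the scheme's conductance map.
#'
#' @param states a `"state_sequence"`.
#' @param scheme the [kinetic_scheme()] providing the conductance map.
#' @param amplitude open-channel amplitude A.
#' @param sigma2 noise variance (0 gives a noiseless two-level signal).
#' @param seed optional integer seed for the noise.
#' @return A [cftr_trace()].
#' @export
emit_current <- function(states, scheme, amplitude = 1, sigma2 = 0.02,
                         seed = NULL) {
  stopifnot(inherits(states, "state_sequence"),
            inherits(scheme, "kinetic_scheme"))
  if (sigma2 < 0) stop("`sigma2` must be nonnegative")
  m <- scheme$conductance[states$states]
  if (anyNA(m)) stop("state sequence contains labels unknown to the scheme")
  if (!is.null(seed)) set.seed(seed)
  y <- amplitude * as.numeric(m)
  if (sigma2 > 0) y <- y + rnorm(length(y), 0, sqrt(sigma2))
  cftr_trace(y, states$dt, amplitude = amplitude, sigma2 = sigma2)
}

#' Simulate a complete patch-clamp experiment
#'
#' Composes the kinetics and emission models: builds the rate matrix at the
#' given ATP concentration, discretizes at `dt`, draws a hidden state sequence
#' from the stationary distribution, and adds Gaussian noise. One user seed
#' drives two independent sub-streams (states, noise), so the state sequence
#' for a given seed is the same whether or not noise is generated.
#'
#' @param scheme a [kinetic_scheme()]; default [cftr_scheme()].
#' @param atp ATP concentration, molar.
#' @param dt sampling interval, seconds.
#' @param n number of samples.
#' @param amplitude open-channel amplitude A.
#' @param sigma2 Gaussian noise variance.
#' @param seed optional integer seed.
#' @param init optional initial distribution (defaults to stationary).
#' @return List with elements `states` (ground-truth `"state_sequence"`),
#'   `trace` (the [cftr_trace()]) and `Q` (the transition matrix used).
#' @export
#' @examples
#' sim <- simulate_trace(atp = 5e-4, dt = 0.01, n = 2000, seed = 1)
#' sim$trace
simulate_trace <- function(scheme = cftr_scheme(), atp, dt, n, amplitude = 1,
                           sigma2 = 0.02, seed = NULL, init = NULL) {
  R <- rate_matrix(scheme, atp)
  Q <- discretize(R, dt)
  seeds <- if (is.null(seed)) c(NULL, NULL) else derive_seeds(seed, 2)
  states <- sample_states(Q, n, init = init, seed = seeds[1])
  trace <- emit_current(states, scheme, amplitude = amplitude,
                        sigma2 = sigma2, seed = seeds[2])
  list(states = states, trace = trace, Q = Q)
}
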