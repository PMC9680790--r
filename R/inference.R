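# Per-sample emission likelihoods, n x S. States sharing a conductance class
# share a density (aggregated HMM), so the two class densities are computed
# once and mapped onto states.
emission_likelihoods <- function(y, scheme, amplitude, sigma2) {
  sdv <- sqrt(sigma2)
  d <- cbind(dnorm(y, 0, sdv), dnorm(y, amplitude, sdv))
  d[, scheme$conductance + 1L, drop = FALSE]
}

#' Exact posterior state marginals by sum-product (forward-backward)
#'
#' Runs the scaled forward-backward algorithm — the sum-product algorithm on
#' the chain factor graph of the hidden Markov model — and returns the exact
#' per-sample posterior marginals p(s_k | y) together with the data
#' log-likelihood. Emission densities are Gaussian, N(A m(s), sigma2), with
#' all states in a conductance class sharing one density. Messages are
#' renormalized at every step, so traces of up to a million samples run
#' without underflow; the accumulated log normalizers give log p(y).
#'
#' @param trace a [cftr_trace()] (or bare numeric vector of samples).
#' @param Q transition probability matrix with state names.
#' @param scheme the [kinetic_scheme()] (conductance map).
#' @param amplitude,sigma2 emission parameters; default to the values stored
#'   in the trace. `sigma2` must be strictly positive.
#' @param init initial distribution; defaults to the stationary distribution
#'   of `Q`.
#' @param pairwise if `TRUE`, also return the full pairwise posterior array
#'   `xi` with `xi[k, i, j] = Pr(s_k = i, s_{k+1} = j | y)` (memory grows as
#'   `n * S^2`; intended for short sequences and diagnostics).
#' @return An object of class `"cftr_posterior"`: list with `marginals`
#'   (n x S matrix, state-named columns, rows summing to 1),
#'   `log_likelihood`, `xi_sum` (pairwise posterior summed over time), `init`,
#'   and `xi` when requested.
#' @export
forward_backward <- function(trace, Q, scheme, amplitude = NULL,
                             sigma2 = NULL, init = NULL, pairwise = FALSE) {
  y <- if (inherits(trace, "cftr_trace")) trace$current else as.numeric(trace)
  if (length(y) < 1L) stop("empty trace")
  if (anyNA(y) || any(!is.finite(y)))
    stop("trace contains missing or non-finite samples")
  if (is.null(amplitude))
    amplitude <- if (inherits(trace, "cftr_trace")) trace$amplitude else NA
  if (is.null(sigma2))
    sigma2 <- if (inherits(trace, "cftr_trace")) trace$sigma2 else NA
  if (!is.finite(amplitude)) stop("`amplitude` is required (not stored in trace)")
  if (!is.finite(sigma2) || sigma2 <= 0)
    stop("`sigma2` must be strictly positive (a zero-noise likelihood is ",
         "degenerate off the two levels)")
  Qm <- unclass(Q)
  if (is.null(rownames(Qm))) stop("`Q` must carry state names")
  if (!identical(rownames(Qm), scheme$states))
    stop("`Q` state order does not match the scheme")
  if (is.null(init)) init <- stationary_distribution(Q)

  B <- emission_likelihoods(y, scheme, amplitude, sigma2)
  res <- fb_core(B, Qm, as.numeric(init), keep_messages = isTRUE(pairwise))
  marg <- res$gamma
  colnames(marg) <- scheme$states
  xi_sum <- res$xi_sum
  dimnames(xi_sum) <- list(scheme$states, scheme$states)
  out <- list(marginals = marg, log_likelihood = res$loglik, xi_sum = xi_sum,
              init = init)
  if (isTRUE(pairwise)) {
    n <- length(y); S <- ncol(B)
    xi <- array(0, dim = c(max(n - 1L, 0L), S, S),
                dimnames = list(NULL, scheme$states, scheme$states))
    if (n > 1) {
      cc <- exp(res$logc)
      for (k in seq_len(n - 1L)) {
        xi[k, , ] <- (res$alpha[k, ] %o% (B[k + 1L, ] * res$beta[k + 1L, ])) *
          Qm / cc[k + 1L]
      }
    }
    out$xi <- xi
  }
  structure(out, class = "cftr_posterior")
}

#' @export
print.cftr_posterior <- function(x, ...) {
  cat(sprintf("Posterior marginals: %d samples x %d states, log-likelihood %.4f\n",
              nrow(x$marginals), ncol(x$marginals), x$log_likelihood))
  invisible(x)
}

#' Log-likelihood of a trace under given parameters
#'
#' Convenience wrapper around [forward_backward()] returning only log p(y).
#'
#' @inheritParams forward_backward
#' @return Scalar natural-log likelihood.
#' @export
log_likelihood <- function(trace, Q, scheme, amplitude = NULL, sigma2 = NULL,
                           init = NULL) {
  forward_backward(trace, Q, scheme, amplitude = amplitude, sigma2 = sigma2,
                   init = init)$log_likelihood
}
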