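#' Block-averaging decimation
#'
#' Reduces the sampling rate by a factor by averaging nonoverlapping blocks of
#' `factor` consecutive samples; a trailing partial block is discarded. Raw
#' patch-clamp signals are oversampled relative to the channel kinetics, and
#' block averaging suppresses high-frequency noise (white-noise variance drops
#' by the factor) while preserving the slower gating transitions. It also
#' makes a Gaussian noise model reasonable for the decimated signal via the
#' central limit theorem.
#'
#' @param x a [cftr_trace()] or a bare numeric vector.
#' @param factor block length (>= 1); a 2 kHz recording decimated by 50 gives
#'   a 40 Hz trace.
#' @param rate optional sampling rate in Hz when `x` is a bare vector; the
#'   result is then a [cftr_trace()] with `dt = factor / rate`.
#' @return Same shape as the input: a trace for a trace (with `dt` scaled by
#'   `factor`), a numeric vector for a vector (unless `rate` is given).
#' @export
#' @examples
#' decimate(rep(c(0, 1), each = 50), 50)  # c(0, 1)
decimate <- function(x, factor, rate = NULL) {
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("`factor` must be a positive integer")
  factor <- as.integer(factor)
  is_trace <- inherits(x, "cftr_trace")
  y <- if (is_trace) x$current else as.numeric(x)
  n <- length(y)
  if (factor > n) stop("decimation factor exceeds the trace length")
  m <- n %/% factor
  out <- colMeans(matrix(y[seq_len(m * factor)], nrow = factor))
  if (is_trace)
    return(cftr_trace(out, dt = x$dt * factor, amplitude = x$amplitude,
                      sigma2 = if (is.finite(x$sigma2)) x$sigma2 / factor
                               else NA_real_))
  if (!is.null(rate)) return(cftr_trace(out, dt = factor / rate))
  out
}

#' Normalize polarity and baseline of a raw recording
#'
#' Recordings at negative holding potentials have negative-going openings,
#' while the emission model assumes a closed level of 0 and an open level of
#' +A. This flips the polarity if needed and subtracts the closed-level
#' baseline, estimated as the median of the samples on the closed side of the
#' min/max midpoint (robust to open/closed imbalance).
#'
#' Polarity `"auto"` takes the majority level as closed — single-channel
#' recordings spend most samples closed or have clear shoulders; when that
#' assumption fails, state the polarity explicitly (`"up"`: openings already
#' positive-going; `"down"`: openings negative-going).
#'
#' A trace without two discernible levels is returned unchanged with a
#' warning.
#'
#' @param x a [cftr_trace()] or numeric vector.
#' @param polarity `"auto"`, `"up"` or `"down"`.
#' @return Same shape as the input, normalized so the closed level is ~0 and
#'   openings are positive deflections.
#' @export
normalize_trace <- function(x, polarity = c("auto", "up", "down")) {
  polarity <- match.arg(polarity)
  is_trace <- inherits(x, "cftr_trace")
  y <- if (is_trace) x$current else as.numeric(x)
  rng <- range(y)
  if (diff(rng) == 0) {
    warning("trace does not separate into two levels; returned unchanged")
    return(x)
  }
  mid <- mean(rng)
  lo <- y <= mid
  mlo <- mean(y[lo]); mhi <- mean(y[!lo])
  pooled_sd <- sqrt(mean((y - ifelse(lo, mlo, mhi))^2))
  # a single Gaussian level split at its midpoint separates by ~2.65 pooled
  # sds; genuine two-level signals separate far more
  if (!any(!lo) || abs(mhi - mlo) < 3 * pooled_sd) {
    warning("trace does not separate into two levels; returned unchanged")
    return(x)
  }
  flip <- switch(polarity,
    up = FALSE,
    down = TRUE,
    auto = sum(!lo) > sum(lo)  # majority level is the closed baseline
  )
  if (flip) y <- -y
  mid2 <- mean(range(y))
  baseline <- median(y[y <= mid2])
  y <- y - baseline
  if (is_trace) cftr_trace(y, x$dt, amplitude = x$amplitude,
                           sigma2 = x$sigma2)
  else y
}
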