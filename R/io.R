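#' Read and write patch-clamp traces as CSV
#'
#' The interchange format is a CSV with a `current` column and an optional
#' `time_s` column. On read, the sampling interval is taken (in this order)
#' from the `dt` argument, from `1 / rate`, or from the spacing of the
#' `time_s` column; it is an error if none is available. Ragged rows are
#' reported with their line number.
#'
#' @param path file path.
#' @param dt sampling interval in seconds, if known.
#' @param rate sampling rate in Hz, alternative to `dt`.
#' @return `read_trace()` returns a [cftr_trace()]; `write_trace()` returns
#'   `path` invisibly after writing `time_s,current` rows.
#' @export
read_trace <- function(path, dt = NULL, rate = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  nf <- count.fields(path, sep = ",")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged row in ", path, " at line ", bad,
         " (", nf[bad], " fields, expected ", nf[1], ")")
  }
  df <- read.csv(path)
  if (!"current" %in% names(df))
    stop("trace file needs a `current` column: ", path)
  if (!is.numeric(df$current)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(df$current)))))[1]
    stop("non-numeric current value in ", path, " at data line ", bad)
  }
  if (anyNA(df$current))
    stop("missing current value in ", path, " at data line ",
         which(is.na(df$current))[1])
  if (is.null(dt) && !is.null(rate)) dt <- 1 / rate
  if (is.null(dt)) {
    if (!"time_s" %in% names(df))
      stop("sampling interval unknown: provide `dt` or `rate`, or include ",
           "a `time_s` column")
    if (nrow(df) < 2L) stop("cannot infer `dt` from a single sample")
    steps <- diff(df$time_s)
    if (any(steps <= 0) || diff(range(steps)) > 1e-6 * median(steps))
      stop("`time_s` column is not uniformly spaced; pass `dt` explicitly")
    dt <- median(steps)
  }
  cftr_trace(df$current, dt)
}

#' @rdname read_trace
#' @param trace a [cftr_trace()] to write.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cftr_trace"))
  df <- data.frame(time_s = seq_along(trace$current) * trace$dt,
                   current = trace$current)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# truth CSV: time_s,state
write_states <- function(states, path) {
  stopifnot(inherits(states, "state_sequence"))
  dt <- if (is.null(states$dt)) NA_real_ else states$dt
  df <- data.frame(time_s = seq_along(states$states) * dt,
                   state = states$states)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_states <- function(path, dt = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"state" %in% names(df)) stop("truth file needs a `state` column")
  if (is.null(dt) && "time_s" %in% names(df) && nrow(df) > 1L)
    dt <- median(diff(df$time_s))
  structure(list(states = as.character(df$state), dt = dt),
            class = "state_sequence")
}

#' Read and write fitted parameters as JSON
#'
#' Serializes a labeled transition matrix together with the emission
#' parameters and sampling interval, either from a [cftr_fit()] or from a
#' plain list with fields `states`, `Q`, `sigma2`, `amplitude`, `dt`.
#'
#' @param x a [cftr_fit()] or parameter list.
#' @param path file path.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   a list with `states`, `Q` (named matrix), `sigma2`, `amplitude`, `dt`.
#' @export
write_params <- function(x, path) {
  if (inherits(x, "cftr_fit"))
    x <- list(states = x$scheme$states, Q = unclass(x$Q), sigma2 = x$sigma2,
              amplitude = x$amplitude, dt = x$trace$dt)
  obj <- list(states = x$states, Q = unname(as.matrix(x$Q)),
              sigma2 = x$sigma2, amplitude = x$amplitude, dt = x$dt)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  Q <- as.matrix(obj$Q)
  dimnames(Q) <- list(obj$states, obj$states)
  list(states = obj$states,
       Q = structure(Q, class = c("transition_matrix", "matrix"),
                     dt = obj$dt),
       sigma2 = obj$sigma2, amplitude = obj$amplitude, dt = obj$dt)
}

# events CSV used by the command-line interface
write_events <- function(events, dt, path) {
  df <- data.frame(start_s = events$start * dt, end_s = events$end * dt,
                   initial_state = events$initial_state,
                   final_state = events$final_state,
                   label = events$label, confident = events$confident)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
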