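#' Define a kinetic scheme for an aggregated-Markov ion channel
#'
#' A kinetic scheme lists the channel's conformational microstates, the
#' conductance class each one produces at the patch-clamp amplifier (0 =
#' closed, 1 = open), and the directed transitions that are kinetically
#' allowed, each with a rate constant. Transitions flagged `atp` are
#' ATP-binding steps whose effective rate is the rate constant multiplied by
#' the molar ATP concentration.
#'
#' Several microstates typically share a conductance class, which is what
#' makes them "hidden": the recorded current cannot distinguish them, and the
#' allowed-transition topology is the only information that does.
#'
#' @param states character vector of state labels; the order given here is
#'   the row/column order of every matrix built from the scheme.
#' @param conductance named numeric vector mapping every state label to its
#'   conductance class, 0 (closed) or 1 (open).
#' @param edges data frame with columns `from`, `to` (state labels), `rate`
#'   (strictly positive; units s^-1, or (M s)^-1 for ATP-binding edges) and
#'   `atp` (logical).
#'
#' @return An object of class `"kinetic_scheme"`.
#' @seealso [cftr_scheme()] for the built-in seven-state CFTR scheme,
#'   [rate_matrix()], [read_scheme()].
#' @export
#' @examples
#' sch <- kinetic_scheme(
#'   states = c("C", "O"),
#'   conductance = c(C = 0, O = 1),
#'   edges = data.frame(from = c("C", "O"), to = c("O", "C"),
#'                      rate = c(1, 2), atp = FALSE)
#' )
kinetic_scheme <- function(states, conductance, edges) {
  if (!is.character(states) || length(states) < 1L || anyDuplicated(states))
    stop("`states` must be a character vector of unique labels")
  if (is.null(names(conductance)) || !all(states %in% names(conductance)))
    stop("`conductance` must be named and cover every state")
  conductance <- conductance[states]
  if (!all(conductance %in% c(0, 1)))
    stop("conductance classes must be 0 (closed) or 1 (open)")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("from", "to", "rate", "atp")
  if (!all(need %in% names(edges)))
    stop("`edges` needs columns from, to, rate, atp")
  edges <- edges[need]
  if (!all(edges$from %in% states) || !all(edges$to %in% states))
    stop("edge endpoints must be scheme states")
  if (any(edges$from == edges$to))
    stop("self-transitions are implicit and may not be listed as edges")
  if (anyDuplicated(paste(edges$from, edges$to)))
    stop("duplicate directed edge")
  if (!is.numeric(edges$rate) || any(!is.finite(edges$rate)) || any(edges$rate <= 0))
    stop("all rate constants must be strictly positive and finite")
  edges$atp <- as.logical(edges$atp)
  if (any(is.na(edges$atp)))
    stop("`atp` flags must be TRUE or FALSE")
  structure(list(states = states, conductance = conductance, edges = edges),
            class = "kinetic_scheme")
}

#' The seven-state CFTR gating scheme
#'
#' Builds the default kinetic scheme for the wild-type (high open probability)
#' CFTR chloride channel: five closed states (C1a, C1b, C2, C3, C4) and two
#' open states (O1, O2) connected in a cycle with twelve directed transitions.
#' Two steps are irreversible: O1 -> O2 (ATP hydrolysis) and C4 -> C1a (ADP
#' release), so neither O2 -> O1 nor C1a -> C4 is an allowed edge. The
#' C1a -> C1b step is ATP binding; its rate constant has units (M s)^-1 and is
#' multiplied by the ATP concentration when a rate matrix is built.
#'
#' The irreversible C4 -> C1a step is what makes a closing "nonpermissive":
#' a closing entered from O2 can only reopen as O1 by passing through it,
#' releasing ADP and requiring fresh ATP binding before the next opening.
#'
#' @return A `"kinetic_scheme"` with state order C1a, C1b, C2, O1, O2, C3, C4.
#' @export
#' @examples
#' sch <- cftr_scheme()
#' sch$conductance
cftr_scheme <- function() {
  kinetic_scheme(
    states = c("C1a", "C1b", "C2", "O1", "O2", "C3", "C4"),
    conductance = c(C1a = 0, C1b = 0, C2 = 0, O1 = 1, O2 = 1, C3 = 0, C4 = 0),
    edges = data.frame(
      from = c("C1a", "C1b", "C1b", "C2", "C2", "O1", "O1", "O2", "C3", "C3",
               "C4", "C4"),
      to   = c("C1b", "C1a", "C2", "C1b", "O1", "C2", "O2", "C3", "O2", "C4",
               "C3", "C1a"),
      rate = c(9.0e3, 5.0, 7.7, 5.8, 4.9, 10.0, 7.1, 3.0, 7.0, 6.0, 12.8, 1.7),
      atp  = c(TRUE, rep(FALSE, 11)),
      stringsAsFactors = FALSE
    )
  )
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  op <- x$states[x$conductance == 1]
  cl <- x$states[x$conductance == 0]
  cat("Kinetic scheme:", length(x$states), "states,", nrow(x$edges),
      "directed transitions\n")
  cat("  open   (conductance 1):", paste(op, collapse = ", "), "\n")
  cat("  closed (conductance 0):", paste(cl, collapse = ", "), "\n")
  lab <- sprintf("%s -> %s  %g %s", x$edges$from, x$edges$to, x$edges$rate,
                 ifelse(x$edges$atp, "(M s)^-1 x [ATP]", "s^-1"))
  cat(paste0("  ", lab, collapse = "\n"), "\n")
  invisible(x)
}

#' Continuous-time rate matrix of a scheme at a given ATP concentration
#'
#' Assembles the generator R of the master equation dP/dt = P R: off-diagonal
#' entry (i, j) is the rate constant of edge i -> j (multiplied by `atp` for
#' ATP-binding edges, zero where no edge exists) and each diagonal entry makes
#' its row sum to zero, so probability is conserved.
#'
#' @param scheme a [kinetic_scheme()].
#' @param atp ATP concentration in molar; must be strictly positive.
#' @return A square matrix (class `"rate_matrix"`) in scheme state order,
#'   units s^-1, with the concentration stored in `attr(, "atp")`.
#' @export
#' @examples
#' R <- rate_matrix(cftr_scheme(), atp = 1e-3)
#' R["C1a", "C1b"]  # 9.0e3 * 1e-3 = 9 s^-1
rate_matrix <- function(scheme, atp) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!is.numeric(atp) || length(atp) != 1L || !is.finite(atp) || atp <= 0)
    stop("`atp` must be a single positive molar concentration")
  S <- length(scheme$states)
  R <- matrix(0, S, S, dimnames = list(scheme$states, scheme$states))
  e <- scheme$edges
  eff <- e$rate * ifelse(e$atp, atp, 1)
  R[cbind(match(e$from, scheme$states), match(e$to, scheme$states))] <- eff
  diag(R) <- -rowSums(R)
  structure(R, class = c("rate_matrix", "matrix"), atp = atp)
}

#' Discretize a rate matrix to a transition probability matrix
#'
#' Solves the master equation over one sampling interval: Q = exp(R dt), the
#' matrix exponential of the generator scaled by the sampling time. Q[i, j] is
#' the probability that a channel in state i at one sample is in state j at
#' the next. Rows sum to one; entries between states with no direct edge are
#' nonzero but of order dt^2 (multi-step paths within one interval).
#'
#' @param R a [rate_matrix()].
#' @param dt sampling interval in seconds; must be strictly positive.
#' @return A stochastic matrix of class `"transition_matrix"` with the
#'   interval stored in `attr(, "dt")`.
#' @export
discretize <- function(R, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive sampling interval in seconds")
  Rm <- unclass(R)
  Q <- as.matrix(Matrix::expm(Matrix::Matrix(Rm * dt)))
  Q[Q < 0] <- 0  # clip round-off from the exponential
  dimnames(Q) <- dimnames(Rm)
  structure(Q, class = c("transition_matrix", "matrix"), dt = dt)
}

#' Stationary distribution of a transition matrix
#'
#' Solves pi Q = pi with pi summing to one. Used as the chain's initial
#' distribution for both simulation and inference: a channel recorded in
#' steady state has no preferred starting microstate beyond its equilibrium
#' occupancy. Fails if the chain is reducible (the stationary distribution is
#' then not unique).
#'
#' @param Q a square stochastic matrix (rows summing to 1).
#' @return Named probability vector over the states.
#' @export
stationary_distribution <- function(Q) {
  Qm <- unclass(Q)
  S <- nrow(Qm)
  if (is.null(S) || S != ncol(Qm)) stop("`Q` must be square")
  if (any(abs(rowSums(Qm) - 1) > 1e-8)) stop("rows of `Q` must sum to 1")
  ev <- eigen(t(Qm))
  unit <- which(abs(ev$values - 1) < 1e-9)
  if (length(unit) == 0L)
    stop("no unit eigenvalue found; `Q` is not stochastic")
  if (length(unit) > 1L)
    stop("transition matrix is reducible (multiple stationary distributions; ",
         "absorbing or disconnected structure)")
  v <- Re(ev$vectors[, unit])
  p <- v / sum(v)
  if (any(p < -1e-9))
    stop("stationary solve produced negative mass; chain may be reducible")
  p <- pmax(p, 0)
  p <- p / sum(p)
  names(p) <- rownames(Qm)
  p
}

#' Restrict a transition matrix to the scheme topology
#'
#' Zeroes every entry of `Q` that is neither a scheme edge nor a
#' self-transition and renormalizes the rows. The exact discretization
#' Q = exp(R dt) has small (order dt^2) probability on multi-step paths —
#' two kinetic transitions inside one sampling interval; the masked chain
#' allows at most one kinetic transition per sample, which is the model class
#' the EM estimator works in and the setting in which closing labels are
#' unambiguous.
#'
#' @param Q a [discretize()]d transition matrix.
#' @param scheme the [kinetic_scheme()] supplying the allowed edges.
#' @return A `"transition_matrix"` with support on scheme edges plus the
#'   diagonal.
#' @export
mask_topology <- function(Q, scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  Qm <- unclass(Q)
  if (!identical(rownames(Qm), scheme$states))
    stop("`Q` state order does not match the scheme")
  S <- length(scheme$states)
  keep <- matrix(FALSE, S, S)
  keep[cbind(match(scheme$edges$from, scheme$states),
             match(scheme$edges$to, scheme$states))] <- TRUE
  diag(keep) <- TRUE
  Qm[!keep] <- 0
  Qm <- Qm / rowSums(Qm)
  structure(Qm, class = c("transition_matrix", "matrix"),
            dt = attr(Q, "dt"))
}

#' Evolve a state distribution under the master equation
#'
#' Propagates a probability row vector for `t` seconds: P(t) = P(0) exp(R t).
#'
#' @param p0 probability vector over scheme states.
#' @param R a [rate_matrix()].
#' @param t time in seconds, `t >= 0`.
#' @return Probability vector at time `t`.
#' @export
evolve <- function(p0, R, t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("`t` must be a single nonnegative time in seconds")
  Rm <- unclass(R)
  if (length(p0) != nrow(Rm)) stop("`p0` length must match the rate matrix")
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-9)
    stop("`p0` must be a probability distribution")
  out <- as.numeric(p0 %*% as.matrix(Matrix::expm(Matrix::Matrix(Rm * t))))
  names(out) <- rownames(Rm)
  out
}

#' Read / write a kinetic scheme as a plain-text config
#'
#' The format is line-oriented: `state <label> <conductance>` declares a state
#' (in matrix order) and `edge <from> <to> <rate> [atp]` declares a directed
#' transition; the optional `atp` token marks the rate as per-molar (scaled by
#' ATP concentration). Blank lines and lines starting with `#` are ignored.
#' This allows variant schemes (e.g. mutant rate sets) to be supplied without
#' touching code.
#'
#' @param path file path.
#' @return `read_scheme()` returns a `"kinetic_scheme"`; `write_scheme()`
#'   returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:]]+")
  states <- character(); cond <- numeric()
  from <- character(); to <- character(); rate <- numeric(); atp <- logical()
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (tk[1] == "state") {
      if (length(tk) != 3L) stop("malformed state line: ", lines[i])
      states <- c(states, tk[2])
      cond <- c(cond, as.numeric(tk[3]))
    } else if (tk[1] == "edge") {
      if (!length(tk) %in% c(4L, 5L)) stop("malformed edge line: ", lines[i])
      if (length(tk) == 5L && tk[5] != "atp")
        stop("unknown edge flag '", tk[5], "' in: ", lines[i])
      from <- c(from, tk[2]); to <- c(to, tk[3])
      rate <- c(rate, as.numeric(tk[4]))
      atp <- c(atp, length(tk) == 5L)
    } else {
      stop("unknown directive '", tk[1], "' in scheme file")
    }
  }
  names(cond) <- states
  kinetic_scheme(states, cond,
                 data.frame(from = from, to = to, rate = rate, atp = atp,
                            stringsAsFactors = FALSE))
}

#' @rdname read_scheme
#' @param scheme a [kinetic_scheme()] to serialize.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  lines <- c(
    sprintf("state %s %d", scheme$states, as.integer(scheme$conductance)),
    sprintf("edge %s %s %.15g%s", scheme$edges$from, scheme$edges$to,
            scheme$edges$rate, ifelse(scheme$edges$atp, " atp", ""))
  )
  writeLines(lines, path)
  invisible(path)
}
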