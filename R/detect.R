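#' Confidence-thresholded MAP state estimates
#'
#' For each sample, takes the maximum a posteriori state if its posterior
#' probability exceeds the confidence threshold C, and a null estimate (`NA`)
#' otherwise. `C = 0` yields the plain MAP estimate at every sample (the
#' maximum of a posterior row is always positive).
#'
#' @param posterior a `"cftr_posterior"` from [forward_backward()], or a bare
#'   marginal matrix with state-named columns.
#' @param threshold confidence threshold C, `0 <= C < 1`.
#' @return A data frame of class `"map_estimate"` with columns `map_state`
#'   (ungated argmax), `confidence` (the row maximum) and `estimate`
#'   (`map_state` where `confidence > threshold`, `NA` otherwise); the
#'   threshold is stored in `attr(, "threshold")`.
#' @export
map_threshold <- function(posterior, threshold = 0) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1)
    stop("`threshold` must lie in [0, 1)")
  marg <- if (inherits(posterior, "cftr_posterior")) posterior$marginals
          else as.matrix(posterior)
  if (is.null(colnames(marg))) stop("marginals need state-named columns")
  idx <- max.col(marg, ties.method = "first")
  conf <- marg[cbind(seq_len(nrow(marg)), idx)]
  map <- colnames(marg)[idx]
  out <- data.frame(map_state = map, confidence = conf,
                    estimate = ifelse(conf > threshold, map, NA_character_),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("map_estimate", class(out))
  out
}

# permissive / nonpermissive labels from flanking open states; only the pair
# (O2, O1) crosses the ADP-releasing step, and (O1, O2) has no closed path —
# it can only appear through two transitions aliased into one sample
label_closing <- function(initial, final) {
  if (initial == final) return("permissive")
  if (initial == "O2" && final == "O1") return("nonpermissive")
  NA_character_
}

#' Segment a state sequence into channel closings and classify them
#'
#' A closing is a maximal run of closed-conductance samples flanked by an
#' open-state sample on both sides. Runs touching either end of the sequence
#' are discarded (their flanking open state is unobserved). Each closing is
#' labeled from its flanking open states: permissive when initial and final
#' open states are identical (the channel reopens without nucleotide
#' exchange), nonpermissive when it closes from O2 and reopens as O1, which
#' requires the irreversible ADP-releasing step.
#'
#' Segmentation always uses the ungated state sequence; the confidence
#' threshold only sets each event's `confident` flag, which is `TRUE` when
#' both flanking open samples have posterior confidence above `threshold`.
#'
#' A closing flanked (O1, O2) has no label: no closed path connects an O1
#' entry to reopening as O2, so such an event can only arise when two kinetic
#' transitions fall inside a single sampling interval (in ground truth
#' sampled from the exact discretization, about 0.5% of closings at 100 Hz)
#' or from estimation noise. With `invalid = "drop"` (default) these events
#' are removed and their count kept in `attr(, "n_invalid")`; with
#' `invalid = "error"` they raise a validation error.
#'
#' @param states the state sequence: a `"state_sequence"` (ground truth), a
#'   `"map_estimate"` (its ungated `map_state` column is used), or a character
#'   vector.
#' @param scheme the [kinetic_scheme()] providing the conductance map.
#' @param confidence optional per-sample confidence vector; taken from a
#'   `"map_estimate"` automatically, and 1 for ground truth.
#' @param threshold confidence threshold C for the `confident` flag.
#' @param invalid how to treat unlabelable (O1, O2)-flanked closings:
#'   `"drop"` (default) or `"error"`.
#' @return Data frame with one row per closing: `start`, `end` (sample indices
#'   of the closed run), `open_before_idx`, `open_after_idx`,
#'   `initial_state`, `final_state`, `label`, `confident`.
#' @export
#' @examples
#' sch <- cftr_scheme()
#' extract_closings(c("O2", "C3", "C4", "C1a", "C1b", "C2", "O1"), sch)
extract_closings <- function(states, scheme, confidence = NULL,
                             threshold = 0, invalid = c("drop", "error")) {
  invalid <- match.arg(invalid)
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (inherits(states, "map_estimate")) {
    if (is.null(confidence)) confidence <- states$confidence
    states <- states$map_state
  } else if (inherits(states, "state_sequence")) {
    states <- states$states
  }
  states <- as.character(states)
  n <- length(states)
  if (n == 0L) stop("empty state sequence")
  if (is.null(confidence)) confidence <- rep(1, n)
  cond <- scheme$conductance[states]
  if (anyNA(cond)) stop("sequence contains labels unknown to the scheme")

  r <- rle(as.numeric(cond))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  closed <- which(r$values == 0)
  # keep closed runs with an open run on both sides
  closed <- closed[closed > 1L & closed < length(r$values)]
  if (length(closed) == 0L) {
    out <- data.frame(start = integer(), end = integer(),
                      open_before_idx = integer(), open_after_idx = integer(),
                      initial_state = character(), final_state = character(),
                      label = character(), confident = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "n_invalid") <- 0L
    return(out)
  }
  start <- starts[closed]
  end <- ends[closed]
  before <- start - 1L
  after <- end + 1L
  ini <- states[before]
  fin <- states[after]
  lab <- vapply(seq_along(ini), function(i) label_closing(ini[i], fin[i]), "")
  if (anyNA(lab)) {
    if (invalid == "error") {
      i <- which(is.na(lab))[1]
      stop("invalid closing at samples ", start[i], "-", end[i],
           ": closed from '", ini[i], "' but reopened as '", fin[i],
           "'; no closed path connects these states (two transitions ",
           "aliased into one sampling interval)")
    }
    keep <- !is.na(lab)
    n_invalid <- sum(!keep)
    start <- start[keep]; end <- end[keep]; before <- before[keep]
    after <- after[keep]; ini <- ini[keep]; fin <- fin[keep]
    lab <- lab[keep]
  } else n_invalid <- 0L
  conf <- confidence[before] > threshold & confidence[after] > threshold
  out <- data.frame(start = start, end = end, open_before_idx = before,
                    open_after_idx = after, initial_state = ini,
                    final_state = fin, label = lab, confident = conf,
                    stringsAsFactors = FALSE)
  attr(out, "n_invalid") <- n_invalid
  out
}

#' Does a closing contain a given transition?
#'
#' Checks, for each closing, whether the stated directed transition occurs
#' between consecutive samples inside the closed run. With `from = "C4"`,
#' `to = "C1a"` this is the ADP-release test: on ground-truth sequences a
#' closing is nonpermissive exactly when it traverses C4 -> C1a.
#'
#' @param states the state sequence the events were extracted from.
#' @param events the data frame returned by [extract_closings()].
#' @param from,to state labels of the transition.
#' @return Logical vector, one entry per event.
#' @export
closing_contains_transition <- function(states, events, from = "C4",
                                        to = "C1a") {
  if (inherits(states, "state_sequence")) states <- states$states
  states <- as.character(states)
  vapply(seq_len(nrow(events)), function(i) {
    k <- events$start[i]:events$end[i]
    if (length(k) < 2L) return(FALSE)
    any(states[k[-length(k)]] == from & states[k[-1]] == to)
  }, logical(1))
}

#' Score estimated closings against ground truth
#'
#' Matches estimated closings one-to-one to ground-truth closings by maximal
#' closed-interval overlap (at least one shared sample), greedily in
#' decreasing overlap with ties broken by earlier start index, then counts
#' nonpermissive detection errors: a false alarm is an estimated nonpermissive
#' closing whose match is not a ground-truth nonpermissive closing (or that
#' matches nothing); a missed detection is a ground-truth nonpermissive
#' closing not matched by an estimated nonpermissive closing. The false-alarm
#' probability is `n_FA / n_est_np` and the missed-detection probability
#' `n_MD / n_gt_np`; either is `NaN` (flagged undefined) when its denominator
#' is zero.
#'
#' @param gt_events ground-truth closings from [extract_closings()].
#' @param est_events estimated closings from [extract_closings()].
#' @param confident_only drop estimated events whose `confident` flag is
#'   `FALSE` before matching (the confidence-gated detector).
#' @return List of class `"detection_metrics"`: counts `n_FA`, `n_MD`,
#'   `n_est_np`, `n_gt_np`, `n_est_total`, `n_gt_total`, probabilities `P_FA`,
#'   `P_MD`, and flags `P_FA_defined`, `P_MD_defined`.
#' @export
score_closings <- function(gt_events, est_events, confident_only = FALSE) {
  if (isTRUE(confident_only)) est_events <- est_events[est_events$confident, ]
  nE <- nrow(est_events); nG <- nrow(gt_events)

  match_of_est <- rep(NA_integer_, nE)
  if (nE > 0 && nG > 0) {
    pairs <- NULL
    for (i in seq_len(nE)) {
      ov <- pmin(est_events$end[i], gt_events$end) -
            pmax(est_events$start[i], gt_events$start) + 1L
      j <- which(ov > 0)
      if (length(j))
        pairs <- rbind(pairs, cbind(i = i, j = j, ov = ov[j]))
    }
    if (!is.null(pairs)) {
      ord <- order(-pairs[, "ov"], est_events$start[pairs[, "i"]],
                   gt_events$start[pairs[, "j"]])
      used_e <- logical(nE); used_g <- logical(nG)
      for (r in ord) {
        i <- pairs[r, "i"]; j <- pairs[r, "j"]
        if (!used_e[i] && !used_g[j]) {
          match_of_est[i] <- j
          used_e[i] <- TRUE; used_g[j] <- TRUE
        }
      }
    }
  }

  est_np <- which(est_events$label == "nonpermissive")
  gt_np <- which(gt_events$label == "nonpermissive")
  n_FA <- sum(vapply(est_np, function(i) {
    j <- match_of_est[i]
    is.na(j) || gt_events$label[j] != "nonpermissive"
  }, logical(1)))
  gt_matched_by_np <- match_of_est[est_np]
  gt_matched_by_np <- gt_matched_by_np[!is.na(gt_matched_by_np)]
  n_MD <- sum(!(gt_np %in% gt_matched_by_np))

  n_est_np <- length(est_np); n_gt_np <- length(gt_np)
  structure(list(
    n_FA = n_FA, n_MD = n_MD,
    n_est_np = n_est_np, n_gt_np = n_gt_np,
    n_est_total = nE, n_gt_total = nG,
    P_FA = if (n_est_np > 0) n_FA / n_est_np else NaN,
    P_MD = if (n_gt_np > 0) n_MD / n_gt_np else NaN,
    P_FA_defined = n_est_np > 0,
    P_MD_defined = n_gt_np > 0
  ), class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat("Nonpermissive-closing detection:\n")
  cat(sprintf("  closings: %d estimated (%d nonpermissive), %d true (%d nonpermissive)\n",
              x$n_est_total, x$n_est_np, x$n_gt_total, x$n_gt_np))
  cat(sprintf("  P_FA = %s (%d false alarms), P_MD = %s (%d missed)\n",
              if (x$P_FA_defined) sprintf("%.3f", x$P_FA) else "undefined",
              x$n_FA,
              if (x$P_MD_defined) sprintf("%.3f", x$P_MD) else "undefined",
              x$n_MD))
  invisible(x)
}

#' Closings of a fitted model's MAP state sequence
#'
#' Convenience accessor: extracts and classifies the closings of the fit's
#' ungated MAP sequence, with confidence flags at the given threshold.
#'
#' @param fit a [cftr_fit()].
#' @param threshold confidence threshold C.
#' @return As [extract_closings()].
#' @export
closings <- function(fit, threshold = 0) {
  stopifnot(inherits(fit, "cftr_fit"))
  est <- map_threshold(fit$posterior, threshold)
  extract_closings(est, fit$scheme, threshold = threshold)
}
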