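test_that("confidence-thresholded MAP estimates follow the decision rule", {
  marg <- rbind(c(0.9, 0.1, 0, 0, 0, 0, 0),
                c(0.6, 0.4, 0, 0, 0, 0, 0),
                c(0.1, 0.1, 0.2, 0.2, 0.2, 0.1, 0.1))
  colnames(marg) <- cftr_scheme()$states
  est <- map_threshold(marg, 0.8)
  expect_identical(est$estimate, c("C1a", NA, NA))
  expect_identical(est$map_state, c("C1a", "C1a", "C2"))
  expect_equal(est$confidence, c(0.9, 0.6, 0.2))

  est0 <- map_threshold(marg, 0)
  expect_false(anyNA(est0$estimate))   # C = 0 is the plain MAP estimate
  expect_identical(est0$estimate, est0$map_state)

  expect_error(map_threshold(marg, 1), "\\[0, 1\\)")
  expect_error(map_threshold(marg, -0.1), "\\[0, 1\\)")
})

test_that("closings are segmented and classified by their flanking states", {
  sch <- cftr_scheme()
  ev <- extract_closings(c("O1", "C2", "C2", "O1"), sch)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$initial_state, "O1")
  expect_equal(ev$final_state, "O1")
  expect_equal(ev$label, "permissive")
  expect_equal(ev$start, 2L)
  expect_equal(ev$end, 3L)

  ev <- extract_closings(c("O2", "C3", "C4", "C1a", "C1b", "C2", "O1"), sch)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$label, "nonpermissive")
  expect_equal(ev$initial_state, "O2")
  expect_equal(ev$final_state, "O1")

  # runs touching the boundary have an unobserved flank and are discarded
  ev <- extract_closings(c("C2", "C2", "O1", "O1"), sch)
  expect_equal(nrow(ev), 0L)
  ev <- extract_closings(c("O1", "C2", "O1", "C3", "C3"), sch)
  expect_equal(nrow(ev), 1L)

  # (O1, O2) flanks cannot arise from a single-transition path
  s <- c("O1", "C2", "O2", "O2")
  ev <- extract_closings(s, sch)
  expect_equal(nrow(ev), 0L)
  expect_equal(attr(ev, "n_invalid"), 1L)
  expect_error(extract_closings(s, sch, invalid = "error"),
               "no closed path")
})

test_that("confidence gating flags events by their flanking samples", {
  sch <- cftr_scheme()
  s <- c("O1", "C2", "C2", "O1", "O2", "C3", "O2")
  conf <- c(0.95, 0.5, 0.5, 0.7, 0.9, 0.5, 0.85)
  ev <- extract_closings(s, sch, confidence = conf, threshold = 0.8)
  expect_equal(ev$confident, c(FALSE, TRUE))  # 0.7 fails, 0.9/0.85 pass
  ev0 <- extract_closings(s, sch, confidence = conf, threshold = 0)
  expect_true(all(ev0$confident))
})

test_that("raising the confidence threshold never adds confident events", {
  sim <- simulate_trace(atp = 1e-3, dt = 0.01, n = 8000, sigma2 = 0.02,
                        seed = 23)
  post <- forward_backward(sim$trace, sim$Q, cftr_scheme(), amplitude = 1,
                           sigma2 = 0.02)
  est <- map_threshold(post, 0)
  n_conf <- vapply(c(0, 0.3, 0.6, 0.8, 0.95), function(C) {
    ev <- extract_closings(est, cftr_scheme(), threshold = C)
    sum(ev$confident)
  }, numeric(1))
  expect_true(all(diff(n_conf) <= 0))
})

test_that("detection scoring implements the error-rate definitions", {
  sch <- cftr_scheme()
  s <- c("O1", "C2", "O1", "O2", "C3", "C4", "C1a", "C1b", "C2", "O1",
         "O1", "C2", "C2", "O1")
  gt <- extract_closings(s, sch)
  m <- score_closings(gt, gt)
  expect_equal(m$P_FA, 0)
  expect_equal(m$P_MD, 0)
  expect_equal(m$n_gt_total, 3L)
  expect_equal(m$n_gt_np, 1L)

  # two true nonpermissive closings; the estimate flags two closings as
  # nonpermissive, one overlapping a true nonpermissive and one overlapping
  # a true permissive closing
  gt2 <- data.frame(start = c(10L, 30L, 50L), end = c(15L, 35L, 55L),
                    open_before_idx = c(9L, 29L, 49L),
                    open_after_idx = c(16L, 36L, 56L),
                    initial_state = c("O2", "O1", "O2"),
                    final_state = c("O1", "O1", "O1"),
                    label = c("nonpermissive", "permissive", "nonpermissive"),
                    confident = TRUE, stringsAsFactors = FALSE)
  est2 <- gt2
  est2$label <- c("nonpermissive", "nonpermissive", "permissive")
  m2 <- score_closings(gt2, est2)
  expect_equal(m2$n_FA, 1L)
  expect_equal(m2$P_FA, 1 / 2)
  expect_equal(m2$n_MD, 1L)
  expect_equal(m2$P_MD, 1 / 2)

  # an empty estimate: false-alarm rate undefined, all true events missed
  empty <- gt2[0, ]
  m3 <- score_closings(gt2, empty)
  expect_false(m3$P_FA_defined)
  expect_true(is.nan(m3$P_FA))
  expect_equal(m3$P_MD, 1)

  # confident-only filtering removes unconfident estimates before matching
  est4 <- gt2
  est4$confident <- c(FALSE, TRUE, TRUE)
  m4 <- score_closings(gt2, est4, confident_only = TRUE)
  expect_equal(m4$n_est_total, 2L)
  expect_equal(m4$n_MD, 1L)   # the unconfident nonpermissive event is gone
})

test_that("matching is one-to-one by maximal interval overlap", {
  gt <- data.frame(start = c(10L, 20L), end = c(14L, 24L),
                   open_before_idx = c(9L, 19L), open_after_idx = c(15L, 25L),
                   initial_state = "O2", final_state = "O1",
                   label = "nonpermissive", confident = TRUE,
                   stringsAsFactors = FALSE)
  # one estimated event straddling both true events: it can match only one
  est <- data.frame(start = 12L, end = 22L, open_before_idx = 11L,
                    open_after_idx = 23L, initial_state = "O2",
                    final_state = "O1", label = "nonpermissive",
                    confident = TRUE, stringsAsFactors = FALSE)
  m <- score_closings(gt, est)
  expect_equal(m$n_FA, 0L)
  expect_equal(m$n_MD, 1L)
})

test_that("flanking-state and ADP-release labels coincide on single-step chains", {
  sch <- cftr_scheme()
  Q <- mask_topology(discretize(rate_matrix(sch, 1e-3), 0.01), sch)
  s <- sample_states(Q, 2e5, seed = 29)
  ev <- extract_closings(s, sch)
  expect_equal(attr(ev, "n_invalid"), 0L)
  has_release <- closing_contains_transition(s, ev, "C4", "C1a")
  expect_identical(ev$label == "nonpermissive", has_release)
})

test_that("labels agree closely even on the exact-discretization chain", {
  sch <- cftr_scheme()
  Q <- discretize(rate_matrix(sch, 1e-3), 0.01)
  s <- sample_states(Q, 2e5, seed = 29)
  ev <- extract_closings(s, sch)
  # multi-step transitions within one interval produce rare disagreements
  expect_lt(attr(ev, "n_invalid") / nrow(ev), 0.02)
  has_release <- closing_contains_transition(s, ev, "C4", "C1a")
  expect_lt(mean((ev$label == "nonpermissive") != has_release), 0.05)
})
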