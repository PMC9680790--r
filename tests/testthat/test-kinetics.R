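test_that("the default CFTR scheme has the published structure", {
  sch <- cftr_scheme()
  expect_setequal(sch$states, c("C1a", "C1b", "C2", "C3", "C4", "O1", "O2"))
  expect_identical(sch$states, c("C1a", "C1b", "C2", "O1", "O2", "C3", "C4"))
  expect_equal(unname(sch$conductance[c("O1", "O2")]), c(1, 1))
  expect_equal(unname(sch$conductance[c("C1a", "C1b", "C2", "C3", "C4")]),
               rep(0, 5))
  expect_equal(nrow(sch$edges), 12L)
  key <- paste(sch$edges$from, sch$edges$to)
  # the two irreversible steps have no reverse edge
  expect_false("O2 O1" %in% key)
  expect_false("C1a C4" %in% key)
  # ATP binding is the single concentration-dependent step
  expect_identical(key[sch$edges$atp], "C1a C1b")
  expect_true(all(sch$edges$rate > 0))
  rate_of <- function(f, t) sch$edges$rate[sch$edges$from == f & sch$edges$to == t]
  expect_equal(rate_of("C1a", "C1b"), 9.0e3)
  expect_equal(rate_of("O1", "O2"), 7.1)
  # C4 row of the printed rate table, read in column order: C1a then C3
  expect_equal(rate_of("C4", "C1a"), 1.7)
  expect_equal(rate_of("C4", "C3"), 12.8)
})

test_that("scheme validation rejects malformed inputs", {
  expect_error(kinetic_scheme("A", c(A = 2), data.frame(
    from = character(), to = character(), rate = numeric(), atp = logical())),
    "conductance")
  sch <- two_state_scheme()
  bad <- sch$edges
  bad$rate[1] <- -1
  expect_error(kinetic_scheme(sch$states, sch$conductance, bad), "positive")
  bad <- rbind(sch$edges, sch$edges[1, ])
  expect_error(kinetic_scheme(sch$states, sch$conductance, bad), "duplicate")
  bad <- sch$edges
  bad$to[1] <- "C"
  expect_error(kinetic_scheme(sch$states, sch$conductance, bad), "self")
})

test_that("rate matrix entries follow the scheme and conserve probability", {
  sch <- cftr_scheme()
  R <- rate_matrix(sch, atp = 1e-3)
  expect_equal(R["C1a", "C1b"], 9.0)        # 9.0e3 (M s)^-1 x 1e-3 M
  expect_equal(R["O2", "O1"], 0)            # irreversible hydrolysis step
  expect_equal(R["C4", "C1a"], 1.7)
  expect_equal(max(abs(rowSums(R))), 0, tolerance = 1e-12)
  for (atp in c(1e-5, 5e-4, 0.9)) {
    Ra <- rate_matrix(sch, atp)
    expect_equal(max(abs(rowSums(Ra))), 0, tolerance = 1e-10)
    off <- unclass(Ra); diag(off) <- 0
    expect_true(all(off >= 0))
  }
  expect_error(rate_matrix(sch, 0), "positive")
  expect_error(rate_matrix(sch, -1e-3), "positive")
})

test_that("discretization matches closed-form and series oracles", {
  # all-zero generator: nothing moves
  R0 <- structure(matrix(0, 2, 2, dimnames = list(c("C", "O"), c("C", "O"))),
                  class = c("rate_matrix", "matrix"))
  expect_equal(unclass(discretize(R0, 0.01)), diag(2), ignore_attr = TRUE)

  # two-state closed form: relaxation at rate a + b
  a <- 1; b <- 2; dt <- 0.5
  R <- rate_matrix(two_state_scheme(a, b), atp = 1)
  Q <- discretize(R, dt)
  e <- exp(-(a + b) * dt)
  closed_form <- matrix(c(b + a * e, a - a * e,
                          b - b * e, a + b * e) / (a + b),
                        2, 2, byrow = TRUE)
  expect_equal(unclass(Q), closed_form, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unclass(Q), expm_series(unclass(R) * dt), ignore_attr = TRUE,
               tolerance = 1e-10)

  # default scheme: a proper stochastic matrix
  Rc <- rate_matrix(cftr_scheme(), 0.5e-3)
  Qc <- discretize(Rc, 0.01)
  expect_lt(max(abs(rowSums(Qc) - 1)), 1e-12)
  expect_true(all(Qc >= 0 & Qc <= 1))
  expect_equal(unclass(Qc), expm_series(unclass(Rc) * 0.01),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_error(discretize(Rc, 0), "positive")
})

test_that("discretization is a semigroup and first-order accurate in dt", {
  R <- rate_matrix(cftr_scheme(), 1e-3)
  Q1 <- discretize(R, 0.013)
  Q2 <- discretize(R, 0.007)
  Q12 <- discretize(R, 0.02)
  expect_equal(unclass(Q12), unclass(Q1) %*% unclass(Q2),
               ignore_attr = TRUE, tolerance = 1e-10)

  # |exp(R dt) - (I + R dt)| = O(dt^2) with constant ~ |R^2|/2
  Rm <- unclass(R)
  cmax <- max(abs(Rm %*% Rm))  # generous second-order constant
  for (dt in c(1e-4, 1e-5)) {
    err <- max(abs(unclass(discretize(R, dt)) - (diag(7) + Rm * dt)))
    expect_lt(err, cmax * dt^2)
  }
})

test_that("off-topology entries of the sampled-interval matrix are small", {
  sch <- cftr_scheme()
  Q <- discretize(rate_matrix(sch, 1e-3), 0.01)
  S <- length(sch$states)
  on_edge <- matrix(FALSE, S, S, dimnames = dimnames(unclass(Q)))
  on_edge[cbind(sch$edges$from, sch$edges$to)] <- TRUE
  diag(on_edge) <- TRUE
  off <- unclass(Q)[!on_edge]
  expect_true(all(off > 0))      # multi-step paths within one interval
  expect_true(all(off < 5e-3))   # ...but of order dt^2
})

test_that("topology masking removes multi-step paths and renormalizes", {
  sch <- cftr_scheme()
  Q <- discretize(rate_matrix(sch, 1e-3), 0.01)
  Qm <- mask_topology(Q, sch)
  S <- length(sch$states)
  on_edge <- matrix(FALSE, S, S, dimnames = dimnames(unclass(Q)))
  on_edge[cbind(sch$edges$from, sch$edges$to)] <- TRUE
  diag(on_edge) <- TRUE
  expect_true(all(unclass(Qm)[!on_edge] == 0))
  expect_lt(max(abs(rowSums(Qm) - 1)), 1e-12)
  expect_lt(max(abs(unclass(Qm) - unclass(Q))), 5e-3 * S)
})

test_that("stationary distribution solves pi Q = pi", {
  expect_equal(stationary_distribution(as_tpm(matrix(1, 1, 1), "A")),
               c(A = 1))
  Qs <- as_tpm(matrix(c(0.7, 0.3, 0.3, 0.7), 2, byrow = TRUE), c("C", "O"))
  expect_equal(unname(stationary_distribution(Qs)), c(0.5, 0.5))

  Q <- discretize(rate_matrix(cftr_scheme(), 1e-3), 0.01)
  p <- stationary_distribution(Q)
  expect_equal(as.numeric(p %*% unclass(Q)), unname(p), tolerance = 1e-12)
  # power-iteration oracle
  P <- unclass(Q)
  for (i in 1:14) P <- P %*% P   # Q^(2^14) >> Q^10000 mixing
  expect_equal(unname(p), unname(P[1, ]), tolerance = 1e-8)

  # absorbing / disconnected structure is rejected
  expect_error(stationary_distribution(as_tpm(diag(2), c("A", "B"))),
               "reducible")
})

test_that("the master equation evolves and preserves distributions", {
  R <- rate_matrix(cftr_scheme(), 1e-3)
  p0 <- c(1, 0, 0, 0, 0, 0, 0)
  expect_equal(unname(evolve(p0, R, 0)), p0)
  pt <- evolve(p0, R, 3.7)
  expect_equal(sum(pt), 1, tolerance = 1e-12)
  expect_true(all(pt >= 0))
  pi <- stationary_distribution(discretize(R, 0.01))
  expect_equal(unname(evolve(pi, R, 2.5)), unname(pi), tolerance = 1e-10)
  expect_error(evolve(p0, R, -1), "nonnegative")
})

test_that("scheme config files round-trip", {
  sch <- cftr_scheme()
  path <- tempfile(fileext = ".cfg")
  write_scheme(sch, path)
  back <- read_scheme(path)
  expect_identical(back$states, sch$states)
  expect_equal(back$conductance, sch$conductance)
  expect_equal(back$edges, sch$edges)

  writeLines(c("state A 0", "junk B"), path)
  expect_error(read_scheme(path), "unknown directive")
  writeLines(c("state A 0", "state B 1", "edge A B 1 turbo"), path)
  expect_error(read_scheme(path), "unknown edge flag")
})
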