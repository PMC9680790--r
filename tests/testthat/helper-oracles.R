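# Brute-force posterior by exhaustive enumeration over all |S|^n state
# sequences. Independent of the message-passing implementation: it only uses
# the joint factorization p(s, y) = init(s1) prod Q(s_{k-1}, s_k) prod B(k, s_k).
enumerate_posterior <- function(Q, init, B) {
  n <- nrow(B)
  S <- ncol(B)
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))
  probs <- apply(grid, 1, function(s) {
    p <- init[s[1]] * prod(B[cbind(seq_len(n), s)])
    if (n > 1) p <- p * prod(Q[cbind(s[-n], s[-1])])
    p
  })
  tot <- sum(probs)
  marg <- matrix(0, n, S)
  for (k in seq_len(n))
    for (i in seq_len(S)) marg[k, i] <- sum(probs[grid[, k] == i]) / tot
  xi <- NULL
  if (n > 1) {
    xi <- array(0, c(n - 1, S, S))
    for (k in seq_len(n - 1))
      for (i in seq_len(S))
        for (j in seq_len(S))
          xi[k, i, j] <- sum(probs[grid[, k] == i & grid[, k + 1] == j]) / tot
  }
  list(marginals = marg, xi = xi, loglik = log(tot))
}

# Gaussian emission likelihoods for a conductance map, computed directly
gauss_B <- function(y, conductance, amplitude, sigma2) {
  sdv <- sqrt(sigma2)
  vapply(conductance, function(m) dnorm(y, amplitude * m, sdv),
         numeric(length(y)))
}

# truncated Taylor series oracle for the matrix exponential
expm_series <- function(M, terms = 80) {
  out <- diag(nrow(M))
  term <- diag(nrow(M))
  for (k in seq_len(terms)) {
    term <- term %*% M / k
    out <- out + term
  }
  out
}

# two-state open/closed scheme: closing rate b, opening rate a
two_state_scheme <- function(a = 1, b = 2) {
  kinetic_scheme(
    states = c("C", "O"),
    conductance = c(C = 0, O = 1),
    edges = data.frame(from = c("C", "O"), to = c("O", "C"),
                       rate = c(a, b), atp = FALSE)
  )
}

# three-state toy with one open state between two closed ones
three_state_scheme <- function() {
  kinetic_scheme(
    states = c("Ca", "O", "Cb"),
    conductance = c(Ca = 0, O = 1, Cb = 0),
    edges = data.frame(from = c("Ca", "O", "O", "Cb"),
                       to   = c("O", "Ca", "Cb", "O"),
                       rate = c(2, 1, 1.5, 3), atp = FALSE)
  )
}

# wrap a stochastic matrix as a transition_matrix with state names
as_tpm <- function(m, states, dt = 0.01) {
  dimnames(m) <- list(states, states)
  structure(m, class = c("transition_matrix", "matrix"), dt = dt)
}

# wrap a state-label vector as a state_sequence
as_state_sequence <- function(states, dt = 0.01) {
  structure(list(states = states, dt = dt), class = "state_sequence")
}
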