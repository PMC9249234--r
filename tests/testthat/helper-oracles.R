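# Independent oracles used across the suite.  These are deliberately
# written as plain scalar loops, transcribing the update equations one
# term at a time, so they share no code with the vectorized implementation.

# Scalar-loop reference simulator: returns v and s traces for given
# weights, input and constants.  Spike registration, reset and trace
# updates follow the same conventions as the package (documented in the
# methods vignette).
oracle_simulate <- function(w, I, params) {
  N <- params$N
  Tn <- ncol(I)
  bm <- exp(-params$dt / params$tau_m)
  bs <- exp(-params$dt / params$tau_s)
  v <- rep(params$v_rest, N)
  s <- numeric(N)
  s_hat <- numeric(N)
  V <- matrix(0, N, Tn); S <- matrix(0, N, Tn)
  for (t in seq_len(Tn)) {
    s_new <- numeric(N)
    for (i in seq_len(N)) s_new[i] <- if (v[i] - params$v_th > 0) 1 else 0
    v_new <- numeric(N)
    for (i in seq_len(N)) {
      rec <- 0
      for (j in seq_len(N)) rec <- rec + w[i, j] * s_hat[j]
      v_new[i] <- bm * v[i] + (1 - bm) * (rec + I[i, t] + params$v_rest) +
        params$w_res * s_new[i]
    }
    s_hat_new <- numeric(N)
    for (j in seq_len(N)) s_hat_new[j] <- bs * s_hat[j] + (1 - bs) * s_new[j]
    v <- v_new; s <- s_new; s_hat <- s_hat_new
    V[, t] <- v; S[, t] <- s
  }
  list(v = V, s = S)
}

# Quadruple-loop transcription of the generalized weight update
# dw[i,j] = eta * sum_t sum_k M[i,k] err[k,t+1] p[i,t] e[j,t]
# where M is either a feedback matrix (target form) or t(B_plus) (error
# form applied to generalized errors), or identity (local rule).
oracle_delta_w <- function(M, err, p, e, eta) {
  N <- nrow(p); Tn <- ncol(p)
  dw <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      acc <- 0
      for (t in seq_len(Tn - 1)) {
        mix <- 0
        for (k in seq_len(nrow(err))) mix <- mix + M[i, k] * err[k, t + 1]
        acc <- acc + mix * p[i, t] * e[j, t]
      }
      dw[i, j] <- eta * acc
    }
  }
  dw
}

# Random toy instance for the update-rule tests: traces, targets and an
# expanded readout of the requested sizes.
toy_instance <- function(N = 5, Tn = 10, O = 2, R = 4, seed = 1) {
  set.seed(seed)
  p <- matrix(runif(N * Tn), N, Tn)
  e <- matrix(runif(N * Tn), N, Tn)
  s_bar <- matrix(runif(N * Tn), N, Tn)
  s_bar_star <- matrix(runif(N * Tn), N, Tn)
  B_plus <- matrix(rnorm(R * N), R, N)
  list(p = p, e = e, s_bar = s_bar, s_bar_star = s_bar_star,
       B_plus = B_plus, N = N, Tn = Tn, O = O, R = R)
}

# Small network parameter set used throughout the unit tests.
toy_params <- function(N = 4, ...) network_params(N = N, ...)
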