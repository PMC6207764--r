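# Independent brute-force oracles used across the test files.

std_game <- function() pd_game(R = 1, T = 2, S = -1, P = 0)

# Absorption probability into the all-cooperator state from S_1 (and into
# all-defectors from S_{N-1}) by a dense first-step-analysis linear solve,
# built directly from the one-step probabilities.
oracle_absorption <- function(game, params, scheme) {
  n <- params$N - 1
  tr <- transition_probabilities(seq_len(n), game, params, scheme)
  U <- diag(1 - tr$t_plus - tr$t_minus, n, n)
  if (n > 1) {
    U[cbind(1:(n - 1), 2:n)] <- tr$t_plus[1:(n - 1)]
    U[cbind(2:n, 1:(n - 1))] <- tr$t_minus[2:n]
  }
  A <- diag(n) - U
  bN <- numeric(n); bN[n] <- tr$t_plus[n]
  b0 <- numeric(n); b0[1] <- tr$t_minus[1]
  list(rho_dc = solve(A, bN)[1], rho_cd = solve(A, b0)[n])
}

# Dense fundamental-matrix visits under the half/half mutant-start rule.
oracle_visits <- function(game, params, scheme) {
  n <- params$N - 1
  tr <- transition_probabilities(seq_len(n), game, params, scheme)
  U <- diag(1 - tr$t_plus - tr$t_minus, n, n)
  if (n > 1) {
    U[cbind(1:(n - 1), 2:n)] <- tr$t_plus[1:(n - 1)]
    U[cbind(2:n, 1:(n - 1))] <- tr$t_minus[2:n]
  }
  Nf <- solve(diag(n) - U)
  (Nf[1, ] + Nf[n, ]) / 2
}

# A random game satisfying the strict PD ordering T > R > P > S.
random_pd_game <- function() {
  v <- sort(stats::rnorm(4, sd = 2), decreasing = TRUE)
  pd_game(R = v[2], T = v[1], P = v[3], S = v[4])
}

random_scheme <- function(N, max_theta = 5) {
  if (stats::runif(1) < 0.5) {
    interference_scheme(stats::runif(N - 1, 0, max_theta), N)
  } else {
    scheme_individual(stats::runif(1, 0, max_theta),
                      sample(N - 1, 1), N)
  }
}
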