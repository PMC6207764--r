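#' Define a one-shot Prisoner's Dilemma payoff matrix
#'
#' Constructs the 2x2 symmetric game played by every pair of individuals.
#' `R` is the reward for mutual cooperation, `T` the temptation to defect,
#' `S` the sucker's payoff of a lone cooperator and `P` the penalty for
#' mutual defection. The Prisoner's Dilemma preference ordering
#' `T > R > P > S` is enforced unless `check = FALSE`, which permits
#' arbitrary 2-strategy games (useful for degenerate or neutral test games).
#'
#' @param R,T,S,P numeric payoff entries (dimensionless payoff units).
#' @param check validate the strict PD ordering `T > R > P > S`?
#' @return An object of class `pd_game`.
#' @examples
#' pd_game() # the standard parameterisation R = 1, T = 2, S = -1, P = 0
#' @export
pd_game <- function(R = 1, T = 2, S = -1, P = 0, check = TRUE) {
  vals <- c(R = R, T = T, S = S, P = P)
  if (any(!is.finite(vals))) {
    stop("payoff entries must be finite numbers", call. = FALSE)
  }
  if (check && !(T > R && R > P && P > S)) {
    stop("payoffs do not satisfy the Prisoner's Dilemma ordering T > R > P > S; ",
         "use check = FALSE for non-PD games", call. = FALSE)
  }
  structure(list(R = R, T = T, S = S, P = P), class = "pd_game")
}

#' @export
print.pd_game <- function(x, ...) {
  cat("<pd_game> R =", x$R, " T =", x$T, " S =", x$S, " P =", x$P, "\n")
  invisible(x)
}

#' Population size and selection intensity of the imitation process
#'
#' @param N integer population size, at least 2 individuals.
#' @param beta selection intensity of the Fermi imitation rule
#'   (`beta = 0` is neutral drift; larger values make imitation of the
#'   fitter player increasingly deterministic). Must be finite and >= 0.
#' @return An object of class `evo_params`.
#' @examples
#' evo_params(N = 100, beta = 0.1)
#' @export
evo_params <- function(N, beta) {
  if (length(N) != 1 || !is.finite(N) || N < 2 || N != round(N)) {
    stop("N must be a single integer >= 2", call. = FALSE)
  }
  if (length(beta) != 1 || !is.finite(beta) || beta < 0) {
    stop("beta must be a single finite number >= 0", call. = FALSE)
  }
  structure(list(N = as.integer(N), beta = as.numeric(beta)),
            class = "evo_params")
}

#' @export
print.evo_params <- function(x, ...) {
  cat("<evo_params> N =", x$N, " beta =", x$beta, "\n")
  invisible(x)
}

check_state <- function(k, N) {
  if (any(k < 1 | k > N - 1 | k != round(k))) {
    stop("cooperator count k must be an integer in 1..N-1 ",
         "(homogeneous states have no mixed payoffs)", call. = FALSE)
  }
}

# Average payoffs of cooperators and defectors at state k, excluding
# self-interaction and excluding any interference bonus. Vectorised over k.
payoffs_raw <- function(k, game, params) {
  N <- params$N
  pi_c <- ((k - 1) * game$R + (N - k) * game$S) / (N - 1)
  pi_d <- (k * game$T + (N - k - 1) * game$P) / (N - 1)
  list(pi_c = pi_c, pi_d = pi_d)
}

#' Average payoffs in a mixed population state
#'
#' At the state with `k` cooperators (and `N - k` defectors) every individual
#' plays every other individual once; self-interaction is excluded, hence the
#' `N - 1` denominators. Interference rewards are *not* included here: they
#' enter downstream as an additive bonus `theta_k / k` to each cooperator.
#'
#' @param k cooperator count(s), integer(s) in `1..N-1`.
#' @inheritParams transition_probabilities
#' @return A tibble with columns `k`, `pi_c`, `pi_d`.
#' @examples
#' average_payoffs(50, pd_game(), evo_params(100, 0.1))
#' @export
average_payoffs <- function(k, game, params) {
  check_state(k, params$N)
  p <- payoffs_raw(k, game, params)
  tibble::tibble(k = as.integer(k), pi_c = p$pi_c, pi_d = p$pi_d)
}

#' Fermi (pairwise-comparison) imitation probability
#'
#' Probability that a focal player with fitness `f_a` adopts the strategy of
#' a model player with fitness `f_b`: `1 / (1 + exp(-beta * (f_b - f_a)))`.
#' Computed through a numerically stable sigmoid, so arbitrarily large
#' fitness differences saturate to 0 or 1 without overflow.
#'
#' @param f_a,f_b fitness (average payoff) of the focal and model player.
#' @param beta selection intensity, >= 0.
#' @return Adoption probability in (0, 1); vectorised over its arguments.
#' @examples
#' fermi_probability(0, 1, beta = 0.1)
#' @export
fermi_probability <- function(f_a, f_b, beta) {
  if (any(beta < 0) || any(!is.finite(beta))) {
    stop("beta must be finite and >= 0", call. = FALSE)
  }
  stats::plogis(beta * (f_b - f_a))
}

# Payoff advantage of a cooperator over a defector at state k, with the
# interference bonus theta_k / k included. The whole analytic layer is a
# function of this single quantity.
delta_k <- function(k, game, params, scheme) {
  p <- payoffs_raw(k, game, params)
  p$pi_c + scheme_theta(scheme)[k] / k - p$pi_d
}

#' One-step transition probabilities of the cooperator-count chain
#'
#' Probabilities that one focal-model imitation event increases (`t_plus`)
#' or decreases (`t_minus`) the number of cooperators `k` by one:
#' `T+(k) = (N-k)/N * k/N * [1 + exp(-beta * D_k)]^-1` and `T-(k)` with the
#' opposite sign, where `D_k` is the cooperator payoff advantage including
#' the interference bonus `theta_k / k`. At `beta = 0` both reduce exactly
#' to the neutral value `k (N - k) / (2 N^2)`.
#'
#' @param k cooperator count(s), integer(s) in `1..N-1`.
#' @param game a [pd_game()].
#' @param params an [evo_params()].
#' @param scheme an [interference_scheme()] (or individual-based variant)
#'   whose state space matches `params$N`.
#' @return A tibble with columns `k`, `t_plus`, `t_minus`.
#' @examples
#' transition_probabilities(50, pd_game(), evo_params(100, 0.1),
#'                          scheme_zero(100))
#' @export
transition_probabilities <- function(k, game, params, scheme) {
  check_state(k, params$N)
  check_scheme_matches(scheme, params$N)
  N <- params$N
  frac <- (N - k) / N * k / N
  if (params$beta == 0) {
    tp <- tm <- frac / 2
  } else {
    d <- delta_k(k, game, params, scheme)
    tp <- frac * stats::plogis(params$beta * d)
    tm <- frac * stats::plogis(-params$beta * d)
  }
  tibble::tibble(k = as.integer(k), t_plus = tp, t_minus = tm)
}
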