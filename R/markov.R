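# Tridiagonal (Thomas) solve of A x = b with A given by its three bands:
# dg[i] = A[i,i], lo[i] = A[i,i-1] (i >= 2), up[i] = A[i,i+1] (i <= n-1).
# A here is I - U (or its transpose) for a birth-death chain: an M-matrix,
# for which elimination without pivoting is well conditioned.
thomas_solve <- function(lo, dg, up, b) {
  n <- length(dg)
  cp <- numeric(n); xp <- numeric(n)
  cp[1] <- up[1] / dg[1]
  xp[1] <- b[1] / dg[1]
  if (n > 1) {
    for (i in 2:n) {
      m <- dg[i] - lo[i] * cp[i - 1]
      if (m == 0 || !is.finite(m)) {
        stop("singular tridiagonal system: some transition probabilities ",
             "are degenerate (check the scheme and beta)", call. = FALSE)
      }
      cp[i] <- up[i] / m
      xp[i] <- (b[i] - lo[i] * xp[i - 1]) / m
    }
  }
  x <- numeric(n)
  x[n] <- xp[n]
  if (n > 1) for (i in (n - 1):1) x[i] <- xp[i] - cp[i] * x[i + 1]
  x
}

#' Absorbing-chain analysis of the imitation dynamics
#'
#' The cooperator count performs a birth-death process on states
#' `S_0 .. S_N` with `S_0` (all defectors) and `S_N` (all cooperators)
#' absorbing. `transient_chain()` assembles the tridiagonal transition
#' matrix `U` between the transient states `S_1 .. S_{N-1}`, with
#' `u_{k,k+1} = T+(k)`, `u_{k,k-1} = T-(k)` and the self-loop
#' `u_{k,k} = 1 - T+(k) - T-(k)`; interference enters through the payoffs
#' inside `T+-`.
#'
#' @inheritParams transition_probabilities
#' @return An object of class `chain_analysis`: the dense matrix `U`, the
#'   band vectors `t_plus` / `t_minus`, and the inputs.
#' @seealso [expected_visits()], [expected_cost()]
#' @export
transient_chain <- function(game, params, scheme) {
  check_scheme_matches(scheme, params$N)
  n <- params$N - 1L
  tr <- transition_probabilities(seq_len(n), game, params, scheme)
  U <- diag(1 - tr$t_plus - tr$t_minus, n, n)
  if (n > 1) {
    U[cbind(1:(n - 1), 2:n)] <- tr$t_plus[1:(n - 1)]
    U[cbind(2:n, 1:(n - 1))] <- tr$t_minus[2:n]
  }
  k <- seq_len(n)
  bd <- if (params$beta == 0) rep(0, n) else
    params$beta * delta_k(k, game, params, scheme)
  structure(list(U = U, t_plus = tr$t_plus, t_minus = tr$t_minus,
                 frac = (params$N - k) / params$N * k / params$N,
                 beta_delta = bd,
                 game = game, params = params, scheme = scheme),
            class = "chain_analysis")
}

#' @export
print.chain_analysis <- function(x, ...) {
  cat("<chain_analysis> N =", x$params$N, " beta =", x$params$beta,
      " transient states =", nrow(x$U), "\n")
  invisible(x)
}

log_add_exp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# Exact birth-death closed form for the two needed rows of the fundamental
# matrix, evaluated entirely in log space. With w_i = prod_{m<=i} T-/T+ =
# exp(-beta C_i) (C_i the cumulative cooperator payoff advantage), the
# gambler's-ruin identities give
#   n_{jj} = 1 / (T+(j) P[hit N before j | j+1] + T-(j) P[hit 0 before j | j-1])
#   n_{1,j} = n_{jj} / sum_{i<j} w_i,   n_{N-1,j} = n_{jj} w_{N-1} / sum_{i>=j} w_i
# so every term is a ratio of log-sum-exp prefix/suffix sums. This stays
# accurate in metastable regimes (strong selection with an interior drift
# attractor) where visit counts reach exp(hundreds) and any linear solve of
# I - U loses all significant digits.
visits_log_space <- function(frac, beta_delta) {
  n <- length(beta_delta)
  N <- n + 1
  lw <- c(0, cumsum(-beta_delta))          # lw[i+1] = log w_i, i = 0..n
  # streaming prefix/suffix log-sum-exp (running max m, rescaled sum s)
  lpre <- lsuf <- numeric(N)
  m <- lw[1]; s <- 1; lpre[1] <- m
  for (i in 2:N) {
    x <- lw[i]
    if (x <= m) s <- s + exp(x - m) else { s <- s * exp(m - x) + 1; m <- x }
    lpre[i] <- m + log(s)
  }
  m <- lw[N]; s <- 1; lsuf[N] <- m
  for (i in (N - 1):1) {
    x <- lw[i]
    if (x <= m) s <- s + exp(x - m) else { s <- s * exp(m - x) + 1; m <- x }
    lsuf[i] <- m + log(s)
  }
  j <- seq_len(n)
  log_tp <- log(frac) + stats::plogis(beta_delta, log.p = TRUE)
  log_tm <- log(frac) + stats::plogis(-beta_delta, log.p = TRUE)
  log_e_up <- lw[j + 1] - lsuf[j + 1]      # escape to S_N before returning to j
  log_e_dn <- lw[j] - lpre[j]              # escape to S_0 before returning to j
  log_d <- log_add_exp(log_tp + log_e_up, log_tm + log_e_dn)
  log_n1 <- -lpre[j] - log_d               # row 1 of (I - U)^-1
  log_n2 <- lw[N] - lsuf[j + 1] - log_d    # row N-1
  (exp(log_n1) + exp(log_n2)) / 2
}

# Cross-check path: rows 1 and n of the fundamental matrix (I - U)^-1 by
# two tridiagonal solves of the transposed system, O(N) each. Accurate in
# benign regimes only; see visits_log_space().
visits_from_rates <- function(t_plus, t_minus) {
  n <- length(t_plus)
  dg <- t_plus + t_minus
  # bands of (I - U)^T
  lo <- c(0, -t_plus[-n])   # (I-U)^T[i, i-1] = -T+(i-1)
  up <- c(-t_minus[-1], 0)  # (I-U)^T[i, i+1] = -T-(i+1)
  e1 <- numeric(n); e1[1] <- 1
  en <- numeric(n); en[n] <- 1
  row1 <- thomas_solve(lo, dg, up, e1)
  rown <- thomas_solve(lo, dg, up, en)
  (row1 + rown) / 2
}

#' Expected number of visits to each transient state
#'
#' Entry `(i, j)` of the fundamental matrix `(I - U)^-1` is the expected
#' number of time steps the population spends in state `S_j` when started
#' at `S_i` (self-loop steps included, and the starting step counts as a
#' visit). Under the convention that a mutant appears at `S_1` or
#' `S_{N-1}` with probability 1/2 each, the expected visits to `S_i` are
#' `(n_{1,i} + n_{N-1,i}) / 2`. The default `"analytic"` method evaluates
#' the exact birth-death closed form for those two rows in log space,
#' which remains accurate even in metastable strong-selection regimes
#' where visit counts are astronomically large; `"banded"` (tridiagonal
#' solves of the transposed system, O(N)) and `"dense"` (full inversion of
#' `I - U`) are kept as independent cross-check paths for benign regimes.
#'
#' @param chain a [transient_chain()].
#' @param method `"analytic"` (default), `"banded"`, or `"dense"`.
#' @return Numeric vector `v` of length `N - 1`, all entries positive.
#' @export
expected_visits <- function(chain, method = c("analytic", "banded", "dense")) {
  method <- match.arg(method)
  if (method == "analytic") {
    v <- visits_log_space(chain$frac, chain$beta_delta)
  } else if (method == "banded") {
    v <- visits_from_rates(chain$t_plus, chain$t_minus)
  } else {
    Nf <- solve(diag(nrow(chain$U)) - chain$U)
    v <- (Nf[1, ] + Nf[nrow(Nf), ]) / 2
  }
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("fundamental-matrix visits are not all positive and finite; ",
         "the transient chain appears degenerate", call. = FALSE)
  }
  v
}

#' Expected total cost of interference
#'
#' Visit-weighted total investment
#' `EC = (1/2) sum_i (n_{1,i} + n_{N-1,i}) theta_i`: each time step spent in
#' state `S_i` (self-loops included) costs the scheme's total investment
#' `theta_i` there. Also reports the expected number of interference events,
#' i.e. the expected visits to states where an investment is actually made.
#'
#' @param chain a [transient_chain()].
#' @param scheme optionally, a different scheme to price on the *same*
#'   chain (same length); by default the scheme the chain was built with.
#' @return An object of class `cost_report` with `expected_cost`,
#'   `expected_interference_events` and a per-state tibble.
#' @examples
#' ch <- transient_chain(pd_game(), evo_params(10, 0.5),
#'                       scheme_individual(2, 5, 10))
#' expected_cost(ch)
#' @export
expected_cost <- function(chain, scheme = NULL) {
  if (is.null(scheme)) scheme <- chain$scheme
  th <- scheme_theta(scheme)
  if (length(th) != length(chain$t_plus)) {
    stop("scheme length does not match the chain dimension", call. = FALSE)
  }
  v <- expected_visits(chain)
  per_state <- tibble::tibble(state = seq_along(v), visits = v,
                              theta = th, cost = v * th)
  structure(list(expected_cost = sum(per_state$cost),
                 expected_interference_events = sum(v[th > 0]),
                 per_state = per_state),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat("<cost_report> EC =", signif(x$expected_cost, 6),
      " expected interference events =",
      signif(x$expected_interference_events, 6), "\n")
  invisible(x)
}

#' @rdname expected_cost
#' @param x a `cost_report`.
#' @param ... unused.
#' @export
tidy.cost_report <- function(x, ...) x$per_state

#' @rdname expected_cost
#' @export
glance.cost_report <- function(x, ...) {
  tibble::tibble(expected_cost = x$expected_cost,
                 expected_interference_events = x$expected_interference_events)
}

#' Absorption probabilities from the transient chain
#'
#' First-step-analysis solve of the same absorbing chain: the probability
#' of absorption in the all-cooperator state starting from `S_1` equals the
#' fixation probability `rho_DC`, and absorption in all-defectors from
#' `S_{N-1}` equals `rho_CD`. Used as an independent consistency route for
#' [fixation_probabilities()].
#'
#' @param chain a [transient_chain()].
#' @return A list with `rho_dc` and `rho_cd`.
#' @export
chain_absorption <- function(chain) {
  tp <- chain$t_plus; tm <- chain$t_minus
  n <- length(tp)
  dg <- tp + tm
  lo <- c(0, -tm[-1])
  up <- c(-tp[-n], 0)
  bN <- numeric(n); bN[n] <- tp[n] # absorb into S_N
  b0 <- numeric(n); b0[1] <- tm[1] # absorb into S_0
  list(rho_dc = thomas_solve(lo, dg, up, bN)[1],
       rho_cd = thomas_solve(lo, dg, up, b0)[n])
}

# Fast internal path used by threshold scans: expected cost and event count
# for an individual-based scheme (theta, t) without building dense U.
ec_individual_fast <- function(game, params, theta, t) {
  N <- params$N
  k <- seq_len(N - 1)
  frac <- (N - k) / N * k / N
  p <- payoffs_raw(k, game, params)
  d0 <- p$pi_c - p$pi_d
  th <- ifelse(k <= t, k * theta, 0)
  bd <- if (params$beta == 0) rep(0, N - 1) else params$beta * (d0 + th / k)
  v <- visits_log_space(frac, bd)
  c(ec = sum(v * th), events = sum(v[th > 0]))
}
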