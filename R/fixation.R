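#' Fixation probabilities of a single mutant under interference
#'
#' Probability `rho_dc` that a single cooperator fixates in an all-defector
#' population, and `rho_cd` that a single defector fixates in an
#' all-cooperator population, for the birth-death imitation chain with the
#' interference bonus `theta_k / k` added to cooperator payoffs. The
#' one-step ratio of the Fermi kernel satisfies `T-(k)/T+(k) = exp(-beta
#' D_k)` exactly, so the classic product-sum formula
#' `rho = (1 + sum_i prod_{k<=i} T-/T+)^-1`
#' is evaluated entirely in log space (log-sum-exp over cumulative payoff
#' advantages); products of Fermi ratios are never formed directly, so the
#' computation is overflow-safe even when `beta * N * payoff` reaches
#' hundreds. At `beta = 0` both probabilities are exactly `1/N`.
#'
#' @inheritParams transition_probabilities
#' @return An object of class `fixation_pair`: a list with `rho_dc`,
#'   `rho_cd`, their logs, and `log_ratio = log(rho_dc / rho_cd)`.
#' @seealso [cooperation_ratio_log()] for the closed form of `log_ratio`,
#'   [cooperation_frequency()] for the stationary cooperation level.
#' @examples
#' fixation_probabilities(pd_game(), evo_params(100, 0.1), scheme_zero(100))
#' @export
fixation_probabilities <- function(game, params, scheme) {
  check_scheme_matches(scheme, params$N)
  N <- params$N
  beta <- params$beta
  if (beta == 0) {
    # exact neutral value, not a limit of the general formula
    lp <- log(1 / N)
    out <- list(rho_dc = 1 / N, rho_cd = 1 / N,
                log_rho_dc = lp, log_rho_cd = lp, log_ratio = 0)
    return(structure(out, class = "fixation_pair"))
  }
  cd <- cumulative_delta(game, params, scheme) # C_0 .. C_{N-1}
  # C mutant in D residents: terms exp(-beta C_i), i = 0..N-1
  log_rho_dc <- -log_sum_exp(-beta * cd)
  # D mutant in C residents: reversed chain, terms exp(beta (C_{N-1} - C_{N-1-i}))
  log_rho_cd <- -log_sum_exp(beta * (cd[N] - rev(cd)))
  structure(list(rho_dc = exp(log_rho_dc), rho_cd = exp(log_rho_cd),
                 log_rho_dc = log_rho_dc, log_rho_cd = log_rho_cd,
                 log_ratio = log_rho_dc - log_rho_cd),
            class = "fixation_pair")
}

#' @export
print.fixation_pair <- function(x, ...) {
  cat("<fixation_pair> rho_DC =", signif(x$rho_dc, 6),
      " rho_CD =", signif(x$rho_cd, 6),
      " log ratio =", signif(x$log_ratio, 6), "\n")
  invisible(x)
}

#' @export
#' @rdname cooperation_frequency
tidy.fixation_pair <- function(x, ...) {
  tibble::tibble(rho_dc = x$rho_dc, rho_cd = x$rho_cd, log_ratio = x$log_ratio)
}

#' Closed-form log-ratio of fixation probabilities
#'
#' The product of one-step Fermi ratios telescopes, giving
#' `log(rho_DC / rho_CD) = beta * (N (R + S - T - P) / 2 + (P - R) + G)`
#' where `G = sum_k theta_k / k` is the scheme's investment statistic. The
#' ratio -- and hence the stationary cooperation frequency -- depends on the
#' scheme only through `G`.
#'
#' @inheritParams transition_probabilities
#' @return The scalar `log(rho_DC / rho_CD)`.
#' @examples
#' cooperation_ratio_log(pd_game(), evo_params(100, 0.1), scheme_zero(100))
#' @export
cooperation_ratio_log <- function(game, params, scheme) {
  check_scheme_matches(scheme, params$N)
  N <- params$N
  params$beta * (N * (game$R + game$S - game$T - game$P) / 2 +
                   (game$P - game$R) + g_statistic(scheme))
}

#' Stationary cooperation frequency in the small-mutation limit
#'
#' In the small-mutation limit the population hops between the two
#' homogeneous states (all-defector, all-cooperator) at rates given by the
#' fixation probabilities, and the long-run fraction of time spent in the
#' all-cooperator state is `rho_DC / (rho_DC + rho_CD)`. At `beta = 0` this
#' is exactly 0.5 for any scheme. For `beta > 0` the frequency is strictly
#' increasing in the scheme statistic `G`.
#'
#' @inheritParams transition_probabilities
#' @return An object of class `coop_outcome`: the `fixation_pair`, the
#'   cooperation frequency, and the scheme statistic `G`.
#' @examples
#' cooperation_frequency(pd_game(), evo_params(100, 0.1),
#'                       scheme_individual(5, 30, 100))
#' @export
cooperation_frequency <- function(game, params, scheme) {
  fix <- fixation_probabilities(game, params, scheme)
  freq <- if (params$beta == 0) 0.5 else stats::plogis(fix$log_ratio)
  structure(list(fixation = fix, coop_frequency = freq,
                 G = g_statistic(scheme),
                 game = game, params = params, scheme = scheme),
            class = "coop_outcome")
}

#' @export
print.coop_outcome <- function(x, ...) {
  cat("<coop_outcome> cooperation frequency =", signif(x$coop_frequency, 6),
      " G =", signif(x$G, 6), "\n")
  print(x$fixation)
  invisible(x)
}

#' @rdname cooperation_frequency
#' @param x a `coop_outcome` (or `fixation_pair`).
#' @param ... unused.
#' @export
tidy.coop_outcome <- function(x, ...) {
  tibble::tibble(rho_dc = x$fixation$rho_dc, rho_cd = x$fixation$rho_cd,
                 log_ratio = x$fixation$log_ratio,
                 coop_frequency = x$coop_frequency, G = x$G)
}

#' @rdname cooperation_frequency
#' @export
glance.coop_outcome <- function(x, ...) {
  tibble::tibble(N = x$params$N, beta = x$params$beta,
                 family = x$scheme$family, G = x$G,
                 coop_frequency = x$coop_frequency)
}

#' Small-mutation-limit stationary distribution over s strategies
#'
#' Given a matrix of pairwise fixation probabilities, builds the
#' homogeneous-state Markov chain of the small-mutation limit (off-diagonal
#' transition `i -> j` equal to `rho[i, j] / (s - 1)`) and returns its
#' stationary distribution as the normalised eigenvector of the transposed
#' transition matrix at eigenvalue 1.
#'
#' @param rho an `s x s` matrix; `rho[i, j]` is the probability that a
#'   single mutant of strategy `j` fixates in a resident population of
#'   strategy `i`. The diagonal is ignored.
#' @param tol tolerance for the leading eigenvalue to be 1 and for negative
#'   components to be treated as numerical noise.
#' @return A non-negative probability vector of length `s` summing to 1.
#' @examples
#' rho <- matrix(c(NA, 0.01, 0.03, NA), 2, 2) # order (D, C): rho[1,2] = rho_DC
#' stationary_distribution(rho) # c(0.25, 0.75)
#' @export
stationary_distribution <- function(rho, tol = 1e-8) {
  s <- nrow(rho)
  if (is.null(s) || s < 2 || ncol(rho) != s) {
    stop("rho must be a square matrix with s >= 2 strategies", call. = FALSE)
  }
  M <- rho / (s - 1)
  diag(M) <- 0
  diag(M) <- 1 - rowSums(M)
  e <- eigen(t(M))
  i <- which.max(Re(e$values))
  if (abs(Re(e$values[i]) - 1) > tol || abs(Im(e$values[i])) > tol) {
    stop("transition matrix has no eigenvalue 1 within tolerance; ",
         "leading eigenvalue = ", format(e$values[i]), call. = FALSE)
  }
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -tol)) {
    stop("stationary eigenvector has significantly negative components; ",
         "the chain may be reducible", call. = FALSE)
  }
  pmax(v, 0) / sum(pmax(v, 0))
}
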