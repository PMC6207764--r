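# One focal-model imitation event, vectorised over a set of populations in
# states kk (cooperator counts). Focal and model individuals are drawn
# uniformly with replacement, so the probability that the focal is a
# cooperator is kk/N independently of the model draw. A strategy change
# happens only when the two differ and the Fermi draw accepts; the
# resulting one-step kernel is exactly T+-(k).
abm_imitation_step <- function(kk, N, p_up, p_down, u_focal, u_model, u_adopt) {
  focal_c <- u_focal < kk / N
  model_c <- u_model < kk / N
  up <- !focal_c & model_c & u_adopt < p_up[kk]
  down <- focal_c & !model_c & u_adopt < p_down[kk]
  kk + up - down
}

# Fermi adoption probabilities for the two discordant pairings at each
# mixed state k = 1..N-1 (interference bonus included in the cooperator
# payoff). p_up[k]: a defector focal adopts a cooperator model.
abm_adoption_probs <- function(game, params, scheme) {
  k <- seq_len(params$N - 1)
  d <- delta_k(k, game, params, scheme)
  list(p_up = stats::plogis(params$beta * d),
       p_down = stats::plogis(-params$beta * d))
}

#' Agent-based mutant-invasion episodes
#'
#' Monte-Carlo simulation of the pairwise-comparison (Fermi) imitation
#' process with interference, used as an independent oracle for the
#' analytic layer. Each episode places a single mutant in a homogeneous
#' population -- a cooperator into all-defectors (state `S_1`) or a
#' defector into all-cooperators (`S_{N-1}`) with probability 1/2 each --
#' and runs focal-model imitation events until the population is
#' homogeneous again. One time step is one imitation event, matching the
#' analytic one-step kernel `T+-(k)`. Per-state dwell counts include
#' no-change steps, and every step spent in `S_i` accrues the scheme's
#' investment `theta_i`, mirroring the fundamental-matrix visit semantics
#' of [expected_cost()].
#'
#' @inheritParams transition_probabilities
#' @param episodes number of independent episodes (> 0).
#' @param seed integer RNG seed (required: runs are fully reproducible).
#' @param max_iter safety cap on the number of synchronous event rounds.
#' @return An object of class `abm_episodes` with fixation-frequency
#'   estimates (`est_rho_dc`, `est_rho_cd`), mean per-state visit counts,
#'   and the mean cumulative payout per episode, each with a standard
#'   error. `tidy()` returns the per-state visit table; `glance()` the
#'   scalar summary.
#' @examples
#' sim <- simulate_episodes(pd_game(), evo_params(10, 0.5), scheme_zero(10),
#'                          episodes = 2000, seed = 1)
#' glance(sim)
#' @export
simulate_episodes <- function(game, params, scheme, episodes = 10000,
                              seed, max_iter = 1e6) {
  check_scheme_matches(scheme, params$N)
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  if (episodes < 1) stop("episodes must be >= 1", call. = FALSE)
  N <- params$N
  if (N > 50) {
    warning("episode simulation is intended for small populations (N <= 50); ",
            "runtime grows quickly with N")
  }
  set.seed(seed)
  th <- scheme_theta(scheme)
  pr <- abm_adoption_probs(game, params, scheme)
  start_lo <- stats::runif(episodes) < 0.5
  k <- ifelse(start_lo, 1L, N - 1L)
  active <- rep(TRUE, episodes)
  visits <- matrix(0, episodes, N - 1)
  cost <- numeric(episodes)
  iter <- 0
  while (any(active)) {
    iter <- iter + 1
    if (iter > max_iter) {
      stop("max_iter reached before all episodes absorbed", call. = FALSE)
    }
    idx <- which(active)
    kk <- k[idx]
    cells <- cbind(idx, kk)
    visits[cells] <- visits[cells] + 1
    cost[idx] <- cost[idx] + th[kk]
    n <- length(idx)
    k[idx] <- kk <- abm_imitation_step(kk, N, pr$p_up, pr$p_down,
                                       stats::runif(n), stats::runif(n),
                                       stats::runif(n))
    active[idx] <- kk > 0 & kk < N
  }
  fixed_c <- k == N
  p_dc <- mean(fixed_c[start_lo])
  p_cd <- mean(!fixed_c[!start_lo])
  n_dc <- sum(start_lo); n_cd <- episodes - n_dc
  visit_mean <- colMeans(visits)
  visit_se <- apply(visits, 2, stats::sd) / sqrt(episodes)
  visit_tbl <- tibble::tibble(state = seq_len(N - 1),
                              visits = visit_mean, se = visit_se)
  structure(list(
    est_rho_dc = p_dc, se_rho_dc = sqrt(p_dc * (1 - p_dc) / n_dc),
    est_rho_cd = p_cd, se_rho_cd = sqrt(p_cd * (1 - p_cd) / n_cd),
    est_visits = visit_tbl,
    est_total_cost = mean(cost),
    se_total_cost = stats::sd(cost) / sqrt(episodes),
    episodes = episodes, seed = seed,
    game = game, params = params, scheme = scheme),
    class = "abm_episodes")
}

#' @export
print.abm_episodes <- function(x, ...) {
  cat("<abm_episodes>", x$episodes, "episodes (seed", paste0(x$seed, ")"), "\n")
  cat("  rho_DC =", signif(x$est_rho_dc, 4), "+/-", signif(x$se_rho_dc, 3),
      "  rho_CD =", signif(x$est_rho_cd, 4), "+/-", signif(x$se_rho_cd, 3), "\n")
  cat("  mean episode cost =", signif(x$est_total_cost, 5),
      "+/-", signif(x$se_total_cost, 3), "\n")
  invisible(x)
}

#' @rdname simulate_episodes
#' @param x an `abm_episodes` object.
#' @param ... unused.
#' @export
tidy.abm_episodes <- function(x, ...) x$est_visits

#' @rdname simulate_episodes
#' @export
glance.abm_episodes <- function(x, ...) {
  tibble::tibble(episodes = x$episodes,
                 est_rho_dc = x$est_rho_dc, se_rho_dc = x$se_rho_dc,
                 est_rho_cd = x$est_rho_cd, se_rho_cd = x$se_rho_cd,
                 est_total_cost = x$est_total_cost,
                 se_total_cost = x$se_total_cost)
}

#' Agent-based stationary simulation with explicit rare mutation
#'
#' Long-run simulation of the imitation process in which, with probability
#' `mu` per strategy-revision event, the revising individual adopts a
#' uniformly random strategy instead of imitating. For `mu` small enough
#' (the default `1e-3` for populations around `N = 10`; `mu <= 1/N^2` is a
#' good rule of thumb) the population is homogeneous almost all of the
#' time and the fraction of time spent in the all-cooperator state, among
#' time spent homogeneous, estimates the small-mutation-limit stationary
#' cooperation frequency of [cooperation_frequency()].
#'
#' Several independent chains are run in parallel from the all-defector
#' state; the estimate is the mean of per-chain conditional fractions and
#' its standard error is taken across chains. Chains shorter than the mean
#' homogeneous dwell time (about `2 / (mu * rho)` events) carry an
#' initial-state bias; increase `generations` when switching is rare.
#'
#' @inheritParams transition_probabilities
#' @param generations number of revision events per chain after burn-in.
#' @param chains number of independent replicate chains.
#' @param mu mutation probability per revision event, > 0.
#' @param burn_in events discarded at the start of each chain.
#' @param seed integer RNG seed (required).
#' @return An object of class `abm_stationary` with `est_coop_frequency`,
#'   its standard error, the fraction of time spent homogeneous, and the
#'   per-chain table.
#' @examples
#' sim <- simulate_stationary(pd_game(), evo_params(10, 0.5),
#'                            scheme_individual(2, 5, 10),
#'                            generations = 20000, chains = 5, seed = 1)
#' sim$est_coop_frequency
#' @export
simulate_stationary <- function(game, params, scheme, generations = 2e5,
                                chains = 20, mu = 1e-3,
                                burn_in = ceiling(generations / 10), seed) {
  check_scheme_matches(scheme, params$N)
  if (missing(seed)) stop("a seed is required for reproducibility", call. = FALSE)
  if (mu <= 0) stop("mu must be > 0 (the chain would absorb)", call. = FALSE)
  N <- params$N
  pr <- abm_adoption_probs(game, params, scheme)
  set.seed(seed)
  k <- rep(0L, chains)
  time_c <- numeric(chains)
  time_d <- numeric(chains)
  total <- burn_in + generations
  for (step in seq_len(total)) {
    u_focal <- stats::runif(chains)
    u_sel <- stats::runif(chains)
    u_model <- stats::runif(chains)
    u_adopt <- stats::runif(chains)
    focal_c <- u_focal < k / N
    mut <- u_sel < mu
    # mutation: the focal adopts a uniformly random strategy
    k_mut <- k + (!focal_c & u_model < 0.5) - (focal_c & u_model >= 0.5)
    # imitation: effective only in mixed states
    mixed <- k > 0 & k < N
    k_imit <- k
    if (any(mixed)) {
      km <- k[mixed]
      model_c <- u_model[mixed] < km / N
      up <- !focal_c[mixed] & model_c & u_adopt[mixed] < pr$p_up[km]
      down <- focal_c[mixed] & !model_c & u_adopt[mixed] < pr$p_down[km]
      k_imit[mixed] <- km + up - down
    }
    k <- ifelse(mut, k_mut, k_imit)
    if (step > burn_in) {
      time_c <- time_c + (k == N)
      time_d <- time_d + (k == 0)
    }
  }
  homog <- time_c + time_d
  per_chain <- tibble::tibble(chain = seq_len(chains), time_all_c = time_c,
                              time_all_d = time_d,
                              frac_homogeneous = homog / generations,
                              coop_fraction = ifelse(homog > 0, time_c / homog, NA))
  est <- mean(per_chain$coop_fraction, na.rm = TRUE)
  se <- stats::sd(per_chain$coop_fraction, na.rm = TRUE) /
    sqrt(sum(!is.na(per_chain$coop_fraction)))
  structure(list(est_coop_frequency = est, se_coop_frequency = se,
                 frac_homogeneous = mean(per_chain$frac_homogeneous),
                 per_chain = per_chain, mu = mu, chains = chains,
                 generations = generations, seed = seed,
                 game = game, params = params, scheme = scheme),
            class = "abm_stationary")
}

#' @export
print.abm_stationary <- function(x, ...) {
  cat("<abm_stationary>", x$chains, "chains x", x$generations,
      "events (mu =", x$mu, ")\n")
  cat("  cooperation fraction =", signif(x$est_coop_frequency, 4),
      "+/-", signif(x$se_coop_frequency, 3),
      "  (homogeneous", signif(100 * x$frac_homogeneous, 3), "% of time)\n")
  invisible(x)
}

#' @rdname simulate_stationary
#' @param x an `abm_stationary` object.
#' @param ... unused.
#' @export
tidy.abm_stationary <- function(x, ...) x$per_chain

#' @rdname simulate_stationary
#' @export
glance.abm_stationary <- function(x, ...) {
  tibble::tibble(chains = x$chains, generations = x$generations, mu = x$mu,
                 est_coop_frequency = x$est_coop_frequency,
                 se_coop_frequency = x$se_coop_frequency,
                 frac_homogeneous = x$frac_homogeneous)
}
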