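check_omega <- function(omega) {
  if (length(omega) != 1 || !is.finite(omega) || omega <= 0 || omega >= 1) {
    stop("target cooperation level omega must lie strictly in (0, 1) ",
         "(the sufficient condition diverges at the endpoints)", call. = FALSE)
  }
}

check_positive_beta <- function(params) {
  if (params$beta == 0) {
    stop("the sufficient conditions require beta > 0; under neutral ",
         "selection the cooperation level is 0.5 regardless of the scheme",
         call. = FALSE)
  }
}

#' Investment needed for a target cooperation level
#'
#' Because the stationary cooperation frequency depends on a scheme only
#' through `G = sum_k theta_k / k`, reaching at least an `omega` fraction of
#' cooperation is *exactly* equivalent to
#' `G >= (1/beta) log(omega / (1 - omega)) + N (T + P - R - S) / 2 + (R - P)`.
#' `g_bound()` returns that right-hand side. For the individual-based
#' family (`G = t * theta`) the bound converts into the minimal
#' per-individual investment at a given threshold (`min_theta()`) and the
#' minimal threshold at a given investment (`min_t()`).
#'
#' `min_t()` uses `ceiling(bound / theta - 1e-9)` so that analytically
#' exact integer boundaries are themselves admissible; if the required
#' threshold exceeds `N - 1` the target is infeasible at that `theta`.
#'
#' @param omega target cooperation fraction, strictly in (0, 1).
#' @param t investment threshold, integer in `1..N-1`.
#' @param theta per-individual investment, > 0 for `min_t()`.
#' @inheritParams transition_probabilities
#' @return `g_bound()` and `min_theta()` return scalars (`min_theta()`
#'   returns 0 when the bound is non-positive). `min_t()` returns a one-row
#'   tibble with `t_min` (the smallest admissible integer, possibly larger
#'   than `N - 1`) and `feasible`.
#' @examples
#' g <- pd_game(); p <- evo_params(100, 0.1)
#' g_bound(0.5, g, p)      # 101
#' min_t(1, 0.4, g, p)     # t_min = 97
#' min_t(5, 0.99, g, p)    # t_min = 30
#' @export
g_bound <- function(omega, game, params) {
  check_omega(omega)
  check_positive_beta(params)
  log(omega / (1 - omega)) / params$beta +
    params$N * (game$T + game$P - game$R - game$S) / 2 + (game$R - game$P)
}

#' @rdname g_bound
#' @export
min_theta <- function(t, omega, game, params) {
  if (length(t) != 1 || t != round(t) || t < 1 || t > params$N - 1) {
    stop("t must be an integer in 1..N-1", call. = FALSE)
  }
  max(g_bound(omega, game, params) / t, 0)
}

#' @rdname g_bound
#' @export
min_t <- function(theta, omega, game, params) {
  if (length(theta) != 1 || !is.finite(theta) || theta <= 0) {
    stop("theta must be a single number > 0", call. = FALSE)
  }
  b <- g_bound(omega, game, params)
  t_min <- max(1L, as.integer(ceiling(b / theta - 1e-9)))
  tibble::tibble(t_min = t_min, feasible = t_min <= params$N - 1,
                 g_bound = b, theta = theta, omega = omega)
}

# Full t-scan of the individual-based family at fixed (game, N, beta, theta):
# cooperation frequency (closed form) and expected cost (banded chain solve)
# for every threshold t in 1..N-1. Shared by optimal_threshold() and the
# experiment drivers, which reuse one scan across several omega values.
threshold_scan <- function(game, params, theta) {
  N <- params$N
  ts <- seq_len(N - 1)
  A <- N * (game$T + game$P - game$R - game$S) / 2 + (game$R - game$P)
  freq <- if (params$beta == 0) rep(0.5, N - 1) else
    stats::plogis(params$beta * (ts * theta - A))
  ec <- vapply(ts, function(t) ec_individual_fast(game, params, theta, t),
               c(ec = 0, events = 0))
  tibble::tibble(t = ts, coop_frequency = freq,
                 expected_cost = ec["ec", ], events = ec["events", ])
}

#' Cost-optimal investment threshold
#'
#' Scans every threshold `t` in `1..N-1` of the individual-based scheme
#' `(theta, t)`, computing the stationary cooperation frequency and the
#' expected total interference cost `EC`. Among the feasible thresholds
#' (frequency at least `omega`) it returns the one with minimal `EC`
#' (`t_star`; ties broken toward the smallest `t`, so the fewest states
#' trigger payment), together with the set of thresholds that beat the
#' always-invest baseline `t = N - 1` (FULL-INVEST).
#'
#' Under neutral selection (`beta = 0`) every scheme yields a cooperation
#' frequency of exactly 0.5, so the target is feasible iff `omega <= 0.5`
#' and the optimal policy is to invest nothing; this degenerate answer is
#' returned with `neutral_selection = TRUE` and zero cost.
#'
#' @param theta per-individual investment, > 0.
#' @param omega target cooperation fraction, strictly in (0, 1).
#' @inheritParams transition_probabilities
#' @return An object of class `threshold_opt` with fields `t_star`,
#'   `ec_at_t_star`, `feasible_set`, `better_than_full_set`, `feasible`,
#'   `neutral_selection` and the full scan `profile` tibble
#'   (`t`, `coop_frequency`, `expected_cost`, `events`, `feasible`).
#'   If no threshold reaches `omega`, `feasible = FALSE` and `t_star = NA`
#'   (no exception is thrown).
#' @examples
#' opt <- optimal_threshold(5, 0.9, pd_game(), evo_params(100, 0.1))
#' opt$t_star
#' @export
optimal_threshold <- function(theta, omega, game, params) {
  check_omega(omega)
  if (length(theta) != 1 || !is.finite(theta) || theta <= 0) {
    stop("theta must be a single number > 0", call. = FALSE)
  }
  N <- params$N
  ts <- seq_len(N - 1)
  if (params$beta == 0) {
    out <- list(t_star = NA_integer_, ec_at_t_star = 0,
                feasible_set = if (omega <= 0.5) ts else integer(0),
                better_than_full_set = integer(0),
                feasible = omega <= 0.5, neutral_selection = TRUE,
                profile = NULL, theta = theta, omega = omega,
                game = game, params = params)
    return(structure(out, class = "threshold_opt"))
  }
  profile <- threshold_scan(game, params, theta)
  profile$feasible <- profile$coop_frequency >= omega
  feas <- ts[profile$feasible]
  if (length(feas) == 0) {
    out <- list(t_star = NA_integer_, ec_at_t_star = NA_real_,
                feasible_set = integer(0), better_than_full_set = integer(0),
                feasible = FALSE, neutral_selection = FALSE,
                profile = profile, theta = theta, omega = omega,
                game = game, params = params)
    return(structure(out, class = "threshold_opt"))
  }
  ec_feas <- profile$expected_cost[feas]
  t_star <- feas[which.min(ec_feas)] # which.min takes the first minimiser
  ec_full <- profile$expected_cost[N - 1]
  better <- feas[ec_feas < ec_full]
  structure(list(t_star = as.integer(t_star),
                 ec_at_t_star = min(ec_feas),
                 feasible_set = as.integer(feas),
                 better_than_full_set = as.integer(better),
                 feasible = TRUE, neutral_selection = FALSE,
                 profile = profile, theta = theta, omega = omega,
                 game = game, params = params),
            class = "threshold_opt")
}

#' @export
print.threshold_opt <- function(x, ...) {
  if (x$neutral_selection) {
    cat("<threshold_opt> neutral selection (beta = 0): frequency 0.5 for any",
        "scheme;", if (x$feasible) "optimal to invest nothing (EC = 0)"
        else paste0("omega = ", x$omega, " unattainable"), "\n")
  } else if (!x$feasible) {
    cat("<threshold_opt> infeasible: no threshold reaches omega =", x$omega,
        "at theta =", x$theta, "\n")
  } else {
    cat("<threshold_opt> t* =", x$t_star, " EC(t*) =",
        signif(x$ec_at_t_star, 6), "\n  feasible t:",
        length(x$feasible_set), "thresholds; beating FULL-INVEST:",
        length(x$better_than_full_set), "\n")
  }
  invisible(x)
}

#' @rdname optimal_threshold
#' @param x a `threshold_opt`.
#' @param ... unused.
#' @export
tidy.threshold_opt <- function(x, ...) {
  if (is.null(x$profile)) return(tibble::tibble())
  x$profile
}

#' @rdname optimal_threshold
#' @export
glance.threshold_opt <- function(x, ...) {
  tibble::tibble(theta = x$theta, omega = x$omega, N = x$params$N,
                 beta = x$params$beta, feasible = x$feasible,
                 neutral_selection = x$neutral_selection,
                 t_star = x$t_star, ec_at_t_star = x$ec_at_t_star,
                 n_better_than_full = length(x$better_than_full_set))
}

#' @rdname optimal_threshold
#' @param object a `threshold_opt`.
#' @export
autoplot.threshold_opt <- function(object, ...) {
  if (is.null(object$profile)) {
    stop("no scan profile to plot (neutral selection)", call. = FALSE)
  }
  df <- tidyr_longer(object$profile)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "investment threshold t", y = NULL)
  if (object$feasible) {
    p <- p + ggplot2::geom_vline(xintercept = object$t_star, linetype = 2)
  }
  p
}

# minimal long-format reshape to avoid a hard tidyr dependency
tidyr_longer <- function(profile) {
  parts <- lapply(c("coop_frequency", "expected_cost", "events"),
                  function(q) tibble::tibble(t = profile$t, quantity = q,
                                             value = profile[[q]]))
  dplyr::bind_rows(parts)
}

#' Tabulate cooperation and cost over a parameter grid
#'
#' Data-frame-first driver for parameter sweeps: takes a tibble with
#' columns `theta`, `t`, `beta` (and optionally `omega`) and appends, for
#' each row, the stationary cooperation frequency, the expected cost, the
#' expected number of interference events, the scheme statistic `G`, and
#' (when `omega` is present) feasibility. Rows are processed in input
#' order and the computation is fully deterministic.
#'
#' @param grid a data frame with numeric columns `theta`, `t`, `beta`, and
#'   optionally `omega`.
#' @param game a [pd_game()].
#' @param N population size.
#' @return The input grid as a tibble with columns `coop_frequency`,
#'   `expected_cost`, `events`, `G` (and `feasible`) appended.
#' @examples
#' grid <- expand.grid(theta = c(1, 5), t = c(10, 50, 99), beta = 0.1)
#' sweep_interference(grid, pd_game(), N = 100)
#' @export
sweep_interference <- function(grid, game, N) {
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0) {
    out <- tibble::add_column(grid, coop_frequency = numeric(0),
                              expected_cost = numeric(0),
                              events = numeric(0), G = numeric(0))
    return(out)
  }
  need <- c("theta", "t", "beta")
  if (!all(need %in% names(grid))) {
    stop("grid must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  res <- purrr::pmap(grid[need], function(theta, t, beta) {
    params <- evo_params(N, beta)
    sch <- scheme_individual(theta, t, N)
    freq <- cooperation_frequency(game, params, sch)$coop_frequency
    ec <- ec_individual_fast(game, params, theta, t)
    tibble::tibble(coop_frequency = freq, expected_cost = ec[["ec"]],
                   events = ec[["events"]], G = t * theta)
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(res))
  if ("omega" %in% names(grid)) {
    out$feasible <- out$coop_frequency >= out$omega
  }
  out
}
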