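write_experiment <- function(df, out_dir, name, parameters) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                   row.names = FALSE)
  manifest <- list(
    experiment = name, parameters = parameters,
    package = "coopcost",
    version = as.character(utils::packageVersion("coopcost")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, paste0(name, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Cooperation, interference events and cost versus the threshold
#'
#' Scans the individual-based scheme over thresholds `t` for several
#' per-individual investments `theta`, reporting for each `(theta, t)` the
#' stationary cooperation frequency, the expected number of interference
#' events (visits to paying states), and the expected total cost `EC`.
#' With the default parameters (`R = 1, T = 2, P = 0, S = -1`, `N = 100`,
#' `beta = 0.1`, `theta` in 1, 5, 40) this reproduces the package's
#' standard threshold-profile experiment: cooperation is non-decreasing in
#' `t`, while `EC` is non-monotone, with an interior cost minimum for
#' moderate `theta`. Stored values are never log-scaled; any scaling is a
#' plotting concern (see [plot_threshold_profile()]).
#'
#' @param game a [pd_game()].
#' @param N population size.
#' @param beta selection intensity.
#' @param thetas per-individual investment values to profile.
#' @param ts thresholds to scan (default all of `1..N-1`).
#' @param out_dir optional directory; when given, the table is written as
#'   CSV together with a JSON manifest of parameters and package version.
#' @return A tibble with columns `theta`, `t`, `coop_frequency`, `events`,
#'   `expected_cost`.
#' @export
threshold_profile <- function(game = pd_game(), N = 100, beta = 0.1,
                              thetas = c(1, 5, 40), ts = seq_len(N - 1),
                              out_dir = NULL) {
  params <- evo_params(N, beta)
  out <- purrr::map(thetas, function(th) {
    sc <- threshold_scan(game, params, th)
    sc <- sc[sc$t %in% ts, ]
    tibble::add_column(sc, theta = th, .before = 1)
  })
  out <- dplyr::bind_rows(out)[, c("theta", "t", "coop_frequency",
                                   "events", "expected_cost")]
  write_experiment(out, out_dir, "threshold_profile",
                   list(game = unclass(game), N = N, beta = beta,
                        thetas = thetas))
  out
}

#' @rdname threshold_profile
#' @param profile a tibble from `threshold_profile()`.
#' @param log10_scale log10-transform the events and cost panels (display
#'   only; the underlying values are unscaled).
#' @export
plot_threshold_profile <- function(profile, log10_scale = TRUE) {
  parts <- lapply(c("coop_frequency", "events", "expected_cost"), function(q) {
    v <- profile[[q]]
    if (log10_scale && q != "coop_frequency") v <- log10(v)
    tibble::tibble(theta = profile$theta, t = profile$t, quantity = q, value = v)
  })
  df <- dplyr::bind_rows(parts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = factor(.data$theta))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~.data$quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "investment threshold t", y = NULL,
                  colour = expression(theta))
}

#' Map of the cost-optimal threshold t*
#'
#' For each combination of selection intensity `beta`, target cooperation
#' level `omega` and per-individual investment `theta`, finds the
#' cost-optimal threshold `t*` (see [optimal_threshold()]) and its expected
#' cost. Infeasible cells -- where no threshold reaches `omega` -- are
#' recorded with `NA` rather than dropped. One t-scan per `(beta, theta)`
#' is shared across all `omega` values.
#'
#' @inheritParams threshold_profile
#' @param betas,omegas,thetas grids of selection intensities, target
#'   levels, and per-individual investments.
#' @return A tibble `(beta, omega, theta, feasible, t_star, ec_at_t_star,
#'   ec_full_invest, n_better_than_full)`.
#' @export
optimal_threshold_map <- function(game = pd_game(), N = 100,
                                  betas = c(0.001, 0.01, 0.1, 1),
                                  omegas = c(0.1, 0.5, 0.7, 0.9),
                                  thetas = seq(0.5, 50, by = 0.5),
                                  out_dir = NULL) {
  rows <- list()
  for (beta in betas) {
    params <- evo_params(N, beta)
    for (th in thetas) {
      sc <- threshold_scan(game, params, th)
      ec_full <- sc$expected_cost[N - 1]
      for (om in omegas) {
        feas <- sc$t[sc$coop_frequency >= om]
        if (length(feas) == 0) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            beta = beta, omega = om, theta = th, feasible = FALSE,
            t_star = NA_integer_, ec_at_t_star = NA_real_,
            ec_full_invest = ec_full, n_better_than_full = 0L)
        } else {
          ec_feas <- sc$expected_cost[feas]
          rows[[length(rows) + 1]] <- tibble::tibble(
            beta = beta, omega = om, theta = th, feasible = TRUE,
            t_star = as.integer(feas[which.min(ec_feas)]),
            ec_at_t_star = min(ec_feas),
            ec_full_invest = ec_full,
            n_better_than_full = sum(ec_feas < ec_full))
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  write_experiment(out, out_dir, "optimal_threshold_map",
                   list(game = unclass(game), N = N, betas = betas,
                        omegas = omegas, thetas = thetas))
  out
}

#' Thresholds beating the always-invest baseline
#'
#' For each `(beta, omega, theta)` combination, determines the set of
#' thresholds `t` whose individual-based scheme both reaches the target
#' cooperation level `omega` and costs strictly less than FULL-INVEST
#' (`t = N - 1`). Reports the size and extent of that set; its aggregate
#' size over the `theta` grid shrinks as selection intensifies.
#'
#' @inheritParams optimal_threshold_map
#' @return A tibble `(beta, omega, theta, feasible, n_better, t_better_min,
#'   t_better_max, ec_full_invest)`; `n_better` is the number of thresholds
#'   beating FULL-INVEST, and the min/max give the extent of that set
#'   (`NA` when empty).
#' @export
full_invest_comparison <- function(game = pd_game(), N = 100,
                                   betas = c(0.01, 0.1),
                                   omegas = c(0.1, 0.5, 0.9),
                                   thetas = seq(0.5, 50, by = 0.5),
                                   out_dir = NULL) {
  rows <- list()
  for (beta in betas) {
    params <- evo_params(N, beta)
    for (th in thetas) {
      sc <- threshold_scan(game, params, th)
      ec_full <- sc$expected_cost[N - 1]
      for (om in omegas) {
        better <- sc$t[sc$coop_frequency >= om & sc$expected_cost < ec_full]
        rows[[length(rows) + 1]] <- tibble::tibble(
          beta = beta, omega = om, theta = th,
          feasible = any(sc$coop_frequency >= om),
          n_better = length(better),
          t_better_min = if (length(better)) min(better) else NA_integer_,
          t_better_max = if (length(better)) max(better) else NA_integer_,
          ec_full_invest = ec_full)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  write_experiment(out, out_dir, "full_invest_comparison",
                   list(game = unclass(game), N = N, betas = betas,
                        omegas = omegas, thetas = thetas))
  out
}
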