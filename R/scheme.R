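#' Interference schemes: state-conditioned investment in cooperators
#'
#' An interference scheme specifies, for every mixed population state with
#' `i` cooperators (`i = 1, ..., N-1`), the *total* amount `theta_i` the
#' external decision-maker invests in that state. The amount is split
#' equally, so each cooperator's average payoff rises by `theta_i / i`.
#' Nothing is paid at the homogeneous (absorbing) states.
#'
#' `interference_scheme()` builds a general scheme from an arbitrary
#' non-negative vector of length `N - 1`. `scheme_individual()` builds the
#' individual-based family: each cooperator receives a fixed per-capita
#' amount `theta` whenever the cooperator count does not exceed the
#' threshold `t`, i.e. `theta_k = k * theta` for `k <= t` and 0 otherwise.
#' `scheme_full_invest()` is the extreme case `t = N - 1` (the standard
#' institutional-reward baseline in which cooperators are always paid), and
#' `scheme_zero()` invests nothing.
#'
#' @param theta for `interference_scheme()`: numeric vector of length
#'   `N - 1` of non-negative per-state total investments; for the
#'   individual-based constructors: a single non-negative per-individual
#'   amount (payoff units).
#' @param N population size (must match the `evo_params` used downstream).
#' @param t investment threshold, an integer in `1..N-1`.
#' @return An object of class `interference_scheme` with fields `theta`
#'   (the per-state totals), `N`, `family`, and for the individual-based
#'   family also `theta_per_capita` and `t`.
#' @examples
#' scheme_individual(theta = 5, t = 30, N = 100)
#' scheme_full_invest(theta = 1, N = 100)
#' interference_scheme(rep(2, 9), N = 10)
#' @export
interference_scheme <- function(theta, N) {
  N <- as.integer(N)
  if (length(theta) != N - 1) {
    stop("theta must have length N - 1 = ", N - 1, call. = FALSE)
  }
  if (any(!is.finite(theta)) || any(theta < 0)) {
    stop("all per-state investments theta_i must be finite and >= 0",
         call. = FALSE)
  }
  structure(list(theta = as.numeric(theta), N = N, family = "general"),
            class = "interference_scheme")
}

#' @rdname interference_scheme
#' @export
scheme_individual <- function(theta, t, N) {
  N <- as.integer(N)
  if (length(theta) != 1 || !is.finite(theta) || theta < 0) {
    stop("per-individual investment theta must be a single number >= 0",
         call. = FALSE)
  }
  if (length(t) != 1 || t != round(t) || t < 1 || t > N - 1) {
    stop("threshold t must be an integer in 1..N-1", call. = FALSE)
  }
  k <- seq_len(N - 1)
  vec <- ifelse(k <= t, k * theta, 0)
  structure(list(theta = vec, N = N,
                 family = if (t == N - 1L) "full_invest" else "individual_based",
                 theta_per_capita = as.numeric(theta), t = as.integer(t)),
            class = "interference_scheme")
}

#' @rdname interference_scheme
#' @export
scheme_full_invest <- function(theta, N) {
  scheme_individual(theta, t = N - 1L, N = N)
}

#' @rdname interference_scheme
#' @export
scheme_zero <- function(N) {
  interference_scheme(rep(0, N - 1L), N)
}

#' @export
print.interference_scheme <- function(x, ...) {
  cat("<interference_scheme> family =", x$family, " N =", x$N, "\n")
  if (!is.null(x$theta_per_capita)) {
    cat("  per-individual theta =", x$theta_per_capita, " threshold t =", x$t, "\n")
  }
  cat("  total invested mass sum(theta_i) =", sum(x$theta),
      "  G = sum(theta_i / i) =", g_statistic(x), "\n")
  invisible(x)
}

# 1-based accessor: scheme_theta(s)[k] is the total investment at the state
# with k cooperators (k = 1..N-1). Internal storage is already 1-based.
scheme_theta <- function(scheme) scheme$theta

check_scheme_matches <- function(scheme, N) {
  if (!inherits(scheme, "interference_scheme")) {
    stop("scheme must be an interference_scheme", call. = FALSE)
  }
  if (scheme$N != N) {
    stop("scheme was built for N = ", scheme$N,
         " but the population has N = ", N, call. = FALSE)
  }
}

#' Scheme investment statistic G
#'
#' The scalar `G = sum_k theta_k / k` through which a scheme determines the
#' stationary cooperation frequency: two schemes with equal `G` yield the
#' same cooperation level regardless of how the investment is spread over
#' states. For the individual-based family `G = t * theta` exactly.
#'
#' @param scheme an [interference_scheme()].
#' @return The scalar G (payoff units).
#' @examples
#' g_statistic(scheme_individual(theta = 5, t = 30, N = 100)) # 150
#' @export
g_statistic <- function(scheme) {
  if (identical(scheme$family, "individual_based") ||
      identical(scheme$family, "full_invest")) {
    return(scheme$t * scheme$theta_per_capita)
  }
  k <- seq_along(scheme$theta)
  sum(scheme$theta / k)
}

#' Read and write interference schemes
#'
#' Schemes serialise to a small JSON object
#' `{"N":..., "family":..., "theta_per_capita":..., "t":..., "theta_vector":[...]}`.
#' General schemes may also be read from a 2-column CSV of
#' `(state index i, theta_i)` covering every state `1..N-1`.
#'
#' @param scheme an [interference_scheme()].
#' @param path file path.
#' @return `read_scheme_json()` and `read_scheme_csv()` return an
#'   `interference_scheme`; the writers return `path` invisibly.
#' @export
write_scheme_json <- function(scheme, path) {
  obj <- list(N = scheme$N, family = scheme$family,
              theta_per_capita = scheme$theta_per_capita,
              t = scheme$t, theta_vector = scheme$theta)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scheme_json
#' @export
read_scheme_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$family %in% c("individual_based", "full_invest")) {
    scheme_individual(obj$theta_per_capita, obj$t, obj$N)
  } else {
    interference_scheme(obj$theta_vector, obj$N)
  }
}

#' @rdname write_scheme_json
#' @export
read_scheme_csv <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("expected columns (state, theta)", call. = FALSE)
  i <- as.integer(df[[1]])
  N <- max(i) + 1L
  if (!setequal(i, seq_len(N - 1))) {
    stop("state indices must cover 1..N-1 exactly", call. = FALSE)
  }
  interference_scheme(df[[2]][order(i)], N)
}
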