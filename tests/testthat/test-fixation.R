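test_that("neutral drift gives fixation 1/N and 50% cooperation exactly", {
  g <- std_game()
  set.seed(3)
  for (N in c(2, 10, 100)) {
    p <- evo_params(N, 0)
    for (sch in list(scheme_zero(N), random_scheme(N))) {
      f <- fixation_probabilities(g, p, sch)
      expect_identical(f$rho_dc, 1 / N)
      expect_identical(f$rho_cd, 1 / N)
      expect_identical(cooperation_frequency(g, p, sch)$coop_frequency, 0.5)
    }
  }
})

test_that("fixation probabilities match brute-force absorption solves", {
  g <- std_game()
  # N = 2: closed form is the single-step Fermi ratio normalisation
  p2 <- evo_params(2, 0.7)
  s2 <- scheme_zero(2)
  d1 <- coopcost:::delta_k(1, g, p2, s2)
  f2 <- fixation_probabilities(g, p2, s2)
  expect_equal(f2$rho_dc, plogis(0.7 * d1), tolerance = 1e-12)
  orc2 <- oracle_absorption(g, p2, s2)
  expect_equal(f2$rho_dc, orc2$rho_dc, tolerance = 1e-10)

  # N = 10 with and without interference, against dense first-step solves
  set.seed(14)
  for (i in 1:10) {
    gg <- if (i <= 5) g else random_pd_game()
    p <- evo_params(10, runif(1, 0, 1))
    sch <- random_scheme(10)
    f <- fixation_probabilities(gg, p, sch)
    orc <- oracle_absorption(gg, p, sch)
    expect_equal(f$rho_dc, orc$rho_dc, tolerance = 1e-9)
    expect_equal(f$rho_cd, orc$rho_cd, tolerance = 1e-9)
  }
})

test_that("product-form and closed-form log-ratios agree", {
  set.seed(8)
  for (i in 1:40) {
    g <- random_pd_game()
    N <- sample(3:200, 1)
    p <- evo_params(N, runif(1, 0.01, 2))
    sch <- random_scheme(N)
    lr_prod <- fixation_probabilities(g, p, sch)$log_ratio
    lr_closed <- cooperation_ratio_log(g, p, sch)
    expect_equal(lr_prod, lr_closed, tolerance = 1e-8)
  }
})

test_that("the log-ratio depends on a scheme only through G", {
  g <- std_game()
  p <- evo_params(30, 0.3)
  s1 <- scheme_individual(2, 10, 30)          # G = 20
  th <- rep(0, 29); th[5] <- 5 * 20           # G = theta_5 / 5 = 20, concentrated
  s2 <- interference_scheme(th, 30)
  expect_equal(g_statistic(s1), g_statistic(s2))
  expect_equal(cooperation_ratio_log(g, p, s1), cooperation_ratio_log(g, p, s2))
  expect_equal(fixation_probabilities(g, p, s1)$log_ratio,
               fixation_probabilities(g, p, s2)$log_ratio, tolerance = 1e-10)
})

test_that("cooperation frequency increases with any single theta_k", {
  g <- std_game()
  p <- evo_params(20, 0.4)
  set.seed(5)
  base <- runif(19, 0, 2)
  f0 <- cooperation_frequency(g, p, interference_scheme(base, 20))$coop_frequency
  for (k in c(1, 7, 19)) {
    th <- base; th[k] <- th[k] + 1
    f1 <- cooperation_frequency(g, p, interference_scheme(th, 20))$coop_frequency
    expect_gt(f1, f0)
  }
})

test_that("target-level equivalence: frequency >= omega iff G >= bound", {
  g <- std_game()
  set.seed(16)
  for (i in 1:25) {
    N <- sample(c(20, 50, 100), 1)
    p <- evo_params(N, runif(1, 0.02, 1))
    omega <- runif(1, 0.05, 0.95)
    theta <- runif(1, 0.1, 10)
    t <- sample(N - 1, 1)
    freq <- cooperation_frequency(g, p, scheme_individual(theta, t, N))$coop_frequency
    b <- g_bound(omega, g, p)
    if (t * theta >= b + 1e-9) expect_gte(freq, omega)
    if (t * theta <= b - 1e-9) expect_lt(freq, omega)
  }
})

test_that("the standard scheme theta = 5, t = 30 sustains 99% cooperation", {
  out <- cooperation_frequency(std_game(), evo_params(100, 0.1),
                               scheme_individual(5, 30, 100))
  expect_gte(out$coop_frequency, 0.99)
  td <- tidy(out)
  expect_named(td, c("rho_dc", "rho_cd", "log_ratio", "coop_frequency", "G"))
  expect_equal(td$coop_frequency,
               td$rho_dc / (td$rho_dc + td$rho_cd), tolerance = 1e-12)
})

test_that("stationary distribution solves the homogeneous-state chain", {
  # two strategies, order (D, C)
  rho <- matrix(c(NA, 0.02, 0.02, NA), 2, 2)
  expect_equal(stationary_distribution(rho), c(0.5, 0.5))
  rho <- matrix(c(NA, 0.01, 0.03, NA), 2, 2) # rho_DC = 0.03 = 3 * rho_CD
  expect_equal(stationary_distribution(rho), c(0.25, 0.75))
  # three strategies, all fixation probabilities equal -> uniform
  rho3 <- matrix(0.1, 3, 3)
  expect_equal(stationary_distribution(rho3), rep(1 / 3, 3))
  # detailed-balance-free case cross-checked by long-run matrix powers
  set.seed(2)
  rho3 <- matrix(runif(9, 0.01, 0.2), 3, 3)
  pi3 <- stationary_distribution(rho3)
  M <- rho3 / 2; diag(M) <- 0; diag(M) <- 1 - rowSums(M)
  P <- M
  for (i in 1:200) P <- P %*% M
  expect_equal(pi3, as.numeric(P[1, ]), tolerance = 1e-8)
  expect_error(stationary_distribution(matrix(1, 2, 2)[, 1, drop = FALSE]),
               "square")
})
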