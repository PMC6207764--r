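test_that("the transient matrix has the birth-death structure", {
  g <- std_game()
  p <- evo_params(3, 0.2)
  sch <- scheme_zero(3)
  ch <- transient_chain(g, p, sch)
  tr <- transition_probabilities(1:2, g, p, sch)
  expect_equal(dim(ch$U), c(2, 2))
  expect_equal(ch$U[1, 1], 1 - tr$t_plus[1] - tr$t_minus[1])
  expect_equal(ch$U[1, 2], tr$t_plus[1])
  expect_equal(ch$U[2, 1], tr$t_minus[2])
  expect_equal(ch$U[2, 2], 1 - tr$t_plus[2] - tr$t_minus[2])

  # neutral N = 4: off-diagonals are k(4-k)/32
  ch4 <- transient_chain(g, evo_params(4, 0), random_scheme(4))
  k <- 1:3
  expect_equal(ch4$U[cbind(1:2, 2:3)], (k * (4 - k) / 32)[1:2])
  expect_equal(ch4$U[cbind(2:3, 1:2)], (k * (4 - k) / 32)[2:3])

  # interior rows are stochastic; rows 1 and N-1 leak to the absorbers
  ch10 <- transient_chain(g, evo_params(10, 0.5), scheme_individual(1, 4, 10))
  rs <- rowSums(ch10$U)
  expect_equal(rs[2:8], rep(1, 7))
  expect_equal(rs[1], 1 - ch10$t_minus[1])
  expect_equal(rs[9], 1 - ch10$t_plus[9])
})

test_that("expected visits match hand and dense oracles", {
  g <- std_game()
  # N = 3 neutral: (I-U)^-1 = [[6,3],[3,6]] by hand, so v = (4.5, 4.5)
  ch3 <- transient_chain(g, evo_params(3, 0), scheme_zero(3))
  expect_equal(expected_visits(ch3), c(4.5, 4.5), tolerance = 1e-12)

  # random draws kept in the benign (well-conditioned) regime, where the
  # dense and banded solves are themselves trustworthy
  set.seed(31)
  for (i in 1:12) {
    gg <- random_pd_game()
    N <- sample(c(2, 5, 10, 40), 1)
    p <- evo_params(N, runif(1, 0, 0.3))
    sch <- random_scheme(N, max_theta = 1.5)
    ch <- transient_chain(gg, p, sch)
    va <- expected_visits(ch)
    expect_true(all(va > 0))
    expect_equal(va, oracle_visits(gg, p, sch), tolerance = 1e-8)
    expect_equal(va, expected_visits(ch, method = "banded"), tolerance = 1e-8)
  }

  # N = 100 under FULL-INVEST: monotone drift, still benign
  g100 <- std_game()
  p100 <- evo_params(100, 0.1)
  ch100 <- transient_chain(g100, p100, scheme_full_invest(5, 100))
  expect_equal(expected_visits(ch100),
               oracle_visits(g100, p100, scheme_full_invest(5, 100)),
               tolerance = 1e-8)
})

test_that("the log-space visits stay finite and ordered in metastable regimes", {
  # strong selection with an interior attractor: visits are astronomical at
  # intermediate thresholds, and EC must dwarf the FULL-INVEST cost there
  g <- std_game()
  p <- evo_params(100, 1)
  ec <- function(t) {
    ch <- transient_chain(g, p, scheme_individual(5, t, 100))
    sum(expected_visits(ch) * coopcost:::scheme_theta(ch$scheme))
  }
  expect_gt(ec(59), 1e15)
  expect_gt(ec(59), ec(95))
  expect_gt(ec(95), ec(99))
})

test_that("expected cost is the visit-weighted investment", {
  g <- std_game()
  p <- evo_params(10, 0.5)
  sch <- scheme_individual(2, 5, 10)
  ch <- transient_chain(g, p, sch)
  cr <- expected_cost(ch)
  v <- expected_visits(ch)
  th <- coopcost:::scheme_theta(sch)
  expect_equal(cr$expected_cost, sum(v * th))
  expect_equal(cr$expected_interference_events, sum(v[th > 0]))
  expect_equal(tidy(cr)$cost, v * th)

  # all-zero scheme costs nothing
  cr0 <- expected_cost(transient_chain(g, p, scheme_zero(10)))
  expect_identical(cr0$expected_cost, 0)
  expect_identical(cr0$expected_interference_events, 0)

  # linearity in theta on a fixed chain
  sch3 <- interference_scheme(3 * th, 10)
  cr3 <- expected_cost(ch, sch3)
  expect_equal(cr3$expected_cost, 3 * cr$expected_cost)

  expect_error(expected_cost(ch, scheme_zero(12)), "dimension")
})

test_that("absorption probabilities from the chain reproduce fixation", {
  set.seed(44)
  for (i in 1:8) {
    g <- random_pd_game()
    N <- sample(c(5, 10, 30), 1)
    p <- evo_params(N, runif(1, 0, 0.8))
    sch <- random_scheme(N, max_theta = 2)
    ab <- chain_absorption(transient_chain(g, p, sch))
    f <- fixation_probabilities(g, p, sch)
    expect_equal(ab$rho_dc, f$rho_dc, tolerance = 1e-8)
    expect_equal(ab$rho_cd, f$rho_cd, tolerance = 1e-8)
  }
})

test_that("spreading the investment can reduce its total cost", {
  # at beta = 0.1, theta = 5 there are thresholds below N-1 that both sustain
  # >= 90% cooperation and cost less than always investing
  g <- std_game()
  p <- evo_params(100, 0.1)
  scan <- coopcost:::threshold_scan(g, p, 5)
  ec_full <- scan$expected_cost[99]
  better <- scan$t[scan$coop_frequency >= 0.9 & scan$expected_cost < ec_full]
  expect_gt(length(better), 0)
  expect_true(all(better < 99))
})
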