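test_that("the G bound reproduces hand-computed values", {
  g <- std_game()
  p <- evo_params(100, 0.1)
  expect_equal(g_bound(0.5, g, p), 101)
  expect_equal(g_bound(0.4, g, p), 101 + 10 * log(2 / 3))
  # continuity through omega = 0.5
  expect_equal(g_bound(0.5 + 1e-9, g, p), 101, tolerance = 1e-6)
  expect_equal(g_bound(0.5 - 1e-9, g, p), 101, tolerance = 1e-6)
  expect_error(g_bound(0, g, p), "\\(0, 1\\)")
  expect_error(g_bound(1, g, p), "\\(0, 1\\)")
  expect_error(g_bound(0.5, g, evo_params(100, 0)), "beta > 0")
})

test_that("minimal per-individual investment inverts the bound", {
  g <- std_game()
  p <- evo_params(100, 0.1)
  expect_equal(min_theta(99, 0.5, g, p), 101 / 99)
  # duality with the printed t >= 97 statement at theta = 1, omega = 0.4
  expect_lte(min_theta(97, 0.4, g, p), 1)
  expect_gt(min_theta(96, 0.4, g, p), 1)
  # non-positive bound: any investment suffices
  expect_identical(min_theta(50, 0.01, g, evo_params(100, 0.01)), 0)
  expect_error(min_theta(0, 0.5, g, p), "1..N-1")
})

test_that("minimal thresholds reproduce the printed integers", {
  g <- std_game()
  p <- evo_params(100, 0.1)
  expect_identical(min_t(1, 0.4, g, p)$t_min, 97L)
  r <- min_t(1, 0.5, g, p)
  expect_identical(r$t_min, 101L)
  expect_false(r$feasible)
  expect_identical(min_t(5, 0.99, g, p)$t_min, 30L)
  expect_identical(min_t(40, 0.99, g, p)$t_min, 4L)
  expect_error(min_t(0, 0.5, g, p), "> 0")
})

test_that("min_t is exact at integer boundaries and dual to min_theta", {
  g <- std_game()
  p <- evo_params(100, 0.1)
  # omega = 0.5 makes the bound exactly 101: the boundary integer qualifies
  expect_identical(min_t(101 / 99, 0.5, g, p)$t_min, 99L)
  set.seed(6)
  for (i in 1:15) {
    om <- runif(1, 0.55, 0.99)
    t <- sample(2:99, 1)
    th <- min_theta(t, om, g, p)
    expect_identical(min_t(th, om, g, p)$t_min, t)
    # the guaranteed scheme really reaches omega
    f <- cooperation_frequency(g, p, scheme_individual(th, t, 100))
    expect_gte(f$coop_frequency, om - 1e-12)
  }
})

test_that("threshold optimisation finds intermediate optima when selection is weak", {
  g <- std_game()
  opt <- optimal_threshold(5, 0.9, g, evo_params(100, 0.1))
  expect_true(opt$feasible)
  expect_lt(opt$t_star, 99)
  expect_gte(opt$t_star, min_t(5, 0.9, g, evo_params(100, 0.1))$t_min)
  expect_lt(opt$ec_at_t_star, opt$profile$expected_cost[99])
  expect_true(all(opt$better_than_full_set %in% opt$feasible_set))
  expect_equal(opt$ec_at_t_star,
               min(opt$profile$expected_cost[opt$profile$feasible]))
  # frequency at t_star really clears the target
  expect_gte(opt$profile$coop_frequency[opt$t_star], 0.9)

  # strong selection: always invest
  opt1 <- optimal_threshold(5, 0.5, g, evo_params(100, 1))
  expect_identical(opt1$t_star, 99L)

  # infeasible target: explicit marker, no exception
  opt_inf <- optimal_threshold(1, 0.5, g, evo_params(100, 0.1))
  expect_false(opt_inf$feasible)
  expect_true(is.na(opt_inf$t_star))

  # glance/tidy surface
  gl <- glance(opt)
  expect_identical(gl$t_star, opt$t_star)
  expect_identical(nrow(tidy(opt)), 99L)
})

test_that("neutral selection short-circuits the optimisation", {
  g <- std_game()
  p0 <- evo_params(50, 0)
  opt <- optimal_threshold(2, 0.4, g, p0)
  expect_true(opt$neutral_selection)
  expect_true(opt$feasible)
  expect_identical(opt$ec_at_t_star, 0)
  opt2 <- optimal_threshold(2, 0.7, g, p0)
  expect_false(opt2$feasible)
})

test_that("sweeps agree with direct calls and handle empty grids", {
  g <- std_game()
  grid <- tibble::tibble(theta = 5, t = 30, beta = 0.1, omega = 0.9)
  sw <- sweep_interference(grid, g, N = 100)
  direct <- cooperation_frequency(g, evo_params(100, 0.1),
                                  scheme_individual(5, 30, 100))
  ch <- transient_chain(g, evo_params(100, 0.1), scheme_individual(5, 30, 100))
  cr <- expected_cost(ch)
  expect_equal(sw$coop_frequency, direct$coop_frequency)
  expect_equal(sw$expected_cost, cr$expected_cost)
  expect_equal(sw$events, cr$expected_interference_events)
  expect_equal(sw$G, 150)
  expect_true(sw$feasible)

  empty <- sweep_interference(tibble::tibble(theta = numeric(0),
                                             t = numeric(0),
                                             beta = numeric(0)), g, 100)
  expect_identical(nrow(empty), 0L)
  expect_error(sweep_interference(tibble::tibble(x = 1), g, 100), "columns")
})
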