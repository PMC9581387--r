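test_that("condition objects derive loss probability and mean winning face", {
  conds <- standard_conditions()
  expect_identical(vapply(conds, `[[`, 0, "zbar"),
                   c("1/6" = 4, "2/6" = 4.25, "3/6" = 4))
  expect_identical(vapply(conds, `[[`, 0, "p_lose"),
                   c("1/6" = 1 / 6, "2/6" = 2 / 6, "3/6" = 3 / 6))
  custom <- game_condition(c(2, 5), label = "custom")
  expect_equal(custom$zbar, mean(c(1, 3, 4, 6)))
  expect_error(game_condition(integer(0)), "proper subset")
  expect_error(game_condition(1:6), "proper subset")
  expect_error(game_condition(7), "proper subset")
})

test_that("expected utilities follow the stop/continue decomposition", {
  c16 <- game_condition(1)
  eu <- expected_utilities(0, c16, alpha = 1)
  expect_equal(eu$eu_stop, 0)
  expect_equal(eu$eu_continue, 40 * 5 / 6)
  # indifference at the risk-neutral IPs, including the printed 2/6 value 85
  eu <- expected_utilities(200, c16, alpha = 1)
  expect_equal(eu$eu_continue, eu$eu_stop)
  eu <- expected_utilities(85, game_condition(c(1, 3)), alpha = 1)
  expect_equal(eu$eu_continue, eu$eu_stop)
  expect_error(expected_utilities(-5, c16), "nonnegative")
  expect_error(expected_utilities(10, c16, alpha = 0), "positive")
})

test_that("analytic indifference points are exact at alpha = 1", {
  conds <- standard_conditions()
  expect_identical(indifference_point(conds[["1/6"]], 1), 200)
  expect_identical(indifference_point(conds[["2/6"]], 1), 85)
  expect_identical(indifference_point(conds[["3/6"]], 1), 40)
})

test_that("general-alpha IP matches a bisection oracle on the EU equality", {
  # independent oracle: root of EU_continue(s) - EU_stop(s) by bisection
  bisect_ip <- function(cond, alpha) {
    f <- function(s) (s + cond$zbar * 10)^alpha * (1 - cond$p_lose) - s^alpha
    lo <- 1e-6; hi <- 5000
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  for (alpha in c(0.6, 0.8, 1.3)) {
    for (cond in standard_conditions()) {
      expect_equal(indifference_point(cond, alpha), bisect_ip(cond, alpha),
                   tolerance = 1e-8)
    }
  }
  expect_equal(indifference_point(game_condition(1), 0.8), 156.3,
               tolerance = 1e-3)
})

test_that("softmax stop probability is calibrated and monotone", {
  c16 <- game_condition(1)
  ag <- agent_params(1, 0.2)
  # exactly 1/2 at the indifference point, for several preference profiles
  for (a in c(0.7, 1, 1.4)) {
    for (cond in standard_conditions()) {
      ip <- indifference_point(cond, a)
      expect_equal(stop_probability(ip, cond, agent_params(a, 0.37)), 0.5)
    }
  }
  expect_equal(stop_probability(0, c16, ag), 1 / (1 + exp(0.2 * 100 / 3)),
               tolerance = 1e-10)
  expect_equal(stop_probability(0, c16, ag), 0.00127, tolerance = 2e-3)
  # zero sensitivity: indifferent everywhere
  expect_equal(stop_probability(c(0, 50, 500), c16, agent_params(1, 0)),
               rep(0.5, 3))
  # strictly increasing in the cumulative sum for alpha <= 1
  s <- seq(0, 600, by = 10)
  for (a in c(0.8, 1)) {
    p <- stop_probability(s, c16, agent_params(a, 0.2))
    expect_true(all(diff(p) > 0))
  }
  # extreme sensitivity approaches a hard threshold at the IP
  hard <- agent_params(1, 1e6)
  expect_lt(stop_probability(190, c16, hard), 1e-6)
  expect_gt(stop_probability(210, c16, hard), 1 - 1e-6)
})

test_that("simulate_round follows the task rules on forced face sequences", {
  c16 <- game_condition(1)
  timing <- timing_model()
  always_stop_after3 <- function(s) as.numeric(s >= 130)
  set.seed(1)
  rnd <- simulate_round(NULL, c16, timing, faces = c(3, 5, 5),
                        policy = always_stop_after3)
  expect_equal(rnd$payoff, 130)
  expect_false(rnd$lost)
  expect_equal(rnd$decisions$cum_sum, c(30, 80, 130))
  expect_equal(rnd$decisions$choice, c("continue", "continue", "stop"))
  rnd <- simulate_round(NULL, c16, timing, faces = c(3, 3, 4, 1),
                        policy = function(s) 0)
  expect_equal(rnd$payoff, 0)
  expect_true(rnd$lost)
  expect_equal(nrow(rnd$decisions), 3L)
  # losing face on the first (automatic) roll: no decisions, no payoff
  rnd <- simulate_round(NULL, c16, timing, faces = 1,
                        policy = function(s) 1)
  expect_equal(nrow(rnd$decisions), 0L)
  expect_equal(rnd$payoff, 0)
  # elapsed time accrues animation + displays within the stated grid
  rnd <- simulate_round(NULL, c16, timing, faces = c(4, 1),
                        policy = function(s) 0)
  expect_gte(rnd$elapsed, 2 * 1.5 + 2 + 2)
  expect_lte(rnd$elapsed, 2 * 3.75 + 2 + 2)
})

test_that("per-roll loss rate converges to the condition loss probability", {
  set.seed(77)
  for (cl in c("1/6", "3/6")) {
    cond <- standard_conditions()[[cl]]
    ag <- agent_params(1, 0.2)
    losses <- 0; rolls <- 0
    for (r in 1:400) {
      rnd <- simulate_round(ag, cond)
      losses <- losses + rnd$lost
      rolls <- rolls + rnd$n_rolls
    }
    phat <- losses / rolls
    tol <- 4 * sqrt(cond$p_lose * (1 - cond$p_lose) / rolls)
    expect_lt(abs(phat - cond$p_lose), tol)
  }
})

test_that("risk-neutral payoff is maximized near the 200-point threshold", {
  set.seed(12)
  cond <- game_condition(1)
  mean_payoff <- function(thr) {
    pol <- function(s) as.numeric(s >= thr)
    mean(vapply(1:600, function(i)
      simulate_round(NULL, cond, policy = pol)$payoff, numeric(1)))
  }
  pay <- vapply(c(100, 200, 300), mean_payoff, numeric(1))
  expect_gt(pay[2], pay[1])
  expect_gt(pay[2], pay[3])
})

test_that("bonus is a tenth of the mean round payoff", {
  expect_equal(compute_bonus(c(130, 0)), 6.5)
  expect_equal(compute_bonus(c(0, 0, 0)), 0)
  expect_equal(compute_bonus(c(200, 100, 0)), 10)
  expect_error(compute_bonus(numeric(0)), "nonempty")
})
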