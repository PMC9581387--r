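# A minimal hand-built choice_fit for unit-testing the derived quantities
# without MCMC: two participants, one condition, fixed coefficient draws.
fake_choice_fit <- function(b0 = c(-4, -4), b1 = c(0.02, 0.02),
                            cum_sum = seq(20, 400, by = 20)) {
  cells <- data.frame(index = 1:2, participant_id = c("p01", "p02"),
                      condition_label = "1/6", stringsAsFactors = FALSE)
  draws <- matrix(rep(c(mean(b0), 0.5, mean(b1), 0.01, b0, b1), each = 4),
                  nrow = 4)
  colnames(draws) <- c("mu_b0", "sigma_b0", "mu_b1", "sigma_b1",
                       "b0[1]", "b0[2]", "b1[1]", "b1[2]")
  data <- data.frame(
    participant_id = rep(c("p01", "p02"), each = length(cum_sum)),
    condition_label = "1/6", round_index = 1L,
    decision_index = seq_along(cum_sum), cum_sum = rep(cum_sum, 2),
    choice = "continue", rt = NA_real_, session_order = 1L,
    stringsAsFactors = FALSE)
  structure(list(draws = draws, cells = cells, conditions = "1/6",
                 data = data,
                 group = list("1/6" = list(mu_b0 = draws[, "mu_b0"],
                                           mu_b1 = draws[, "mu_b1"])),
                 rhat = c(mu_b0 = 1, mu_b1 = 1)),
            class = "choice_fit")
}

test_that("logistic IP formula is exact and rescaling-invariant", {
  expect_equal(ip_from_coefficients(-4, 0.02), 200)
  expect_equal(ip_from_coefficients(0, 0.5), 0)
  expect_equal(ip_from_coefficients(-4 * 3, 0.02 * 3), 200)
  expect_error(ip_from_coefficients(-4, 0), "undefined")
})

test_that("conflict series is the logistic derivative with its maximum at the IP", {
  fit <- fake_choice_fit(cum_sum = c(50, 100, 200, 300, 400, 600))
  cs <- conflict_series(fit)
  p <- plogis(-4 + 0.02 * cs$cum_sum)
  expect_equal(cs$conflict, 0.02 * p * (1 - p))
  # maximal value |b1|/4 at the IP, symmetric in p about one half
  at_ip <- conflict_series(fit, transform(fit$data[1, ], cum_sum = 200))
  expect_equal(at_ip$conflict, 0.02 / 4)
  expect_true(all(cs$conflict <= 0.02 / 4 + 1e-12))
  lo <- conflict_series(fit, transform(fit$data[1, ], cum_sum = 150))
  hi <- conflict_series(fit, transform(fit$data[1, ], cum_sum = 250))
  expect_equal(lo$conflict, hi$conflict, tolerance = 1e-10)
  far <- conflict_series(fit, transform(fit$data[1, ], cum_sum = 5000))
  expect_lt(far$conflict, 1e-12)
})

test_that("conflict collinearity is near one below the IP and drops past it", {
  # decisions all below the IP: conflict rises monotonically with cum_sum
  below <- fake_choice_fit(cum_sum = seq(20, 180, by = 20))
  cc <- conflict_value_collinearity(conflict_series(below))
  expect_equal(cc$per_cell$rho, rep(1, 2))
  # decisions straddling the IP: rank correlation clearly below one
  straddle <- fake_choice_fit(cum_sum = seq(20, 400, by = 20))
  cc2 <- conflict_value_collinearity(conflict_series(straddle))
  expect_true(all(cc2$per_cell$rho < 0.5))
  # constant series is reported missing, not an error
  flat <- fake_choice_fit(b1 = c(1e-30, 1e-30), cum_sum = c(100, 110, 120))
  cc3 <- conflict_value_collinearity(conflict_series(flat))
  expect_true(all(is.na(cc3$per_cell$rho)))
})

test_that("odds ratio and Bayesian R2 follow their definitions", {
  fit <- fake_choice_fit()
  summ <- choice_fit_summaries(fit)
  expect_equal(summ$odds_ratio, exp(0.02))
  # the paper-scale slope: exp(0.0392) rounds to 1.04
  expect_equal(round(exp(0.0392), 2), 1.04)
  # null slope explains nothing
  null_fit <- fake_choice_fit(b0 = c(0.3, 0.3), b1 = c(1e-12, 1e-12))
  expect_lt(choice_fit_summaries(null_fit)$r2_median, 1e-10)
  # near-separated data push R2 toward its upper bound
  steep <- fake_choice_fit(b0 = c(-40, -40), b1 = c(0.2, 0.2))
  expect_gt(choice_fit_summaries(steep)$r2_median, 0.8)
})

test_that("degenerate all-continue cells are excluded from the hierarchy", {
  fx <- small_population_fit()
  trials <- fx$sim$trials
  bad <- data.frame(participant_id = "deg01", condition_label = "1/6",
                    round_index = 1:30, decision_index = 1L,
                    cum_sum = 40, choice = "continue", rt = NA_real_,
                    session_order = 1L, stringsAsFactors = FALSE)
  fit <- fit_choice_model(rbind(trials, bad),
                          mcmc_settings(chains = 1, iter = 400,
                                        warmup = 200, seed = 1))
  expect_true("deg01" %in% fit$excluded$participant_id)
  expect_false("deg01" %in% fit$cells$participant_id)
})

test_that("the fitted model recovers the simulated choice structure", {
  fx <- small_population_fit()
  fit <- fx$fit
  # positive group slope in every condition (stopping rises with reward)
  for (cl in fit$conditions) {
    expect_gt(quantile(fit$group[[cl]]$mu_b1, 0.05), 0)
  }
  # posterior-predictive stop curve is monotone nondecreasing in cum_sum
  co <- pigdice:::cell_coefficients(fit)
  expect_true(all(co$b1 > 0))
  # group IP ordering follows the conditions' analytic ordering
  ips <- vapply(fit$conditions, function(cl) mean(fit$group[[cl]]$ip),
                numeric(1))
  expect_true(ips[["3/6"]] < ips[["2/6"]] &&
                ips[["2/6"]] < ips[["1/6"]])
  # IP equals -b0/b1 draw-wise
  g <- fit$group[["1/6"]]
  expect_equal(g$ip, -g$mu_b0 / g$mu_b1)
})
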