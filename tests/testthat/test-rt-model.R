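# Log-normal RT data generated directly from the regression model with known
# coefficients, for recovery checks.
make_rt_data <- function(J = 8, n = 120, g = c(-0.6, -0.004, 0.03, 0.001),
                         sd_res = 0.2, seed = 17) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(J), function(j) {
    r <- sort(sample(1:30, n, replace = TRUE))
    t <- sample(1:8, n, replace = TRUE)
    s <- sample(seq(20, 400, by = 20), n, replace = TRUE)
    m <- g[1] + g[2] * r + g[3] * t + g[4] * s
    data.frame(participant_id = sprintf("p%02d", j), condition_label = "1/6",
               round_index = r, decision_index = t, cum_sum = s,
               choice = "continue", rt = exp(rnorm(n, m, sd_res)),
               session_order = 1L, stringsAsFactors = FALSE)
  }))
}

test_that("the RT regression recovers generating coefficients and scale", {
  d <- make_rt_data()
  fit <- fit_rt_model(d, NULL, mcmc_settings(chains = 2, iter = 1200,
                                             warmup = 600, seed = 7))
  g <- fit$group[["1/6"]]
  truth <- c(mu_g0 = -0.6, mu_g1 = -0.004, mu_g2 = 0.03, mu_g3 = 0.001)
  for (p in names(truth)) {
    h <- hdi(g[[p]])
    expect_true(h[1] <= truth[p] && truth[p] <= h[2],
                label = sprintf("%s HDI [%.4f, %.4f] covers %.4f",
                                p, h[1], h[2], truth[p]))
  }
  # residual-scale posterior concentrates on the generating value
  expect_equal(mean(g$sigma_res), 0.2, tolerance = 0.1)
})

test_that("a zero-slope generator leaves all slope HDIs straddling zero", {
  d <- make_rt_data(J = 6, n = 80, g = c(-0.5, 0, 0, 0), seed = 23)
  fit <- fit_rt_model(d, NULL, mcmc_settings(chains = 2, iter = 1000,
                                             warmup = 500, seed = 8))
  g <- fit$group[["1/6"]]
  for (p in c("mu_g1", "mu_g2", "mu_g3")) {
    h <- hdi(g[[p]])
    expect_true(h[1] < 0 && h[2] > 0, label = p)
  }
})

test_that("fitting is equivariant under shifting the round regressor", {
  d <- make_rt_data(J = 5, n = 60, seed = 31)
  d2 <- d; d2$round_index <- d2$round_index + 50L
  mc <- mcmc_settings(chains = 1, iter = 1500, warmup = 700, seed = 9)
  f1 <- fit_rt_model(d, NULL, mc)
  f2 <- fit_rt_model(d2, NULL, mc)
  for (p in c("mu_g1", "mu_g2", "mu_g3")) {
    expect_equal(mean(f1$group[["1/6"]][[p]]), mean(f2$group[["1/6"]][[p]]),
                 tolerance = 0.15, label = p)
  }
  # the intercept absorbs the shift: g0 drops by 50 * g1
  m2 <- mean(f1$group[["1/6"]]$mu_g0) - 50 * mean(f1$group[["1/6"]]$mu_g1)
  expect_equal(mean(f2$group[["1/6"]]$mu_g0), m2, tolerance = 0.15)
})

test_that("rows without usable RTs are dropped with a count", {
  d <- make_rt_data(J = 3, n = 30, seed = 5)
  d$rt[c(1, 11, 21)] <- NA
  d$rt[2] <- 0
  fit <- fit_rt_model(d, NULL, mcmc_settings(chains = 1, iter = 300,
                                             warmup = 150, seed = 2))
  expect_equal(fit$n_dropped, 4L)
  expect_equal(nrow(fit$data), nrow(d) - 4L)
})

test_that("post-IP OLS slopes recover constructed RT trends", {
  ips <- data.frame(participant_id = "p01", condition_label = "1/6", ip = 150)
  base <- data.frame(participant_id = "p01", condition_label = "1/6",
                     round_index = 1:20, decision_index = 1:20,
                     cum_sum = seq(160, 540, by = 20), choice = "continue",
                     session_order = 1L, stringsAsFactors = FALSE)
  # constant RT past the IP: slope exactly zero
  flat <- transform(base, rt = 0.8)
  res <- post_ip_rt_slopes(flat, ips)
  expect_equal(res$per_cell$slope, 0)
  # linear decline of -0.002 s/point with small noise: recovered within SE
  set.seed(19)
  dec <- transform(base, rt = 1.5 - 0.002 * cum_sum + rnorm(20, 0, 0.01))
  res <- post_ip_rt_slopes(dec, ips)
  expect_equal(res$per_cell$slope, -0.002, tolerance = 0.15)
  expect_lt(res$per_cell$p_value, 0.01)
  expect_equal(res$summary$share_p_below_.01, 1)
  # cells with too few post-IP decisions are skipped and counted
  few <- transform(base[1:2, ], rt = 0.8)
  res <- post_ip_rt_slopes(few, ips)
  expect_equal(res$n_skipped, 1L)
})

test_that("posterior predictive buckets expose conflict- vs value-driven RTs", {
  fx <- make_ddm_trials(n_participants = 6, n_trials = 90, seed = 59)
  tr <- fx$trials
  mc <- mcmc_settings(chains = 1, iter = 800, warmup = 400, seed = 3)
  cf <- fit_choice_model(tr, mc)
  conf <- conflict_series(cf, tr)
  # conflict-driven generator (DDM): RT peaks in the max-conflict bucket
  rf <- fit_rt_model(tr, conf, mc)
  set.seed(4)
  pp <- rt_posterior_predictive_by_pstop(rf, cf, bins = 8, n_draws = 100)
  expect_gt(pp$contrast$predicted_diff, 0)
  expect_equal(nrow(pp$table), 8L)
  # value-driven generator (RT proportional to cum_sum): monotone profile,
  # so the max-p(stop) bucket is the slowest and the contrast flips sign
  tr2 <- tr
  tr2$rt <- 0.3 + 0.004 * tr2$cum_sum + abs(rnorm(nrow(tr2), 0, 0.02))
  rf2 <- fit_rt_model(tr2, conflict_series(cf, tr2), mc)
  pp2 <- rt_posterior_predictive_by_pstop(rf2, cf, bins = 8, n_draws = 100)
  expect_lt(pp2$contrast$predicted_diff, 0)
  filled <- which(!is.na(pp2$table$predicted_mean_rt) & pp2$table$n > 5)
  expect_gt(cor(pp2$table$p_stop_mid[filled],
                pp2$table$predicted_mean_rt[filled], method = "spearman"),
            0.8)
})
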