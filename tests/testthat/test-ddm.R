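test_that("the model space enumerates exactly 19 variants", {
  space <- ddm_model_space()
  expect_equal(nrow(space), 19L)
  expect_equal(anyDuplicated(space$variant_id), 0L)
  expect_equal(sum(space$is_baseline), 1L)
  base <- space[space$is_baseline, ]
  expect_true(all(base[, c("drift_modulator", "threshold_modulator",
                           "start_modulator")] == "none"))
  # drift is always modulated outside the baseline (2 x 3 x 3 grid)
  nb <- space[!space$is_baseline, ]
  expect_setequal(unique(nb$drift_modulator),
                  c("cumulative_sum", "decision_number"))
  expect_equal(nrow(nb), 18L)
  # the all-cumulative-sum variant (the winning model class) is a member
  expect_true("d.cs_a.cs_z.cs" %in% space$variant_id)
  # stable ordering across calls
  expect_identical(space, ddm_model_space())
  expect_error(ddm_variant("no-such-model"), "unknown")
})

test_that("IP from drift coefficients is a scale-invariant zero crossing", {
  expect_equal(ip_from_drift(-2, 0.02), 100)
  expect_equal(ip_from_drift(-2 * 7.3, 0.02 * 7.3), 100)
  draws <- ip_from_drift(c(-1, -2, -4), c(0.01, 0.02, 0.04))
  expect_equal(draws, rep(100, 3))
  expect_error(ip_from_drift(-2, 0), "undefined")
})

test_that("generated DDM datasets behave like the generating process", {
  set.seed(31)
  design <- data.frame(participant_id = "p01", condition_label = "3/6",
                       round_index = 1:400, decision_index = 1L,
                       cum_sum = rep(c(20, 40, 60, 80), 100))
  # zero drift, centered start: even stop odds regardless of covariates
  tp0 <- data.frame(participant_id = "p01", d0 = 0, d1 = 0, a0 = 1.2,
                    z0 = 0, ter = 0.3)
  dd <- generate_ddm_dataset("baseline", tp0, design)
  expect_equal(mean(dd$choice == "stop"), 0.5, tolerance = 0.12)
  expect_true(all(dd$rt > 0.3))
  # strong positive drift: stopping dominates and responses speed up
  tp_fast <- transform(tp0, d0 = 4)
  fast <- generate_ddm_dataset("baseline", tp_fast, design)
  expect_gt(mean(fast$choice == "stop"), 0.95)
  expect_lt(mean(fast$rt), mean(dd$rt))
  # drift modulation: stop rate rises with the cumulative sum
  tpm <- data.frame(participant_id = "p01", d0 = -2, d1 = 0.04, a0 = 1.2,
                    z0 = 0, ter = 0.3)
  dm <- generate_ddm_dataset("d.cs_a.fix_z.fix", tpm, design)
  sr <- tapply(dm$choice == "stop", dm$cum_sum, mean)
  expect_true(all(diff(sr[order(as.numeric(names(sr)))]) > 0))
  expect_error(generate_ddm_dataset("baseline", transform(tp0, ter = -1),
                                    design), "nonnegative")
})

test_that("waic matches its definition and degenerates correctly", {
  set.seed(5)
  ll <- matrix(rnorm(200, -1, 0.3), 20, 10)
  w <- waic(ll)
  lpd <- log(colMeans(exp(ll)))
  pw <- apply(ll, 2, var)
  expect_equal(w$waic, -2 * sum(lpd - pw))
  expect_equal(w$p_waic, sum(pw))
  expect_equal(w$se, sqrt(10 * var(-2 * (lpd - pw))))
  # identical models: zero WAIC difference
  expect_equal(waic(ll)$waic - waic(ll)$waic, 0)
  # a single draw has no variance penalty
  one <- ll[1, , drop = FALSE]
  expect_equal(waic(one)$waic, -2 * sum(one))
  expect_equal(waic(one)$p_waic, 0)
  expect_error(waic(cbind(ll, Inf)), "finite")
})

test_that("a small hierarchical fit recovers drift structure", {
  fx <- make_ddm_trials(n_participants = 5, n_trials = 60, seed = 77)
  fit <- fit_ddm(fx$trials, "d.cs_a.fix_z.fix",
                 ddm_mcmc_settings(chains = 2, iter = 900, warmup = 500,
                                   keep = 100, seed = 5))
  expect_s3_class(fit, "ddm_fit")
  f <- fit$fits[["3/6"]]
  expect_equal(dim(f$loglik), c(dim(f$psi)[1], nrow(f$data)))
  expect_true(all(is.finite(f$loglik)))
  expect_equal(nrow(f$group), 2 * 400)
  # drift slope posterior concentrates on the generating sign and scale
  expect_gt(mean(f$group[, "mu_d1"]), 0)
  summ <- ddm_group_summary(fit)
  ip <- summ[summ$parameter == "ip", ]
  true_ip <- mean(-fx$true_params$d0 / fx$true_params$d1)
  expect_gt(ip$upper, true_ip * 0.6)
  expect_lt(ip$lower, true_ip * 1.4)
  w <- waic(fit)
  expect_true(is.finite(w$waic) && w$p_waic > 0)
})

test_that("posterior predictives reproduce the conflict RT profile", {
  fx <- make_ddm_trials(n_participants = 6, n_trials = 80, seed = 42)
  fit <- fit_ddm(fx$trials, "d.cs_a.fix_z.fix",
                 ddm_mcmc_settings(chains = 2, iter = 900, warmup = 500,
                                   keep = 100, seed = 6))
  set.seed(9)
  pp <- ddm_posterior_predictive(fit, bins = 8, n_draws = 25)
  tab <- pp$table
  expect_equal(nrow(tab), 8L)
  filled <- !is.na(tab$observed_mean_rt)
  # observed and replicated bucket means agree on well-specified data
  expect_true(all(tab$predicted_lower[filled] <=
                    tab$observed_mean_rt[filled] + 0.25))
  expect_true(all(tab$predicted_upper[filled] >=
                    tab$observed_mean_rt[filled] - 0.25))
  # replicated mean RT declines from the maximum-conflict bucket to the
  # maximum-stop-probability bucket
  expect_gt(pp$contrast$predicted_diff, 0)
  expect_false(is.null(pp$past_ip))
  expect_true(all(pp$past_ip$fraction_past_ip >= 0 &
                    pp$past_ip$fraction_past_ip <= 1))
})
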