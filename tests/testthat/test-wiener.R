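test_that("link functions match their closed forms", {
  expect_equal(threshold_link(0), log(2))
  expect_equal(threshold_link(5), 5.0067, tolerance = 1e-4)
  expect_lt(threshold_link(-40), 1e-15)
  expect_gt(threshold_link(-40), 0)
  expect_equal(threshold_link(800), 800)  # stable for large predictors
  expect_equal(start_link(0), 0.5)
  expect_equal(start_link(1.96), 0.975, tolerance = 1e-3)
  z <- start_link(0.1, 0.01, seq(-50, 50, 5))
  expect_true(all(diff(z) > 0) && all(z > 0 & z < 1))
  # drift is linear and flips sign exactly at the implied IP
  expect_equal(drift_link(-2, 0.02, 100), 0)
  expect_equal(drift_link(-2, 0, 300), -2)
  eps <- 1e-9
  expect_lt(drift_link(-2, 0.02, 100 - eps), 0)
  expect_gt(drift_link(-2, 0.02, 100 + eps), 0)
})

test_that("wiener density is symmetric at zero drift and centered start", {
  rt <- seq(0.35, 3, length.out = 40)
  up <- wiener_logpdf(rt, "stop", 0, 1.4, 0.3, 0.5)
  lo <- wiener_logpdf(rt, "continue", 0, 1.4, 0.3, 0.5)
  expect_equal(up, lo, tolerance = 1e-9)
  expect_true(all(is.finite(up)))
  # zero likelihood below the non-decision time
  expect_identical(wiener_logpdf(0.2, "stop", 1, 1, 0.3), -Inf)
})

test_that("stop-coded density equals the drift-negated continue density", {
  # the likelihood convention: evaluating the upper boundary under drift v
  # is the same as the lower boundary under -v with mirrored start
  set.seed(8)
  for (i in 1:10) {
    v <- runif(1, -3, 3); a <- runif(1, 0.7, 1.8); w <- runif(1, 0.25, 0.75)
    rt <- runif(5, 0.1, 2.5)
    expect_equal(wiener_logpdf(rt, "stop", v, a, 0, w),
                 wiener_logpdf(rt, "continue", -v, a, 0, 1 - w),
                 tolerance = 1e-10)
  }
})

test_that("density integrates to the analytic absorption probabilities", {
  set.seed(3)
  for (i in 1:6) {
    v <- runif(1, -2.5, 2.5); a <- runif(1, 0.7, 1.6); w <- runif(1, 0.3, 0.7)
    p_up <- wiener_p_stop(v, a, w)
    int_up <- integrate(function(t)
      exp(wiener_logpdf(t, "stop", v, a, 0, w)), 0, 60,
      rel.tol = 1e-9)$value
    int_lo <- integrate(function(t)
      exp(wiener_logpdf(t, "continue", v, a, 0, w)), 0, 60,
      rel.tol = 1e-9)$value
    expect_equal(int_up, p_up, tolerance = 1e-6)
    expect_equal(int_up + int_lo, 1, tolerance = 1e-6)
  }
  # degenerate cases of the absorption probability
  expect_equal(wiener_p_stop(0, 1.2, 0.37), 0.37)
  expect_gt(wiener_p_stop(8, 1.5, 0.5), 0.999)
  expect_lt(wiener_p_stop(-30, 2, 0.5), 1e-10)
})

test_that("sampler choices and RTs agree with the density", {
  set.seed(14)
  v <- 0.8; a <- 1.2; w <- 0.45; t0 <- 0.3
  n <- 30000
  s <- rwiener_trials(rep(v, n), a, t0, w)
  p_up <- wiener_p_stop(v, a, w)
  expect_equal(mean(s$choice == "stop"), p_up,
               tolerance = 4 * sqrt(p_up * (1 - p_up) / n) / p_up)
  expect_true(all(s$rt > t0))
  # binned stop-side RT distribution versus integrated conditional density
  rts <- s$rt[s$choice == "stop"] - t0
  qs <- quantile(rts, c(0.25, 0.5, 0.75))
  dens <- function(t) exp(wiener_logpdf(t + t0, "stop", v, a, t0, w)) / p_up
  for (q in c(0.25, 0.5, 0.75)) {
    mass <- integrate(dens, 0, quantile(rts, q), rel.tol = 1e-8)$value
    expect_equal(mass, q, tolerance = 0.03)
  }
})

test_that("drift of zero with centered start yields even odds; strong drift dominates", {
  set.seed(6)
  s <- rwiener_trials(rep(0, 8000), 1.3, 0.25, 0.5)
  expect_equal(mean(s$choice == "stop"), 0.5, tolerance = 0.05)
  fast <- rwiener_trials(rep(4, 2000), 1.3, 0.25, 0.5)
  slow <- rwiener_trials(rep(0.5, 2000), 1.3, 0.25, 0.5)
  expect_gt(mean(fast$choice == "stop"), 0.95)
  expect_lt(mean(fast$rt), mean(slow$rt))  # mean RT decreasing in |drift|
})

test_that("expected decision time peaks where drift crosses zero", {
  # the model-embodied conflict signature: for fixed boundary and start the
  # mean first-passage time is maximal at the indifference point
  mean_fpt <- function(v) {
    f <- function(t) t * (exp(wiener_logpdf(t, "stop", v, 1.4, 0, 0.5)) +
                          exp(wiener_logpdf(t, "continue", v, 1.4, 0, 0.5)))
    integrate(f, 0, 80, rel.tol = 1e-8)$value
  }
  vs <- c(-2, -1, -0.4, 0, 0.4, 1, 2)
  m <- vapply(vs, mean_fpt, numeric(1))
  expect_equal(which.max(m), which(vs == 0))
  expect_true(all(diff(m[vs <= 0]) > 0) && all(diff(m[vs >= 0]) < 0))
})
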