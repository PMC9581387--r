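# Shared fixture builders. Everything is generated in code under fixed seeds;
# the heavier fixtures are memoized so several test files can reuse them.

fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, builder) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, builder(), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

# Per-participant DDM coefficients around given group means.
make_ddm_params <- function(n, d0 = -1.5, d1 = 0.035, a0 = 1.3, z0 = 0,
                            ter_lo = 0.25, ter_hi = 0.4, a1 = NULL,
                            z1 = NULL) {
  out <- data.frame(
    participant_id = sprintf("p%02d", seq_len(n)),
    d0 = stats::rnorm(n, d0, 0.25),
    d1 = stats::rnorm(n, d1, abs(d1) / 6),
    a0 = stats::rnorm(n, a0, 0.15),
    z0 = stats::rnorm(n, z0, 0.1),
    ter = stats::runif(n, ter_lo, ter_hi),
    stringsAsFactors = FALSE
  )
  if (!is.null(a1)) out$a1 <- stats::rnorm(n, a1, abs(a1) / 6 + 1e-12)
  if (!is.null(z1)) out$z1 <- stats::rnorm(n, z1, abs(z1) / 6 + 1e-12)
  out
}

# A joint choice/RT dataset from the drift-modulated DDM in a 3/6-like
# regime (balanced decisions around the implied indifference point).
make_ddm_trials <- function(n_participants = 8, n_trials = 80, seed = 101,
                            condition = standard_conditions()[["3/6"]],
                            variant = "d.cs_a.fix_z.fix", ...) {
  set.seed(seed)
  design <- simulate_task_design(n_participants, n_trials, condition)
  tp <- make_ddm_params(n_participants, ...)
  list(trials = generate_ddm_dataset(variant, tp, design), true_params = tp)
}

# Small simulated softmax-agent population with a fitted choice model,
# reused by the choice/RT/pipeline tests.
small_population_fit <- function() {
  memoize("small_population_fit", function() {
    spec <- population_spec(n_agents = 10, duration_min = 10, seed = 303)
    sim <- population_past_ip_summary(spec)
    fit <- fit_choice_model(
      sim$trials, mcmc_settings(chains = 2, iter = 1000, warmup = 500,
                                seed = 303))
    list(spec = spec, sim = sim, fit = fit)
  })
}
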