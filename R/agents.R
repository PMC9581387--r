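#' Fraction of decisions past an indifference point
#'
#' Share of decision points whose cumulative sum exceeds the indifference
#' point. The discrete reward grid puts an atom of decisions exactly at the
#' IP whenever the IP is a multiple of 10 (e.g. the risk-neutral IPs 200 and
#' 40); there the stop probability is exactly one half and the decision is
#' maximally ambiguous, so the atom is attributed half to each side. For the
#' continuous IPs of heterogeneous-alpha populations the tie term vanishes.
#'
#' @param cum_sum cumulative sums at the decision points.
#' @param ip indifference point in points.
#' @return Fraction in `[0, 1]` (NA for empty input).
#' @export
fraction_past_ip <- function(cum_sum, ip) {
  if (length(cum_sum) == 0L) return(NA_real_)
  mean((cum_sum > ip) + 0.5 * (cum_sum == ip))
}

#' Softplus transform
#'
#' `log(1 + exp(x))`, evaluated stably for large positive and negative `x`.
#' Used both for the positive-valued agent-parameter distributions and as the
#' threshold link of the diffusion model.
#'
#' @param x numeric vector.
#' @return Numeric vector of the same length, strictly positive.
#' @export
softplus <- function(x) {
  # log1p(exp(x)) overflows for large x; x + log1p(exp(-x)) is exact there
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

#' Mean of a softplus-transformed normal
#'
#' `E[softplus(X)]` for `X ~ Normal(location, scale)`, by quadrature.
#'
#' @param location,scale normal parameters (`scale > 0`).
#' @return Scalar mean.
#' @export
softplus_normal_mean <- function(location, scale) {
  stopifnot(scale > 0)
  stats::integrate(function(x) softplus(x) * stats::dnorm(x, location, scale),
                   lower = location - 10 * scale, upper = location + 10 * scale,
                   rel.tol = 1e-10)$value
}

#' Normal location giving a softplus-normal a target mean
#'
#' Solves `E[softplus(Normal(m, scale))] = target_mean` for `m`. Used to build
#' populations with a stated mean risk curvature (e.g. a risk-averse
#' population with mean alpha 0.8) when only the mean is specified.
#'
#' @param target_mean desired mean of the transformed variable (> 0).
#' @param scale normal scale (> 0).
#' @return The location `m`.
#' @export
solve_softplus_location <- function(target_mean, scale = 0.3) {
  stopifnot(target_mean > 0, scale > 0)
  stats::uniroot(function(m) softplus_normal_mean(m, scale) - target_mean,
                 interval = c(-20, 20), tol = 1e-10)$root
}

#' Specify a simulated agent population
#'
#' Agents have risk curvature `alpha = softplus(Normal(alpha_location,
#' alpha_scale))` and softmax sensitivity `theta = softplus(Normal(
#' theta_location, theta_scale))`. The defaults (0.5, 0.3) and (-1.5, 0.3)
#' give a population that is risk-neutral on average (mean alpha close to 1)
#' with mean sensitivity close to 0.2.
#'
#' @param n_agents number of agents.
#' @param alpha_location,alpha_scale normal parameters behind alpha.
#' @param theta_location,theta_scale normal parameters behind theta.
#' @param duration_min simulated session length per condition, minutes.
#' @param conditions list of [game_condition()] objects.
#' @param seed integer seed governing population draws and session play.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n_agents = 100, alpha_location = 0.5,
                            alpha_scale = 0.3, theta_location = -1.5,
                            theta_scale = 0.3, duration_min = 20,
                            conditions = standard_conditions(), seed = 1L) {
  stopifnot(n_agents >= 1, alpha_scale > 0, theta_scale > 0, duration_min > 0)
  structure(list(
    n_agents = as.integer(n_agents),
    alpha_location = alpha_location, alpha_scale = alpha_scale,
    theta_location = theta_location, theta_scale = theta_scale,
    duration_min = duration_min, conditions = conditions,
    seed = as.integer(seed)
  ), class = "population_spec")
}

#' A risk-averse population preset
#'
#' Same as [population_spec()] but with the alpha location solved numerically
#' so the population mean risk curvature equals `mean_alpha` (default 0.8).
#'
#' @param mean_alpha target mean alpha.
#' @param ... passed to [population_spec()].
#' @export
risk_averse_spec <- function(mean_alpha = 0.8, ...) {
  loc <- solve_softplus_location(mean_alpha, 0.3)
  population_spec(alpha_location = loc, alpha_scale = 0.3, ...)
}

#' Draw agent parameters for a population
#'
#' @param spec a [population_spec()].
#' @return Data frame with `agent_id`, `alpha`, `theta`, one row per agent.
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  data.frame(
    agent_id = sprintf("agent%03d", seq_len(spec$n_agents)),
    alpha = softplus(stats::rnorm(spec$n_agents, spec$alpha_location, spec$alpha_scale)),
    theta = softplus(stats::rnorm(spec$n_agents, spec$theta_location, spec$theta_scale)),
    stringsAsFactors = FALSE
  )
}

#' Simulate a timed session of the 'pig' dice game
#'
#' Plays rounds via [simulate_round()] until the simulated clock reaches
#' `duration_min` minutes; the session may end mid-round, in which case the
#' partial round's decisions still count. Returns the canonical trial table
#' together with the fraction of decision points past the agent's own analytic
#' indifference point.
#'
#' Randomness comes from R's global RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param agent an [agent_params()].
#' @param condition a [game_condition()].
#' @param duration_min session length in minutes.
#' @param timing a [timing_model()].
#' @param participant_id id string recorded in the trial table.
#' @param session_order 1-based position of this condition in the session.
#' @param policy optional stop-probability override (see [simulate_round()]).
#' @return List of class `session_result`: `trials` (data frame with
#'   `participant_id`, `condition_label`, `round_index`, `decision_index`,
#'   `cum_sum`, `choice`, `rt`, `session_order`), `n_rounds`, `n_decisions`,
#'   `fraction_past_ip` (NA with a warning if the session produced no
#'   decisions), `agent_ip`, `round_payoffs`, `elapsed` (s).
#' @export
simulate_session <- function(agent, condition, duration_min = 20,
                             timing = timing_model(),
                             participant_id = "sim01", session_order = 1L,
                             policy = NULL) {
  stopifnot(duration_min > 0)
  budget <- duration_min * 60
  elapsed <- 0
  rounds <- list()
  payoffs <- numeric(0)
  r <- 0L
  while (elapsed < budget) {
    r <- r + 1L
    rnd <- simulate_round(agent, condition, timing,
                          time_budget = budget - elapsed, policy = policy)
    elapsed <- elapsed + rnd$elapsed
    d <- rnd$decisions
    if (nrow(d) > 0) {
      d$round_index <- r
      rounds[[length(rounds) + 1L]] <- d
    }
    if (!rnd$truncated) payoffs <- c(payoffs, rnd$payoff)
    if (rnd$truncated) break
  }
  trials <- if (length(rounds)) do.call(rbind, rounds) else
    data.frame(decision_index = integer(0), cum_sum = numeric(0),
               choice = character(0), round_index = integer(0))
  ip <- if (inherits(agent, "agent_params")) {
    indifference_point(condition, agent$alpha)
  } else NA_real_
  n_dec <- nrow(trials)
  frac <- if (n_dec == 0L) {
    warning("session produced no decisions; fraction_past_ip undefined")
    NA_real_
  } else {
    fraction_past_ip(trials$cum_sum, ip)
  }
  trials <- data.frame(
    participant_id = rep(participant_id, n_dec),
    condition_label = rep(condition$label, n_dec),
    round_index = trials$round_index,
    decision_index = trials$decision_index,
    cum_sum = trials$cum_sum,
    choice = trials$choice,
    rt = rep(NA_real_, n_dec),
    session_order = rep(as.integer(session_order), n_dec),
    stringsAsFactors = FALSE
  )
  structure(list(
    trials = trials, n_rounds = r, n_decisions = n_dec,
    fraction_past_ip = frac, agent_ip = ip,
    round_payoffs = payoffs, elapsed = elapsed
  ), class = "session_result")
}

#' Simulate a population and summarize decisions past the indifference point
#'
#' Draws the population from `spec`, plays `spec$duration_min` minutes per
#' agent in each condition, and aggregates the per-agent fraction of decision
#' points whose cumulative sum exceeds that agent's own analytic indifference
#' point.
#'
#' @param spec a [population_spec()].
#' @param timing a [timing_model()].
#' @return List with `summary` (data frame: condition, mean/sd/min/max of the
#'   per-agent fractions, n_agents, n_undefined), `agents` (per agent x
#'   condition: alpha, theta, agent_ip, fraction_past_ip, n_decisions) and
#'   `trials` (the pooled trial table).
#' @export
population_past_ip_summary <- function(spec, timing = timing_model()) {
  stopifnot(inherits(spec, "population_spec"))
  pop <- sample_population(spec)  # also seeds the session RNG stream
  res <- list(); trl <- list(); k <- 0L
  for (ci in seq_along(spec$conditions)) {
    cond <- spec$conditions[[ci]]
    for (i in seq_len(nrow(pop))) {
      agent <- agent_params(pop$alpha[i], pop$theta[i])
      ses <- simulate_session(agent, cond, spec$duration_min, timing,
                              participant_id = pop$agent_id[i],
                              session_order = ci)
      k <- k + 1L
      res[[k]] <- data.frame(
        agent_id = pop$agent_id[i], condition = cond$label,
        alpha = pop$alpha[i], theta = pop$theta[i],
        agent_ip = ses$agent_ip, fraction_past_ip = ses$fraction_past_ip,
        n_decisions = ses$n_decisions, stringsAsFactors = FALSE
      )
      trl[[k]] <- ses$trials
    }
  }
  agents <- do.call(rbind, res)
  summ <- do.call(rbind, lapply(split(agents, agents$condition), function(g) {
    f <- g$fraction_past_ip
    data.frame(
      condition = g$condition[1],
      mean_fraction = mean(f, na.rm = TRUE),
      sd_fraction = stats::sd(f, na.rm = TRUE),
      min_fraction = min(f, na.rm = TRUE),
      max_fraction = max(f, na.rm = TRUE),
      n_agents = nrow(g),
      n_undefined = sum(is.na(f)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summ) <- NULL
  n_undef <- sum(summ$n_undefined)
  if (n_undef > 0) {
    message(sprintf("%d agent x condition cells had no decisions (excluded)", n_undef))
  }
  list(summary = summ, agents = agents, trials = do.call(rbind, trl))
}
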