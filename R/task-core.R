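#' Define a 'pig' dice game condition
#'
#' A condition of the 'pig' dice game is a partition of the six die faces into
#' losing and winning faces, together with the reward multiplier. Rolling a
#' winning face adds `reward_multiplier * face` points to the round's
#' cumulative sum; rolling a losing face ends the round and zeroes the sum.
#'
#' The loss probability `p_lose` and the mean winning face `zbar` are derived
#' from the face partition. Both are stored together with their integer
#' numerators so that risk-neutral indifference points are exact.
#'
#' @param losing_faces integer vector of die faces in 1..6 that zero the round;
#'   must be a nonempty proper subset of 1..6.
#' @param label display label; defaults to `"<n>/6"` with `n` the number of
#'   losing faces.
#' @param reward_multiplier points awarded per pip of a winning face.
#' @return An object of class `pig_condition` with fields `label`,
#'   `losing_faces`, `winning_faces`, `reward_multiplier`, `p_lose`, `zbar`.
#' @examples
#' cond <- game_condition(c(1, 3))
#' cond$p_lose  # 2/6
#' cond$zbar    # mean of 2,4,5,6 = 4.25
#' @export
game_condition <- function(losing_faces, label = NULL, reward_multiplier = 10) {
  losing_faces <- sort(unique(as.integer(losing_faces)))
  if (length(losing_faces) == 0L || length(losing_faces) >= 6L ||
      any(losing_faces < 1L | losing_faces > 6L)) {
    stop("losing_faces must be a nonempty proper subset of 1..6")
  }
  if (!is.numeric(reward_multiplier) || reward_multiplier <= 0) {
    stop("reward_multiplier must be positive")
  }
  winning <- setdiff(1:6, losing_faces)
  if (is.null(label)) label <- sprintf("%d/6", length(losing_faces))
  structure(list(
    label = label,
    losing_faces = losing_faces,
    winning_faces = winning,
    reward_multiplier = reward_multiplier,
    n_lose = length(losing_faces),
    sum_win = sum(winning),
    p_lose = length(losing_faces) / 6,
    zbar = sum(winning) / length(winning)
  ), class = "pig_condition")
}

#' The three standard task conditions
#'
#' Losing faces \{1\}, \{1,3\}, and \{1,3,5\}, i.e. loss probabilities 1/6,
#' 2/6, and 3/6 with reward multiplier 10.
#'
#' @return Named list of [game_condition()] objects.
#' @export
standard_conditions <- function() {
  list(
    "1/6" = game_condition(1L),
    "2/6" = game_condition(c(1L, 3L)),
    "3/6" = game_condition(c(1L, 3L, 5L))
  )
}

#' @export
print.pig_condition <- function(x, ...) {
  cat(sprintf(
    "'pig' condition %s: losing faces {%s}, p(lose) = %d/6, mean winning face = %g\n",
    x$label, paste(x$losing_faces, collapse = ","), x$n_lose, x$zbar
  ))
  invisible(x)
}

#' Agent preference parameters
#'
#' Risk curvature `alpha` (exponent on reward in the utility function;
#' `alpha < 1` risk-averse, `= 1` risk-neutral, `> 1` risk-seeking) and softmax
#' sensitivity `theta` (inverse temperature on the utility difference;
#' `theta = 0` yields random choice).
#'
#' @param alpha positive risk-curvature exponent.
#' @param theta nonnegative softmax sensitivity.
#' @return Object of class `agent_params`.
#' @export
agent_params <- function(alpha = 1, theta = 0.2) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("alpha must be a positive scalar")
  }
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta < 0) {
    stop("theta must be a nonnegative scalar")
  }
  structure(list(alpha = alpha, theta = theta), class = "agent_params")
}

#' Task timing model
#'
#' Durations (seconds) of the task's screen events, used to convert simulated
#' rounds into elapsed session time. The die-roll animation lasts a uniform
#' draw from the discrete grid `roll_anim_min, roll_anim_min + roll_anim_step,
#' ..., roll_anim_max`. After a winning roll the outcome (and decision window)
#' is shown for `outcome_display` seconds; a losing roll shows the loss for
#' `loss_display` seconds; a stop decision shows the cashed-in sum for
#' `cashin_display` seconds.
#'
#' @param roll_anim_min,roll_anim_max,roll_anim_step die animation grid (s).
#' @param outcome_display outcome/decision window after a winning roll (s).
#' @param loss_display loss screen duration (s).
#' @param cashin_display cash-in screen duration (s).
#' @param decision_window response deadline within the outcome display (s).
#' @return Object of class `timing_model`.
#' @export
timing_model <- function(roll_anim_min = 1.5, roll_anim_max = 3.75,
                         roll_anim_step = 0.15, outcome_display = 2.0,
                         loss_display = 2.0, cashin_display = 2.5,
                         decision_window = 2.0) {
  if (roll_anim_min > roll_anim_max) stop("roll_anim_min must be <= roll_anim_max")
  k <- (roll_anim_max - roll_anim_min) / roll_anim_step
  if (abs(k - round(k)) > 1e-8) {
    stop("animation range must be divisible by roll_anim_step")
  }
  structure(list(
    roll_anim_min = roll_anim_min, roll_anim_max = roll_anim_max,
    roll_anim_step = roll_anim_step, outcome_display = outcome_display,
    loss_display = loss_display, cashin_display = cashin_display,
    decision_window = decision_window
  ), class = "timing_model")
}

anim_grid <- function(timing) {
  seq(timing$roll_anim_min, timing$roll_anim_max, by = timing$roll_anim_step)
}

#' Expected utilities of stopping and continuing
#'
#' Utility of a cumulative sum `s` is `s^alpha`. Stopping cashes in the
#' current sum; continuing is worth the utility of the sum plus the average
#' winning gain (`zbar * reward_multiplier`), discounted by the probability of
#' not losing:
#' `EU_stop = s^alpha`, `EU_continue = (s + zbar * m)^alpha * (1 - p_lose)`.
#'
#' @param cum_sum nonnegative cumulative sum(s) of rewards, in points.
#' @param condition a [game_condition()].
#' @param alpha positive risk-curvature exponent.
#' @return List with numeric vectors `eu_stop` and `eu_continue`.
#' @examples
#' expected_utilities(0, game_condition(1), alpha = 1)   # continue worth 100/3
#' @export
expected_utilities <- function(cum_sum, condition, alpha = 1) {
  stopifnot(inherits(condition, "pig_condition"))
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be positive")
  if (any(!is.finite(cum_sum)) || any(cum_sum < 0)) {
    stop("cum_sum must be nonnegative and finite")
  }
  gain <- condition$zbar * condition$reward_multiplier
  list(
    eu_stop = cum_sum^alpha,
    eu_continue = (cum_sum + gain)^alpha * (1 - condition$p_lose)
  )
}

#' Softmax probability of stopping
#'
#' `p(stop) = exp(theta * EU_stop) / (exp(theta * EU_stop) + exp(theta *
#' EU_continue))`, evaluated stably via the utility difference. With
#' `theta = 0` every decision is a coin flip.
#'
#' @inheritParams expected_utilities
#' @param agent an [agent_params()] object.
#' @return Numeric vector of stop probabilities.
#' @export
stop_probability <- function(cum_sum, condition, agent) {
  stopifnot(inherits(agent, "agent_params"))
  eu <- expected_utilities(cum_sum, condition, agent$alpha)
  # logistic of theta * (EU_stop - EU_continue); plogis is overflow-safe
  stats::plogis(agent$theta * (eu$eu_stop - eu$eu_continue))
}

#' Analytic indifference point
#'
#' The cumulative sum at which stopping and continuing have equal expected
#' utility: the root of `(s + zbar * m)^alpha * (1 - p_lose) = s^alpha`,
#' which in closed form is `zbar * m / ((1 - p_lose)^(-1/alpha) - 1)`.
#' For a risk-neutral agent (`alpha = 1`) this reduces to
#' `m * sum(winning faces) / n_losing_faces`, evaluated in integer arithmetic
#' so the standard conditions give exactly 200, 85, and 40 points.
#'
#' @param condition a [game_condition()].
#' @param alpha positive risk-curvature exponent.
#' @return Indifference point in points.
#' @examples
#' indifference_point(game_condition(1))          # 200
#' indifference_point(game_condition(c(1, 3, 5))) # 40
#' @export
indifference_point <- function(condition, alpha = 1) {
  stopifnot(inherits(condition, "pig_condition"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("alpha must be a positive scalar")
  }
  if (alpha == 1) {
    return(condition$reward_multiplier * condition$sum_win / condition$n_lose)
  }
  gain <- condition$zbar * condition$reward_multiplier
  gain / ((1 - condition$p_lose)^(-1 / alpha) - 1)
}

#' Simulate one round of the 'pig' dice game
#'
#' The round starts with an automatic die roll. After every winning roll the
#' agent decides to stop (cashing in the cumulative sum) or continue; a losing
#' roll ends the round with zero payoff. Elapsed time accrues the animation
#' draw per roll, the 2 s outcome/decision window after winning rolls, and the
#' terminal loss or cash-in display.
#'
#' Randomness is taken from R's global RNG stream; seed with [set.seed()].
#'
#' @param agent an [agent_params()] softmax agent.
#' @param condition a [game_condition()].
#' @param timing a [timing_model()].
#' @param time_budget remaining session time in seconds; the round is cut off
#'   (no further rolls) once the elapsed clock reaches it, as happens when a
#'   timed session ends mid-round.
#' @param faces optional forced face sequence (recycled rolls are not allowed:
#'   must be long enough for the round it induces).
#' @param policy optional override: function of the cumulative-sum vector
#'   returning stop probabilities, replacing the softmax rule.
#' @return List with `decisions` (data frame: `decision_index`, `cum_sum`,
#'   `choice`), `payoff`, `lost` (logical), `n_rolls`, `elapsed` (seconds),
#'   and `truncated` (round cut off by the session clock).
#' @export
simulate_round <- function(agent, condition, timing = timing_model(),
                           time_budget = Inf, faces = NULL, policy = NULL) {
  stopifnot(inherits(condition, "pig_condition"), inherits(timing, "timing_model"))
  if (is.null(policy)) {
    stopifnot(inherits(agent, "agent_params"))
    policy <- function(s) stop_probability(s, condition, agent)
  }
  grid <- anim_grid(timing)
  cum <- 0
  elapsed <- 0
  idx <- 0L
  dec_sum <- numeric(0)
  dec_choice <- character(0)
  payoff <- 0
  lost <- FALSE
  truncated <- FALSE
  n_rolls <- 0L
  repeat {
    if (elapsed >= time_budget) { truncated <- TRUE; break }
    n_rolls <- n_rolls + 1L
    if (is.null(faces)) {
      face <- sample.int(6L, 1L)
    } else {
      if (n_rolls > length(faces)) stop("forced face sequence exhausted")
      face <- faces[n_rolls]
    }
    elapsed <- elapsed + if (length(grid) == 1L) grid else sample(grid, 1L)
    if (face %in% condition$losing_faces) {
      elapsed <- elapsed + timing$loss_display
      lost <- TRUE
      payoff <- 0
      break
    }
    cum <- cum + condition$reward_multiplier * face
    elapsed <- elapsed + timing$outcome_display
    idx <- idx + 1L
    stop_now <- stats::runif(1) < policy(cum)
    dec_sum[idx] <- cum
    dec_choice[idx] <- if (stop_now) "stop" else "continue"
    if (stop_now) {
      elapsed <- elapsed + timing$cashin_display
      payoff <- cum
      break
    }
  }
  list(
    decisions = data.frame(
      decision_index = seq_len(idx),
      cum_sum = dec_sum,
      choice = dec_choice,
      stringsAsFactors = FALSE
    ),
    payoff = payoff, lost = lost, n_rolls = n_rolls,
    elapsed = elapsed, truncated = truncated
  )
}

#' Bonus payment from round payoffs
#'
#' Participants are paid one tenth of the average cumulative sum cashed in per
#' round, counting lost rounds as zero.
#'
#' @param round_payoffs numeric vector of per-round payoffs in points (0 for
#'   lost rounds); must be nonempty.
#' @return Bonus in currency units.
#' @export
compute_bonus <- function(round_payoffs) {
  if (length(round_payoffs) == 0L || !is.numeric(round_payoffs)) {
    stop("round_payoffs must be a nonempty numeric vector")
  }
  mean(round_payoffs) / 10
}
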