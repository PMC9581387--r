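#' Trial-wise DDM parameter links
#'
#' The diffusion decision model's parameters are regressed on task covariates
#' at every decision: the drift rate is linear in the covariate,
#' `d_t = delta0 + delta1 * x_t` (positive drift favors stopping); the
#' boundary separation uses a softplus link, `A_t = log(1 + exp(delta0 +
#' delta1 * x_t))`, keeping it positive; and the relative starting point uses
#' the standard-normal CDF (Phi) link, `z_t = Phi(delta0 + delta1 * x_t)`,
#' keeping it in (0, 1).
#'
#' @param delta0 intercept coefficient.
#' @param delta1 slope coefficient (0 for an unmodulated parameter).
#' @param covariate trial covariate (cumulative sum in points, or decision
#'   number).
#' @return Numeric vector of trial-wise parameter values.
#' @name ddm-links
NULL

#' @rdname ddm-links
#' @export
drift_link <- function(delta0, delta1 = 0, covariate = 0) {
  delta0 + delta1 * covariate
}

#' @rdname ddm-links
#' @export
threshold_link <- function(delta0, delta1 = 0, covariate = 0) {
  softplus(delta0 + delta1 * covariate)
}

#' @rdname ddm-links
#' @export
start_link <- function(delta0, delta1 = 0, covariate = 0) {
  stats::pnorm(delta0 + delta1 * covariate)
}

#' Indifference point from drift-rate coefficients
#'
#' The cumulative sum at which the trial-wise drift rate crosses zero,
#' `-delta0 / delta1`: the model-implied point of equal evidence for stopping
#' and continuing (and of longest expected decision time).
#'
#' @param delta0,delta1 drift coefficients (vectors, e.g. posterior draws).
#' @return Numeric vector of indifference points.
#' @export
ip_from_drift <- function(delta0, delta1) {
  if (any(delta1 == 0)) stop("delta1 = 0: indifference point undefined")
  -delta0 / delta1
}

#' Enumerate the DDM model space
#'
#' Nineteen variants: the drift rate is modulated by either the cumulative sum
#' of rewards or the decision number (2 options), the threshold and relative
#' starting point are each fixed or modulated by one of the two covariates
#' (3 options each), plus one baseline model in which drift, threshold, and
#' starting point are all fixed.
#'
#' @return Data frame with columns `variant_id`, `drift_modulator`,
#'   `threshold_modulator`, `start_modulator`, `is_baseline`; 19 rows in a
#'   stable order (baseline first).
#' @export
ddm_model_space <- function() {
  mods <- c("none", "cumulative_sum", "decision_number")
  grid <- expand.grid(
    start_modulator = mods,
    threshold_modulator = mods,
    drift_modulator = c("cumulative_sum", "decision_number"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("drift_modulator", "threshold_modulator", "start_modulator")]
  out <- rbind(
    data.frame(drift_modulator = "none", threshold_modulator = "none",
               start_modulator = "none", stringsAsFactors = FALSE),
    grid
  )
  short <- c(none = "fix", cumulative_sum = "cs", decision_number = "dn")
  out$variant_id <- ifelse(
    out$drift_modulator == "none", "baseline",
    sprintf("d.%s_a.%s_z.%s", short[out$drift_modulator],
            short[out$threshold_modulator], short[out$start_modulator])
  )
  out$is_baseline <- out$variant_id == "baseline"
  rownames(out) <- NULL
  out[, c("variant_id", "drift_modulator", "threshold_modulator",
          "start_modulator", "is_baseline")]
}

#' Look up one DDM variant
#'
#' @param variant_id id string as in [ddm_model_space()] (e.g. `"baseline"`,
#'   `"d.cs_a.cs_z.cs"`).
#' @return One-row data frame describing the variant.
#' @export
ddm_variant <- function(variant_id) {
  space <- ddm_model_space()
  row <- space[space$variant_id == variant_id, ]
  if (nrow(row) != 1L) {
    stop("unknown variant_id; see ddm_model_space()$variant_id")
  }
  row
}

# Covariate vector implied by a modulator name (zeros for "none", so a zero
# slope never contributes).
modulator_covariate <- function(modulator, cum_sum, decision_index) {
  switch(modulator,
    none = rep(0, length(cum_sum)),
    cumulative_sum = cum_sum,
    decision_number = as.numeric(decision_index),
    stop("unknown modulator: ", modulator)
  )
}

#' Wiener first-passage log-density
#'
#' Log density of observing response time `rt` at the boundary matching
#' `choice` under a Wiener diffusion with drift `drift` (positive toward
#' "stop", the upper boundary), boundary separation `boundary`, relative
#' starting point `start` (from the lower, "continue", boundary), and
#' non-decision time `ndt`. Evaluated by truncated series with automatic
#' switching between the small-time and large-time expansions at truncation
#' tolerance `err`.
#'
#' @param rt response times in seconds.
#' @param choice `"stop"` / `"continue"` (or a logical vector, TRUE = stop).
#' @param drift,boundary,ndt,start DDM parameters; recycled to the length of
#'   `rt`. `boundary > 0`, `start` in (0,1), `ndt >= 0`.
#' @param err series truncation tolerance.
#' @return Log densities; `-Inf` where `rt <= ndt`.
#' @export
wiener_logpdf <- function(rt, choice, drift, boundary, ndt, start = 0.5,
                          err = 1e-7) {
  n <- length(rt)
  is_stop <- choice_to_stop(choice, n)
  drift <- rep_len(drift, n); boundary <- rep_len(boundary, n)
  ndt <- rep_len(ndt, n); start <- rep_len(start, n)
  if (any(boundary <= 0)) stop("boundary must be positive")
  if (any(start <= 0 | start >= 1)) stop("start must lie in (0,1)")
  if (any(ndt < 0)) stop("ndt must be nonnegative")
  wiener_logpdf_cpp(rt - ndt, is_stop, drift, boundary, start, err)
}

#' Probability that the diffusion stops (absorbs at the upper boundary)
#'
#' Closed-form absorption probability of the Wiener process; equals `start`
#' at zero drift, hence 0.5 at the indifference point when the start is
#' centered.
#'
#' @inheritParams wiener_logpdf
#' @return Vector of stop probabilities.
#' @export
wiener_p_stop <- function(drift, boundary, start = 0.5) {
  n <- max(length(drift), length(boundary), length(start))
  wiener_p_upper_cpp(rep_len(drift, n), rep_len(boundary, n),
                     rep_len(start, n))
}

choice_to_stop <- function(choice, n) {
  if (is.logical(choice)) return(as.integer(rep_len(choice, n)))
  choice <- rep_len(as.character(choice), n)
  if (!all(choice %in% c("stop", "continue"))) {
    stop("choice must be 'stop' or 'continue'")
  }
  as.integer(choice == "stop")
}

#' Sample choices and response times from the Wiener diffusion
#'
#' Boundary drawn from its analytic absorption probability; the first-passage
#' time from the conditional density via inverse-CDF on a fine grid (exact in
#' distribution up to grid interpolation). Uses R's RNG stream.
#'
#' @inheritParams wiener_logpdf
#' @return Data frame with `choice` (`"stop"`/`"continue"`) and `rt` seconds.
#' @export
rwiener_trials <- function(drift, boundary, ndt, start = 0.5) {
  n <- max(length(drift), length(boundary), length(ndt), length(start))
  drift <- rep_len(drift, n); boundary <- rep_len(boundary, n)
  ndt <- rep_len(ndt, n); start <- rep_len(start, n)
  if (any(boundary <= 0)) stop("boundary must be positive")
  if (any(start <= 0 | start >= 1)) stop("start must lie in (0,1)")
  if (any(ndt < 0)) stop("ndt must be nonnegative")
  s <- wiener_sample_cpp(drift, boundary, start, ndt)
  data.frame(choice = ifelse(s$choice_upper == 1L, "stop", "continue"),
             rt = s$rt, stringsAsFactors = FALSE)
}

#' Generate a joint choice/RT dataset from a DDM variant
#'
#' The generative twin of the fitted model family: given a trial design
#' (which covariates each decision carries) and per-participant coefficients,
#' computes the trial-wise drift, threshold, and starting point through the
#' model's links and samples choice and RT from the Wiener first-passage
#' process.
#'
#' @param variant a row of [ddm_model_space()] or a `variant_id` string.
#' @param true_params data frame, one row per participant (and per condition
#'   if the design spans several): columns `participant_id`, optionally
#'   `condition_label`, and coefficients `d0`, `d1`, `a0`, `a1`, `z0`, `z1`,
#'   `ter` (slopes of unmodulated parameters are ignored).
#' @param design data frame with `participant_id`, `condition_label`,
#'   `round_index`, `decision_index`, `cum_sum` (and optionally
#'   `session_order`).
#' @param truncate_rounds when TRUE (default), design rows following a
#'   sampled stop within the same round are dropped, so the generated table
#'   respects the task's round structure (a stop ends the round) the way real
#'   data do; set FALSE to keep every design row for density cross-checks.
#' @return The design with `choice` and `rt` columns appended (a canonical
#'   trial table).
#' @export
generate_ddm_dataset <- function(variant, true_params, design,
                                 truncate_rounds = TRUE) {
  if (is.character(variant)) variant <- ddm_variant(variant)
  need <- c("participant_id", "condition_label", "round_index",
            "decision_index", "cum_sum")
  if (!all(need %in% names(design))) {
    stop("design must carry columns: ", paste(need, collapse = ", "))
  }
  by_cond <- "condition_label" %in% names(true_params)
  key_d <- if (by_cond) {
    paste(design$participant_id, design$condition_label)
  } else design$participant_id
  key_p <- if (by_cond) {
    paste(true_params$participant_id, true_params$condition_label)
  } else true_params$participant_id
  idx <- match(key_d, key_p)
  if (anyNA(idx)) stop("true_params missing rows for some design cells")
  p <- true_params[idx, , drop = FALSE]
  slope <- function(col, modulator) {
    if (modulator == "none" || !col %in% names(p)) rep(0, nrow(p)) else p[[col]]
  }
  xd <- modulator_covariate(variant$drift_modulator, design$cum_sum,
                            design$decision_index)
  xa <- modulator_covariate(variant$threshold_modulator, design$cum_sum,
                            design$decision_index)
  xz <- modulator_covariate(variant$start_modulator, design$cum_sum,
                            design$decision_index)
  v <- p$d0 + slope("d1", variant$drift_modulator) * xd
  a <- threshold_link(p$a0, slope("a1", variant$threshold_modulator), xa)
  w <- start_link(p$z0, slope("z1", variant$start_modulator), xz)
  w <- pmin(pmax(w, 1e-9), 1 - 1e-9)
  if (any(p$ter < 0)) stop("non-decision time must be nonnegative")
  sim <- rwiener_trials(v, a, p$ter, w)
  out <- design
  out$choice <- sim$choice
  out$rt <- sim$rt
  if (!"session_order" %in% names(out)) out$session_order <- 1L
  if (truncate_rounds) {
    key <- paste(out$participant_id, out$condition_label, out$round_index)
    keep <- unlist(lapply(split(seq_len(nrow(out)), key), function(i) {
      i <- i[order(out$decision_index[i])]
      first_stop <- match("stop", out$choice[i])
      if (is.na(first_stop)) i else i[seq_len(first_stop)]
    }), use.names = FALSE)
    out <- out[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Build a task-shaped trial design for DDM simulation
#'
#' Simulates rounds of the dice game with a softmax agent to obtain a
#' realistic schedule of (round, decision number, cumulative sum) triples,
#' truncated to `n_trials` decisions per participant. The agent's choices are
#' discarded; only the covariate schedule is kept.
#'
#' @param n_participants number of participants.
#' @param n_trials decisions per participant.
#' @param condition a [game_condition()].
#' @param agent softmax agent steering round lengths (default risk-neutral,
#'   theta 0.2).
#' @return Design data frame for [generate_ddm_dataset()].
#' @export
simulate_task_design <- function(n_participants, n_trials, condition,
                                 agent = agent_params(1, 0.2)) {
  out <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    rows <- list(); got <- 0L; r <- 0L
    while (got < n_trials) {
      r <- r + 1L
      rnd <- simulate_round(agent, condition)
      d <- rnd$decisions
      if (nrow(d) == 0L) next
      d$round_index <- r
      rows[[length(rows) + 1L]] <- d
      got <- got + nrow(d)
    }
    d <- do.call(rbind, rows)[seq_len(n_trials), ]
    out[[i]] <- data.frame(
      participant_id = sprintf("p%02d", i),
      condition_label = condition$label,
      round_index = d$round_index,
      decision_index = d$decision_index,
      cum_sum = d$cum_sum,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
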