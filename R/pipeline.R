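#' Canonical trial-table I/O
#'
#' The pipeline's tabular interchange format: comma-separated, UTF-8, header
#' row, fixed column order `participant_id, condition_label, round_index,
#' decision_index, cum_sum, choice, rt, session_order`, missing RT written as
#' an empty field. [read_trials()] validates structure on the way in.
#'
#' @param trials trial table data frame.
#' @param path file path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` the
#'   validated data frame.
#' @export
write_trials <- function(trials, path) {
  cols <- c("participant_id", "condition_label", "round_index",
            "decision_index", "cum_sum", "choice", "rt", "session_order")
  missing <- setdiff(cols, names(trials))
  if (length(missing)) stop("trials missing columns: ",
                            paste(missing, collapse = ", "))
  utils::write.csv(trials[, cols], path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                       fileEncoding = "UTF-8",
                       colClasses = c(participant_id = "character",
                                      condition_label = "character",
                                      round_index = "integer",
                                      decision_index = "integer",
                                      cum_sum = "numeric",
                                      choice = "character", rt = "numeric",
                                      session_order = "integer"))
  validate_trials(d)
  d
}

#' Validate a trial table
#'
#' Checks the structural invariants of the canonical table: required columns;
#' within each round the cumulative sum strictly increasing in increments of
#' `{20, ..., 60}` points; at most one stop per round with no decisions after
#' it; choices in stop/continue.
#'
#' @param trials trial table.
#' @param increments allowed cumulative-sum increments (winning faces times
#'   the reward multiplier).
#' @return `trials`, invisibly; errors describe the first violation.
#' @export
validate_trials <- function(trials, increments = 10 * (2:6)) {
  cols <- c("participant_id", "condition_label", "round_index",
            "decision_index", "cum_sum", "choice", "rt", "session_order")
  missing <- setdiff(cols, names(trials))
  if (length(missing)) stop("trials missing columns: ",
                            paste(missing, collapse = ", "))
  if (!all(trials$choice %in% c("stop", "continue"))) {
    stop("choice must be 'stop' or 'continue'")
  }
  key <- paste(trials$participant_id, trials$condition_label,
               trials$round_index)
  for (g in split(seq_len(nrow(trials)), key)) {
    g <- g[order(trials$decision_index[g])]
    s <- trials$cum_sum[g]
    inc <- diff(c(0, s))
    if (any(!(inc %in% increments))) {
      stop("cum_sum increments outside winning-face grid in round ",
           key[g[1]])
    }
    ch <- trials$choice[g]
    if (sum(ch == "stop") > 1L || any(ch[-length(ch)] == "stop")) {
      stop("decisions found after a stop in round ", key[g[1]])
    }
  }
  invisible(trials)
}

#' Participant exclusion rules
#'
#' Drops participants who (a) made fewer than `min_share` (default 5%) of
#' either response type overall, or (b) made more stop than continue
#' responses at the beginning of a round (the first `first_window` decisions
#' of each round; default the first decision) — both signs of not engaging
#' with the task's sequential structure.
#'
#' @param trials trial table.
#' @param min_share minimum share of each response type.
#' @param first_window how many initial decisions of a round count as its
#'   "beginning".
#' @return List with `kept` (filtered trials) and `report` (per participant:
#'   kept flag and reason).
#' @export
apply_exclusions <- function(trials, min_share = 0.05, first_window = 1L) {
  per <- split(trials, trials$participant_id)
  report <- do.call(rbind, lapply(per, function(g) {
    sh_stop <- mean(g$choice == "stop")
    early <- g[g$decision_index <= first_window, , drop = FALSE]
    early_stop_excess <- sum(early$choice == "stop") >
      sum(early$choice == "continue")
    reason <- NA_character_
    if (sh_stop < min_share || (1 - sh_stop) < min_share) {
      reason <- sprintf("share of %s decisions below %g%%",
                        if (sh_stop < min_share) "stop" else "continue",
                        100 * min_share)
    } else if (early_stop_excess) {
      reason <- "more stop than continue responses at round beginnings"
    }
    data.frame(participant_id = g$participant_id[1], kept = is.na(reason),
               reason = reason, n_decisions = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(report) <- NULL
  kept_ids <- report$participant_id[report$kept]
  list(kept = trials[trials$participant_id %in% kept_ids, , drop = FALSE],
       report = report)
}

#' Convergence gate for MCMC fits
#'
#' Passes when every R-hat is below 1.05, divergent transitions do not exceed
#' 1% of post-warmup iterations, and maximum-treedepth saturation does not
#' exceed 1%. The divergence and treedepth checks apply to samplers that
#' report them (NUTS-style); the Gibbs and Metropolis samplers used here
#' report zero for both.
#'
#' @param rhat named vector of R-hat values (NAs ignored).
#' @param divergent_frac fraction of divergent transitions.
#' @param treedepth_frac fraction of iterations hitting maximum treedepth.
#' @param rhat_max,frac_max gate thresholds.
#' @return List of class `convergence_report`: `pass`, `rhat`, `worst`
#'   (named worst R-hat), `failed_parameters`, `divergent_frac`,
#'   `treedepth_frac`.
#' @export
convergence_gate <- function(rhat, divergent_frac = 0, treedepth_frac = 0,
                             rhat_max = 1.05, frac_max = 0.01) {
  rh <- rhat[is.finite(rhat)]
  failed <- names(rh)[rh >= rhat_max]
  pass <- length(failed) == 0L && divergent_frac <= frac_max &&
    treedepth_frac <= frac_max
  structure(list(pass = pass, rhat = rhat,
                 worst = if (length(rh)) rh[which.max(rh)] else NA_real_,
                 failed_parameters = failed,
                 divergent_frac = divergent_frac,
                 treedepth_frac = treedepth_frac),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("Convergence gate: %s (worst R-hat %.3f%s; divergences %.1f%%)\n",
              if (x$pass) "PASS" else "FAIL",
              x$worst,
              if (length(x$failed_parameters))
                paste0("; failed: ",
                       paste(utils::head(x$failed_parameters, 5),
                             collapse = ", ")) else "",
              100 * x$divergent_frac))
  invisible(x)
}

#' Decisions past the indifference point, per condition
#'
#' Given per-cell indifference points (from the logistic model, the DDM, or
#' the analytic agent IPs), reports the distribution of per-participant
#' fractions of decisions past the IP by condition, with descriptive pairwise
#' condition differences.
#'
#' @param trials trial table.
#' @param ips data frame `participant_id`, `condition_label`, `ip`.
#' @return List with `per_cell`, `summary` (condition, mean, sd, n), and
#'   `pairwise` (descriptive mean differences between conditions).
#' @export
past_ip_report <- function(trials, ips) {
  key <- paste(trials$participant_id, trials$condition_label)
  ip <- ips$ip[match(key, paste(ips$participant_id, ips$condition_label))]
  d <- trials[!is.na(ip), , drop = FALSE]
  ip <- ip[!is.na(ip)]
  per <- do.call(rbind, lapply(
    split(seq_len(nrow(d)), paste(d$participant_id, d$condition_label,
                                  sep = "\r")),
    function(i) data.frame(
      participant_id = d$participant_id[i[1]],
      condition_label = d$condition_label[i[1]],
      ip = ip[i[1]],
      fraction_past_ip = fraction_past_ip(d$cum_sum[i], ip[i[1]]),
      n_decisions = length(i), stringsAsFactors = FALSE)))
  rownames(per) <- NULL
  summ <- do.call(rbind, lapply(split(per, per$condition_label), function(g)
    data.frame(condition_label = g$condition_label[1],
               mean_fraction = mean(g$fraction_past_ip),
               sd_fraction = stats::sd(g$fraction_past_ip),
               n = nrow(g), stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  pw <- NULL
  if (nrow(summ) > 1L) {
    cmb <- utils::combn(summ$condition_label, 2)
    pw <- data.frame(
      condition_a = cmb[1, ], condition_b = cmb[2, ],
      mean_difference = summ$mean_fraction[match(cmb[2, ], summ$condition_label)] -
        summ$mean_fraction[match(cmb[1, ], summ$condition_label)],
      stringsAsFactors = FALSE)
  }
  list(per_cell = per, summary = summ, pairwise = pw)
}

#' Pipeline configuration
#'
#' Reads a YAML configuration covering conditions, timing, population,
#' sampler settings, and the stage list; unspecified fields fall back to the
#' package defaults (the standard three conditions, the default timing model,
#' a 100-agent risk-neutral-mean population at 20 min/condition, regression
#' chains 2 x 2000).
#'
#' @param path YAML file path.
#' @return Config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg
}

config_conditions <- function(cfg) {
  if (is.null(cfg$conditions)) return(standard_conditions())
  out <- lapply(cfg$conditions, function(co)
    game_condition(co$losing_faces, label = co$label,
                   reward_multiplier = co$reward_multiplier %||% 10))
  names(out) <- vapply(out, `[[`, "", "label")
  out
}

config_timing <- function(cfg) {
  if (is.null(cfg$timing)) return(timing_model())
  do.call(timing_model, cfg$timing)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the simulation/fitting pipeline
#'
#' Orchestrates: simulate (population trial table) -> exclusions -> choice
#' model -> conflict/RT model -> DDM variants -> WAIC comparison -> past-IP
#' report, writing each stage's outputs (CSV tables and a plain-text log)
#' under `out_dir`. Stages are selected by `config$stages`; a failed
#' convergence gate halts the downstream model stages unless
#' `config$force` is TRUE.
#'
#' @param config configuration list (see [read_pipeline_config()]); fields
#'   used: `stages` (subset of `"simulate"`, `"fit-choice"`, `"fit-rt"`,
#'   `"fit-ddm"`, `"compare"`, `"report"`), `input_csv` (instead of
#'   simulate), `population` (arguments of [population_spec()]),
#'   `conditions`, `timing`, `mcmc` (chains/iter/warmup), `ddm_mcmc`,
#'   `variants` (ids for fit-ddm/compare), `force`.
#' @param seed integer seed for every stochastic stage.
#' @param out_dir output directory (created if needed).
#' @return Invisible list of stage results.
#' @export
run_pipeline <- function(config = list(), seed = 1L, out_dir = "pipeline-out") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run-log.txt")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logf, append = TRUE)
  cat(sprintf("pipeline run, seed %d\n", seed), file = logf)
  stages <- config$stages %||%
    c("simulate", "fit-choice", "fit-rt", "report")
  res <- list()
  conditions <- config_conditions(config)
  timing <- config_timing(config)

  if ("simulate" %in% stages) {
    pop_args <- config$population %||% list()
    pop_args$conditions <- conditions
    pop_args$seed <- seed
    spec <- do.call(population_spec, pop_args)
    sim <- population_past_ip_summary(spec, timing)
    res$simulate <- sim
    write_trials(sim$trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(sim$summary, file.path(out_dir, "past-ip-analytic.csv"),
                     row.names = FALSE)
    logline("simulate: %d agents, %d trials", spec$n_agents, nrow(sim$trials))
    trials <- sim$trials
  } else if (!is.null(config$input_csv)) {
    trials <- read_trials(config$input_csv)
    logline("input: %s (%d rows)", config$input_csv, nrow(trials))
  } else {
    stop("config needs either the simulate stage or input_csv")
  }

  exc <- apply_exclusions(trials)
  res$exclusions <- exc$report
  utils::write.csv(exc$report, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  logline("exclusions: %d of %d participants kept", sum(exc$report$kept),
          nrow(exc$report))
  trials <- exc$kept
  gate_ok <- TRUE

  if ("fit-choice" %in% stages) {
    mc <- do.call(mcmc_settings, c(config$mcmc %||% list(),
                                   list(seed = seed)))
    cf <- fit_choice_model(trials, mc)
    res$choice <- cf
    gate <- convergence_gate(cf$rhat)
    res$choice_gate <- gate
    logline("fit-choice: worst R-hat %.3f, gate %s", gate$worst,
            if (gate$pass) "pass" else "FAIL")
    gate_ok <- gate_ok && gate$pass
    summ <- choice_fit_summaries(cf)
    utils::write.csv(summ, file.path(out_dir, "choice-summaries.csv"),
                     row.names = FALSE)
    ips <- do.call(rbind, lapply(cf$conditions, function(cl) {
      g <- cf$group[[cl]]
      co <- cell_coefficients(cf)
      co <- co[co$condition_label == cl, ]
      data.frame(participant_id = co$participant_id, condition_label = cl,
                 ip = ip_from_coefficients(co$b0, co$b1),
                 stringsAsFactors = FALSE)
    }))
    res$ips <- ips
    utils::write.csv(ips, file.path(out_dir, "ips-logistic.csv"),
                     row.names = FALSE)
  }

  if ("fit-rt" %in% stages) {
    if (!gate_ok && !isTRUE(config$force)) {
      logline("fit-rt: skipped (failed gate upstream)")
    } else if (all(is.na(trials$rt))) {
      logline("fit-rt: skipped (no RTs in trial table)")
    } else {
      mc <- do.call(mcmc_settings, c(config$mcmc %||% list(),
                                     list(seed = seed + 1L)))
      conf <- conflict_series(res$choice, trials)
      rf <- fit_rt_model(trials, conf, mc)
      res$rt <- rf
      gate <- convergence_gate(rf$rhat)
      res$rt_gate <- gate
      logline("fit-rt: worst R-hat %.3f, gate %s", gate$worst,
              if (gate$pass) "pass" else "FAIL")
      gate_ok <- gate_ok && gate$pass
    }
  }

  if (any(c("fit-ddm", "compare") %in% stages)) {
    if (!gate_ok && !isTRUE(config$force)) {
      logline("fit-ddm: skipped (failed gate upstream)")
    } else if (all(is.na(trials$rt))) {
      logline("fit-ddm: skipped (no RTs in trial table)")
    } else {
      dmc <- do.call(ddm_mcmc_settings, c(config$ddm_mcmc %||% list(),
                                          list(seed = seed + 2L)))
      ids <- config$variants %||% "d.cs_a.fix_z.fix"
      cmp <- compare_ddm_variants(trials, ids, dmc)
      res$ddm <- cmp
      utils::write.csv(cmp$table, file.path(out_dir, "waic-table.csv"),
                       row.names = FALSE)
      logline("fit-ddm: best variant %s (WAIC %.1f)",
              cmp$table$variant_id[1], cmp$table$waic[1])
    }
  }

  if ("report" %in% stages && !is.null(res$ips)) {
    rep <- past_ip_report(trials, res$ips)
    res$past_ip <- rep
    utils::write.csv(rep$summary, file.path(out_dir, "past-ip-report.csv"),
                     row.names = FALSE)
    logline("report: past-IP fractions %s",
            paste(sprintf("%s=%.3f", rep$summary$condition_label,
                          rep$summary$mean_fraction), collapse = ", "))
  }
  invisible(res)
}
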