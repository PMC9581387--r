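#' Hierarchical Bayesian regression of log response times
#'
#' Regresses `log(RT)` on round number, within-round decision number,
#' cumulative sum of rewards, and trial choice conflict, with separate
#' regressors per condition and normal residuals:
#' `log(RT) = gamma0 + gamma1 r + gamma2 t + gamma3 cum_sum + gamma4 cc`.
#' Participant coefficients are drawn from condition-specific group normals;
#' hyper-priors are `Cauchy(0,10)` / `HalfCauchy(0,5)` for the intercept and
#' `Cauchy(0,5)` / `HalfCauchy(0,5)` for the slopes; the residual scale gets
#' a `HalfCauchy(0,1)`. Fitted with JAGS.
#'
#' Round and decision numbers enter untransformed (1-based); the conflict
#' regressor comes from a choice model fitted to the same data (two-stage).
#' Rows without a positive RT (e.g. loss-terminated rolls or simulated agents
#' without an RT process) are dropped with a count.
#'
#' @param trials canonical trial table with an `rt` column in seconds.
#' @param conflict output of [conflict_series()] aligned with `trials`, or
#'   NULL to fit without the conflict regressor (coefficient fixed at 0).
#' @param mcmc an [mcmc_settings()].
#' @return Object of class `rt_fit` with `draws`, `group` (per-condition
#'   group-level draws `mu_g0..mu_g4`, `sigma_g0..sigma_g4`, `sigma_res`),
#'   `cells`, `rhat`, `conditions`, `data`, `n_dropped`, `mcmc`.
#' @export
fit_rt_model <- function(trials, conflict = NULL, mcmc = mcmc_settings()) {
  d <- trials
  has_conflict <- !is.null(conflict)
  if (has_conflict) {
    if (nrow(conflict) != nrow(trials)) {
      stop("conflict series must align row-for-row with trials")
    }
    d$conflict <- conflict$conflict
  } else {
    d$conflict <- 0
  }
  usable <- !is.na(d$rt) & d$rt > 0 & !is.na(d$conflict)
  n_dropped <- sum(!usable)
  d <- d[usable, , drop = FALSE]
  if (nrow(d) == 0L) stop("no usable RT rows")
  conditions <- unique(d$condition_label)
  cell_key <- paste(d$participant_id, d$condition_label, sep = "\r")
  cells_id <- sort(unique(cell_key))
  cell <- match(cell_key, cells_id)
  cell_info <- do.call(rbind, strsplit(cells_id, "\r", fixed = TRUE))
  cells <- data.frame(index = seq_along(cells_id),
                      participant_id = cell_info[, 1],
                      condition_label = cell_info[, 2],
                      stringsAsFactors = FALSE)
  cond_of_cell <- match(cells$condition_label, conditions)

  # Sampled in an exactly equivalent centered form (see fit_choice_model):
  # u_k is the linear predictor at the condition-mean regressors; its
  # conditional prior reproduces independent normal populations on g0..g4.
  cc_pred <- if (has_conflict) " +\n              g4[cell[n]] * (cc[n] - ccbar[condn[n]])" else ""
  cc_pop <- if (has_conflict)
    "g4[k] ~ dnorm(mu_g4[cond[k]], pow(sigma_g4[cond[k]], -2))" else ""
  cc_u <- if (has_conflict) " +\n                   ccbar[cond[k]] * g4[k]" else ""
  cc_g0 <- if (has_conflict) " - ccbar[cond[k]] * g4[k]" else ""
  cc_hyper <- if (has_conflict)
    "mu_g4[c] ~ dt(0, pow(5, -2), 1)\n      sigma_g4[c] ~ dt(0, pow(5, -2), 1) T(0,)" else ""
  model <- sprintf("
  model {
    for (n in 1:N) {
      y[n] ~ dnorm(m[n], tau_res[condn[n]])
      m[n] <- u[cell[n]] + g1[cell[n]] * (r[n] - rbar[condn[n]]) +
              g2[cell[n]] * (t[n] - tbar[condn[n]]) +
              g3[cell[n]] * (s[n] - sbar[condn[n]])%s
    }
    for (k in 1:K) {
      g1[k] ~ dnorm(mu_g1[cond[k]], pow(sigma_g1[cond[k]], -2))
      g2[k] ~ dnorm(mu_g2[cond[k]], pow(sigma_g2[cond[k]], -2))
      g3[k] ~ dnorm(mu_g3[cond[k]], pow(sigma_g3[cond[k]], -2))
      %s
      u[k] ~ dnorm(mu_g0[cond[k]] + rbar[cond[k]] * g1[k] +
                   tbar[cond[k]] * g2[k] + sbar[cond[k]] * g3[k]%s,
                   pow(sigma_g0[cond[k]], -2))
      g0[k] <- u[k] - rbar[cond[k]] * g1[k] - tbar[cond[k]] * g2[k] -
               sbar[cond[k]] * g3[k]%s
    }
    for (c in 1:C) {
      mu_g0[c] ~ dt(0, pow(10, -2), 1)
      mu_g1[c] ~ dt(0, pow(5, -2), 1)
      mu_g2[c] ~ dt(0, pow(5, -2), 1)
      mu_g3[c] ~ dt(0, pow(5, -2), 1)
      %s
      sigma_g0[c] ~ dt(0, pow(5, -2), 1) T(0,)
      sigma_g1[c] ~ dt(0, pow(5, -2), 1) T(0,)
      sigma_g2[c] ~ dt(0, pow(5, -2), 1) T(0,)
      sigma_g3[c] ~ dt(0, pow(5, -2), 1) T(0,)
      sigma_res[c] ~ dt(0, 1, 1) T(0,)
      tau_res[c] <- pow(sigma_res[c], -2)
    }
  }", cc_pred, cc_pop, cc_u, cc_g0, cc_hyper)
  condn <- cond_of_cell[cell]
  cmean <- function(v) vapply(seq_along(conditions), function(c)
    mean(v[condn == c]), numeric(1))
  data <- list(N = nrow(d), K = nrow(cells), C = length(conditions),
               y = log(d$rt), r = as.numeric(d$round_index),
               t = as.numeric(d$decision_index), s = d$cum_sum,
               cell = cell, cond = cond_of_cell,
               condn = condn, rbar = cmean(as.numeric(d$round_index)),
               tbar = cmean(as.numeric(d$decision_index)),
               sbar = cmean(d$cum_sum))
  if (has_conflict) {
    data$cc <- d$conflict
    data$ccbar <- cmean(d$conflict)
  }
  gset <- if (has_conflict) 0:4 else 0:3
  monitor <- c(paste0("mu_g", gset), paste0("sigma_g", gset), "sigma_res",
               paste0("g", gset))
  fit <- run_jags(model, data, monitor, mcmc,
                  inits_extra = list(mu_g0 = rep(log(0.6), length(conditions))))
  group <- lapply(seq_along(conditions), function(c) {
    lapply(stats::setNames(nm = c(paste0("mu_g", gset),
                                  paste0("sigma_g", gset), "sigma_res")),
           function(p) fit$draws[, jcols(fit$draws, p, c)])
  })
  names(group) <- conditions
  structure(list(draws = fit$draws, group = group, cells = cells,
                 rhat = fit$rhat, conditions = conditions, data = d,
                 has_conflict = has_conflict, n_dropped = n_dropped,
                 mcmc = mcmc),
            class = "rt_fit")
}

#' @export
print.rt_fit <- function(x, ...) {
  cat(sprintf("Hierarchical log-RT model: %d trials (%d dropped), %d condition(s)\n",
              nrow(x$data), x$n_dropped, length(x$conditions)))
  for (cl in x$conditions) {
    g <- x$group[[cl]]
    h <- hdi(g$mu_g3)
    cat(sprintf("  %s: cum-sum slope mean %.5f HDI [%.5f, %.5f]\n",
                cl, mean(g$mu_g3), h[1], h[2]))
  }
  invisible(x)
}

# Posterior-mean participant coefficients of the RT model, one row per cell.
rt_cell_coefficients <- function(fit) {
  k <- fit$cells$index
  out <- fit$cells
  for (i in 0:4) {
    out[[paste0("g", i)]] <- if (i == 4L && !isTRUE(fit$has_conflict)) 0 else
      colMeans(fit$draws[, jcols(fit$draws, paste0("g", i), k), drop = FALSE])
  }
  out
}

#' Posterior predictive mean RT by probability-of-stopping bin
#'
#' Buckets the modeled decisions by their fitted probability of stopping
#' (from the choice model, at posterior-mean participant coefficients),
#' simulates replicated log-RT datasets from posterior draws of the RT model,
#' and summarizes replicated mean RT per bucket against the observed means.
#' The focused contrast compares the maximum-conflict bucket (fitted p(stop)
#' nearest .5) with the maximum-stop-probability bucket (nearest 1): under
#' conflict-driven RTs the former is slower.
#'
#' @param rt_fit an `rt_fit`.
#' @param choice_fit the `choice_fit` used for the conflict series.
#' @param bins number of equal-width p(stop) bins on (0, 1).
#' @param n_draws number of thinned posterior draws to simulate.
#' @return List with `table` (per condition x bin: observed mean RT, number
#'   of decisions, replicated mean and 95% HDI; empty buckets carry NA) and
#'   `contrast` (per condition: replicated mean-RT difference max-conflict
#'   minus max-p(stop), with HDI, plus the observed difference).
#' @export
rt_posterior_predictive_by_pstop <- function(rt_fit, choice_fit, bins = 10,
                                             n_draws = 300L) {
  d <- conflict_series(choice_fit, rt_fit$data)
  co <- rt_cell_coefficients(rt_fit)
  idx_cell <- match(paste(d$participant_id, d$condition_label),
                    paste(co$participant_id, co$condition_label))
  breaks <- seq(0, 1, length.out = bins + 1)
  bin <- cut(d$p_stop, breaks, include.lowest = TRUE, labels = FALSE)
  gset <- if (isTRUE(rt_fit$has_conflict)) 0:4 else 0:3
  mu_cols <- lapply(gset, function(i)
    jcols(rt_fit$draws, paste0("g", i), rt_fit$cells$index))
  idx <- thin_index(nrow(rt_fit$draws), n_draws)
  X <- cbind(1, d$round_index, d$decision_index, d$cum_sum, d$conflict)
  X <- X[, 1 + c(0, gset[-1]), drop = FALSE]
  sig_col <- jcols(rt_fit$draws, "sigma_res",
                   match(d$condition_label, rt_fit$conditions))
  tab <- list(); ctr <- list()
  for (cl in rt_fit$conditions) {
    sel <- which(d$condition_label == cl)
    rep_means <- matrix(NA_real_, length(idx), bins)
    for (r in seq_along(idx)) {
      dr <- rt_fit$draws[idx[r], ]
      B <- vapply(mu_cols, function(cols) dr[cols][idx_cell[sel]],
                  numeric(length(sel)))
      m <- rowSums(X[sel, , drop = FALSE] * B)
      y <- stats::rnorm(length(sel), m, dr[sig_col[sel]])
      rep_means[r, ] <- vapply(seq_len(bins), function(b) {
        j <- bin[sel] == b
        if (any(j)) mean(exp(y[j])) else NA_real_
      }, numeric(1))
    }
    obs <- vapply(seq_len(bins), function(b) {
      j <- sel[bin[sel] == b]
      if (length(j)) mean(d$rt[j]) else NA_real_
    }, numeric(1))
    nb <- vapply(seq_len(bins), function(b) sum(bin[sel] == b), numeric(1))
    hd <- apply(rep_means, 2, function(v)
      if (all(is.na(v))) c(NA_real_, NA_real_) else hdi(v))
    tab[[cl]] <- data.frame(
      condition_label = cl, bin = seq_len(bins),
      p_stop_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
      n = nb, observed_mean_rt = obs,
      predicted_mean_rt = colMeans(rep_means, na.rm = TRUE),
      predicted_lower = hd[1, ], predicted_upper = hd[2, ],
      stringsAsFactors = FALSE)
    nonempty <- which(nb > 0)
    b_conf <- nonempty[which.min(abs(tab[[cl]]$p_stop_mid[nonempty] - 0.5))]
    b_stop <- nonempty[which.max(tab[[cl]]$p_stop_mid[nonempty])]
    diffs <- rep_means[, b_conf] - rep_means[, b_stop]
    hc <- hdi(diffs)
    ctr[[cl]] <- data.frame(
      condition_label = cl, bin_conflict = b_conf, bin_stop = b_stop,
      predicted_diff = mean(diffs, na.rm = TRUE),
      diff_lower = hc[1], diff_upper = hc[2],
      observed_diff = obs[b_conf] - obs[b_stop], stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, tab), contrast = do.call(rbind, ctr))
}

#' Ordinary least-squares RT slopes past the indifference point
#'
#' For each participant-by-condition cell, restricts to decisions whose
#' cumulative sum exceeds the cell's indifference point and regresses raw RT
#' (seconds) on the cumulative sum. A declining RT past the IP is the
#' signature of conflict (rather than switch value) driving response times.
#'
#' @param trials trial table with `rt`.
#' @param ips data frame `participant_id`, `condition_label`, `ip`.
#' @param min_decisions minimum post-IP decisions required per cell.
#' @return List with `per_cell` (slope in s/point, p-value, n) and `summary`
#'   per condition (mean, sd, share of cells with `p < .01`, cells skipped
#'   for lack of data).
#' @export
post_ip_rt_slopes <- function(trials, ips, min_decisions = 3L) {
  key <- paste(trials$participant_id, trials$condition_label)
  ip <- ips$ip[match(key, paste(ips$participant_id, ips$condition_label))]
  d <- trials[!is.na(trials$rt) & !is.na(ip) & trials$cum_sum > ip, ,
              drop = FALSE]
  skipped <- 0L
  per <- do.call(rbind, lapply(
    split(d, paste(d$participant_id, d$condition_label, sep = "\r")),
    function(g) {
      if (nrow(g) < min_decisions || stats::sd(g$cum_sum) == 0) {
        skipped <<- skipped + 1L
        return(NULL)
      }
      # suppressed warning: degenerate cells with an essentially perfect fit
      sm <- suppressWarnings(
        summary(stats::lm(rt ~ cum_sum, data = g)))$coefficients
      data.frame(participant_id = g$participant_id[1],
                 condition_label = g$condition_label[1],
                 slope = sm["cum_sum", "Estimate"],
                 p_value = sm["cum_sum", "Pr(>|t|)"],
                 n = nrow(g), stringsAsFactors = FALSE)
    }))
  if (is.null(per)) {
    return(list(per_cell = NULL, summary = NULL, n_skipped = skipped))
  }
  rownames(per) <- NULL
  summ <- do.call(rbind, lapply(split(per, per$condition_label), function(g) {
    data.frame(condition_label = g$condition_label[1],
               mean_slope = mean(g$slope), sd_slope = stats::sd(g$slope),
               share_p_below_.01 = mean(g$p_value < 0.01),
               n_cells = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_cell = per, summary = summ, n_skipped = skipped)
}

# Pointwise log-likelihood matrix of the RT model (thinned draws x trials).
rt_pointwise_loglik <- function(fit, n_draws = 400L) {
  d <- fit$data
  idx_cell <- match(paste(d$participant_id, d$condition_label),
                    paste(fit$cells$participant_id,
                          fit$cells$condition_label))
  X <- cbind(1, d$round_index, d$decision_index, d$cum_sum, d$conflict)
  gset <- if (isTRUE(fit$has_conflict)) 0:4 else 0:3
  mu_cols <- lapply(gset, function(i)
    jcols(fit$draws, paste0("g", i), fit$cells$index))
  sig_col <- jcols(fit$draws, "sigma_res", match(d$condition_label, fit$conditions))
  idx <- thin_index(nrow(fit$draws), n_draws)
  ll <- matrix(NA_real_, length(idx), nrow(d))
  for (r in seq_along(idx)) {
    dr <- fit$draws[idx[r], ]
    B <- vapply(mu_cols, function(cols) dr[cols][idx_cell], numeric(nrow(d)))
    m <- rowSums(X * B)
    ll[r, ] <- stats::dnorm(log(d$rt), m, dr[sig_col], log = TRUE)
  }
  ll
}
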