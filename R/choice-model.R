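#' Hierarchical Bayesian logistic regression of stop/continue choices
#'
#' Models the probability of stopping as a logistic function of the cumulative
#' sum of rewards, with separate regressors per task condition:
#' `p(stop)_t = logistic(beta0 + beta1 * cum_sum_t)`. Participant coefficients
#' are drawn from condition-specific group normals; hyper-priors are
#' `mu_beta0 ~ Cauchy(0,5)`, `sigma_beta0 ~ HalfCauchy(0,1)`,
#' `mu_beta1 ~ Cauchy(0,1)`, `sigma_beta1 ~ HalfCauchy(0,0.5)`.
#' The indifference point `-beta0/beta1` (where `p(stop) = 0.5`) is derived
#' per posterior draw. Fitted with JAGS.
#'
#' Participant-by-condition cells lacking at least one stop and one continue
#' decision are inestimable, excluded from the hierarchy, and listed in the
#' returned `excluded` data frame.
#'
#' @param trials canonical trial table (`participant_id`, `condition_label`,
#'   `cum_sum`, `choice`; see [write_trials()]). Rows with `choice` not in
#'   stop/continue are dropped.
#' @param mcmc an [mcmc_settings()].
#' @return Object of class `choice_fit`: `draws` (matrix, retained draws x
#'   parameters), `group` (per-condition group-parameter draws incl. derived
#'   `ip`), `cells` (participant x condition map to coefficient columns),
#'   `excluded`, `rhat`, `conditions`, `data` (the modeled rows), `mcmc`.
#' @export
fit_choice_model <- function(trials, mcmc = mcmc_settings()) {
  d <- trials[trials$choice %in% c("stop", "continue"), , drop = FALSE]
  if (nrow(d) == 0L) stop("no stop/continue decisions in trials")
  conditions <- unique(d$condition_label)
  cell_key <- paste(d$participant_id, d$condition_label, sep = "\r")
  tab <- tapply(d$choice == "stop", cell_key, function(z) c(sum(z), sum(!z)))
  ok <- vapply(tab, function(z) all(z >= 1), logical(1))
  excluded <- do.call(rbind, lapply(names(tab)[!ok], function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    data.frame(participant_id = parts[1], condition_label = parts[2],
               reason = "needs >= 1 stop and >= 1 continue decision",
               stringsAsFactors = FALSE)
  }))
  if (is.null(excluded)) {
    excluded <- data.frame(participant_id = character(0),
                           condition_label = character(0),
                           reason = character(0), stringsAsFactors = FALSE)
  }
  keep <- ok[cell_key]
  d <- d[keep, , drop = FALSE]
  cell_key <- cell_key[keep]
  cells_id <- sort(unique(cell_key))
  cell <- match(cell_key, cells_id)
  cell_info <- do.call(rbind, strsplit(cells_id, "\r", fixed = TRUE))
  cells <- data.frame(index = seq_along(cells_id),
                      participant_id = cell_info[, 1],
                      condition_label = cell_info[, 2],
                      stringsAsFactors = FALSE)
  cond_of_cell <- match(cells$condition_label, conditions)

  # Sampled in an exactly equivalent centered form: u_k = b0_k + xbar_c b1_k
  # is the linear predictor at the condition-mean covariate, so u and b1 are
  # nearly uncorrelated in the likelihood; the conditional prior
  # u | b1 ~ N(mu_b0 + xbar b1, sigma_b0^2) reproduces independent normal
  # populations on (b0, b1) exactly.
  model <- "
  model {
    for (n in 1:N) {
      y[n] ~ dbern(p[n])
      logit(p[n]) <- u[cell[n]] + b1[cell[n]] * (x[n] - xbar[condn[n]])
    }
    for (k in 1:K) {
      b1[k] ~ dnorm(mu_b1[cond[k]], tau_b1[cond[k]])
      u[k] ~ dnorm(mu_b0[cond[k]] + xbar[cond[k]] * b1[k], tau_b0[cond[k]])
      b0[k] <- u[k] - xbar[cond[k]] * b1[k]
    }
    for (c in 1:C) {
      mu_b0[c] ~ dt(0, pow(5, -2), 1)
      sigma_b0[c] ~ dt(0, 1, 1) T(0,)
      mu_b1[c] ~ dt(0, 1, 1)
      sigma_b1[c] ~ dt(0, pow(0.5, -2), 1) T(0,)
      tau_b0[c] <- pow(sigma_b0[c], -2)
      tau_b1[c] <- pow(sigma_b1[c], -2)
    }
  }"
  xbar <- vapply(conditions, function(cl)
    mean(d$cum_sum[d$condition_label == cl]), numeric(1))
  data <- list(N = nrow(d), K = nrow(cells), C = length(conditions),
               y = as.integer(d$choice == "stop"), x = d$cum_sum,
               cell = cell, cond = cond_of_cell,
               condn = cond_of_cell[cell], xbar = unname(xbar))
  fit <- run_jags(model, data,
                  monitor = c("mu_b0", "sigma_b0", "mu_b1", "sigma_b1",
                              "b0", "b1"),
                  mcmc = mcmc,
                  inits_extra = list(mu_b1 = rep(0.02, length(conditions))))
  group <- lapply(seq_along(conditions), function(c) {
    g <- list(mu_b0 = fit$draws[, jcols(fit$draws, "mu_b0", c)],
              sigma_b0 = fit$draws[, jcols(fit$draws, "sigma_b0", c)],
              mu_b1 = fit$draws[, jcols(fit$draws, "mu_b1", c)],
              sigma_b1 = fit$draws[, jcols(fit$draws, "sigma_b1", c)])
    g$ip <- ip_from_coefficients(g$mu_b0, g$mu_b1)
    g
  })
  names(group) <- conditions
  structure(list(draws = fit$draws, group = group, cells = cells,
                 excluded = excluded, rhat = fit$rhat,
                 conditions = conditions, data = d, mcmc = mcmc),
            class = "choice_fit")
}

#' @export
print.choice_fit <- function(x, ...) {
  cat(sprintf("Hierarchical logistic choice model: %d decisions, %d cells, %d condition(s)\n",
              nrow(x$data), nrow(x$cells), length(x$conditions)))
  for (cl in x$conditions) {
    g <- x$group[[cl]]
    hs <- hdi(g$mu_b1); hi <- hdi(g$ip)
    cat(sprintf("  %s: slope mean %.4f HDI [%.4f, %.4f]; group IP HDI [%.1f, %.1f]\n",
                cl, mean(g$mu_b1), hs[1], hs[2], hi[1], hi[2]))
  }
  cat(sprintf("  max R-hat %.3f; %d cell(s) excluded\n",
              max(x$rhat, na.rm = TRUE), nrow(x$excluded)))
  invisible(x)
}

#' Indifference point from logistic coefficients
#'
#' The cumulative sum at which the fitted choice probability is one half:
#' `-beta0 / beta1`. Applied per posterior draw it yields an IP distribution;
#' it is invariant to joint rescaling of the two coefficients.
#'
#' @param beta0,beta1 intercept and slope (vectors of draws or scalars).
#' @return Numeric vector of indifference points (points).
#' @export
ip_from_coefficients <- function(beta0, beta1) {
  if (any(beta1 == 0)) stop("beta1 = 0: indifference point undefined")
  -beta0 / beta1
}

# Posterior-mean participant coefficients, one row per cell.
cell_coefficients <- function(fit) {
  k <- fit$cells$index
  data.frame(fit$cells,
             b0 = colMeans(fit$draws[, jcols(fit$draws, "b0", k), drop = FALSE]),
             b1 = colMeans(fit$draws[, jcols(fit$draws, "b1", k), drop = FALSE]),
             stringsAsFactors = FALSE)
}

#' Trial-wise choice conflict from a fitted choice model
#'
#' Conflict is the derivative of the fitted logistic choice curve at the
#' trial's cumulative sum, `cc_t = |beta1| p_t (1 - p_t)` evaluated at the
#' posterior means of the participant coefficients. It is maximal
#' (`|beta1|/4`) at the indifference point and decays symmetrically in the
#' choice probability on both sides.
#'
#' @param fit a `choice_fit`.
#' @param trials trial table to score (defaults to the fitted data).
#' @return `trials` with columns `p_stop` and `conflict` appended (NA for
#'   cells excluded from the fit).
#' @export
conflict_series <- function(fit, trials = fit$data) {
  co <- cell_coefficients(fit)
  idx <- match(paste(trials$participant_id, trials$condition_label),
               paste(co$participant_id, co$condition_label))
  b0 <- co$b0[idx]; b1 <- co$b1[idx]
  p <- stats::plogis(b0 + b1 * trials$cum_sum)
  out <- trials
  out$p_stop <- p
  out$conflict <- abs(b1) * p * (1 - p)
  out
}

#' Collinearity of conflict and cumulative reward
#'
#' Spearman rank correlation between the estimated trial conflict and the
#' cumulative sum of rewards, per participant and condition: the diagnostic
#' of whether switch value and choice conflict can be dissociated. Near the
#' standard (1/6) regime almost all decisions lie below the indifference
#' point, so conflict rises monotonically with the cumulative sum and the
#' correlation approaches +1; regimes with many past-IP decisions push it
#' down and eventually negative.
#'
#' @param conflict output of [conflict_series()].
#' @param min_decisions minimum decisions per participant x condition cell.
#' @return List with `per_cell` (participant, condition, rho, p_value, n) and
#'   `summary` per condition (mean, sd, share with `rho > 0.9`, share with
#'   `rho < -0.9`, share of `p < .01`).
#' @export
conflict_value_collinearity <- function(conflict, min_decisions = 3L) {
  d <- conflict[!is.na(conflict$conflict), , drop = FALSE]
  key <- paste(d$participant_id, d$condition_label, sep = "\r")
  per <- do.call(rbind, lapply(split(d, key), function(g) {
    if (nrow(g) < min_decisions || stats::sd(g$conflict) == 0 ||
        stats::sd(g$cum_sum) == 0) {
      rho <- NA_real_; pv <- NA_real_
    } else {
      ct <- suppressWarnings(
        stats::cor.test(g$conflict, g$cum_sum, method = "spearman"))
      rho <- unname(ct$estimate); pv <- ct$p.value
    }
    data.frame(participant_id = g$participant_id[1],
               condition_label = g$condition_label[1],
               rho = rho, p_value = pv, n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  summ <- do.call(rbind, lapply(split(per, per$condition_label), function(g) {
    data.frame(condition_label = g$condition_label[1],
               mean_rho = mean(g$rho, na.rm = TRUE),
               sd_rho = stats::sd(g$rho, na.rm = TRUE),
               share_above_0.9 = mean(g$rho > 0.9, na.rm = TRUE),
               share_below_m0.9 = mean(g$rho < -0.9, na.rm = TRUE),
               share_p_below_.01 = mean(g$p_value < 0.01, na.rm = TRUE),
               n_cells = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_cell = per, summary = summ)
}

#' Odds ratio and Bayesian R-squared of the choice model
#'
#' The odds ratio is `exp` of the posterior-mean group slope (the
#' multiplicative change in stop odds per point of cumulative reward). The
#' Bayesian R-squared is computed per posterior draw on the probability
#' scale as `var(fitted p) / (var(fitted p) + mean(p (1 - p)))`, i.e.
#' explained variance over explained-plus-expected Bernoulli residual
#' variance, summarized by the median and 95% HDI.
#'
#' @param fit a `choice_fit`.
#' @param n_draws number of (thinned) draws used for the R-squared.
#' @return Data frame per condition: `odds_ratio`, `r2_median`, `r2_lower`,
#'   `r2_upper`.
#' @export
choice_fit_summaries <- function(fit, n_draws = 400L) {
  rows <- lapply(fit$conditions, function(cl) {
    sel <- fit$data$condition_label == cl
    d <- fit$data[sel, , drop = FALSE]
    cell <- match(paste(d$participant_id, d$condition_label),
                  paste(fit$cells$participant_id, fit$cells$condition_label))
    b0_cols <- jcols(fit$draws, "b0", fit$cells$index)
    b1_cols <- jcols(fit$draws, "b1", fit$cells$index)
    idx <- thin_index(nrow(fit$draws), n_draws)
    r2 <- vapply(idx, function(i) {
      b0 <- fit$draws[i, b0_cols][cell]
      b1 <- fit$draws[i, b1_cols][cell]
      p <- stats::plogis(b0 + b1 * d$cum_sum)
      vp <- stats::var(p)
      vp / (vp + mean(p * (1 - p)))
    }, numeric(1))
    h <- hdi(r2)
    data.frame(condition_label = cl,
               odds_ratio = exp(mean(fit$group[[cl]]$mu_b1)),
               r2_median = stats::median(r2), r2_lower = h[1], r2_upper = h[2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Pointwise log-likelihood matrix (thinned draws x decisions) of the choice
# model, for WAIC.
choice_pointwise_loglik <- function(fit, n_draws = 400L) {
  d <- fit$data
  cell <- match(paste(d$participant_id, d$condition_label),
                paste(fit$cells$participant_id, fit$cells$condition_label))
  b0_cols <- jcols(fit$draws, "b0", fit$cells$index)
  b1_cols <- jcols(fit$draws, "b1", fit$cells$index)
  y <- as.integer(d$choice == "stop")
  idx <- thin_index(nrow(fit$draws), n_draws)
  ll <- matrix(NA_real_, length(idx), nrow(d))
  for (r in seq_along(idx)) {
    b0 <- fit$draws[idx[r], b0_cols][cell]
    b1 <- fit$draws[idx[r], b1_cols][cell]
    eta <- b0 + b1 * d$cum_sum
    ll[r, ] <- ifelse(y == 1L, stats::plogis(eta, log.p = TRUE),
                      stats::plogis(-eta, log.p = TRUE))
  }
  ll
}
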