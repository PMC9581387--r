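#' MCMC settings for the hierarchical diffusion model
#'
#' Defaults mirror the sequential-sampling fitting recipe: 4 chains of 8000
#' iterations with the first 7000 discarded. Tests and examples scale these
#' down. The sampler is an adaptive Metropolis-within-Gibbs: participant
#' coefficients are updated component-wise with random-walk proposals tuned
#' during warmup, group means and scales with random-walk proposals on the
#' natural and log scale respectively.
#'
#' @param chains number of chains.
#' @param iter iterations per chain (including warmup).
#' @param warmup iterations discarded per chain.
#' @param keep number of retained draws (pooled over chains) used for
#'   pointwise log-likelihoods and posterior predictives.
#' @param err Wiener density truncation tolerance.
#' @param seed integer seed.
#' @return List of class `ddm_mcmc_settings`.
#' @export
ddm_mcmc_settings <- function(chains = 4, iter = 8000, warmup = 7000,
                              keep = 400, err = 1e-7, seed = 1L) {
  stopifnot(chains >= 1, iter > warmup, warmup >= 1)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), keep = as.integer(keep),
                 err = err, seed = as.integer(seed)),
            class = "ddm_mcmc_settings")
}

# Parameter table of one variant: one row per scalar participant coefficient.
# Hyper-priors: Normal(0,10)/HalfNormal(0,10) for drift, threshold, and
# non-decision time; Normal(0,0.8)/HalfNormal(0,0.5) for the starting point.
ddm_par_table <- function(variant) {
  rows <- list(data.frame(name = "d0", mu_scale = 10, sigma_scale = 10,
                          stringsAsFactors = FALSE))
  if (variant$drift_modulator != "none") {
    rows <- c(rows, list(data.frame(name = "d1", mu_scale = 10,
                                    sigma_scale = 10)))
  }
  rows <- c(rows, list(data.frame(name = "a0", mu_scale = 10, sigma_scale = 10)))
  if (variant$threshold_modulator != "none") {
    rows <- c(rows, list(data.frame(name = "a1", mu_scale = 10,
                                    sigma_scale = 10)))
  }
  rows <- c(rows, list(data.frame(name = "z0", mu_scale = 0.8,
                                  sigma_scale = 0.5)))
  if (variant$start_modulator != "none") {
    rows <- c(rows, list(data.frame(name = "z1", mu_scale = 0.8,
                                    sigma_scale = 0.5)))
  }
  rows <- c(rows, list(data.frame(name = "ter", mu_scale = 10,
                                  sigma_scale = 10)))
  do.call(rbind, rows)
}

# Map a psi row (participant coefficient vector) to the full
# (d0,d1,a0,a1,z0,z1,ter) argument set, zeros for absent slopes.
psi_to_args <- function(psi, pos) {
  c(d0 = psi[pos["d0"]],
    d1 = if (is.na(pos["d1"])) 0 else psi[pos["d1"]],
    a0 = psi[pos["a0"]],
    a1 = if (is.na(pos["a1"])) 0 else psi[pos["a1"]],
    z0 = psi[pos["z0"]],
    z1 = if (is.na(pos["z1"])) 0 else psi[pos["z1"]],
    ter = psi[pos["ter"]])
}

# One MCMC chain for one condition. dat: list of per-participant lists
# (rt, stop, xd, xa, xz, minrt). Returns group draws, thinned psi draws.
run_ddm_chain <- function(dat, par, mcmc, keep_psi) {
  J <- length(dat)
  P <- nrow(par)
  pos <- stats::setNames(match(c("d0", "d1", "a0", "a1", "z0", "z1", "ter"),
                               par$name),
                         c("d0", "d1", "a0", "a1", "z0", "z1", "ter"))
  is_ter <- par$name == "ter"
  ub <- vapply(dat, function(x) 0.99 * x$minrt, numeric(1))
  cov_sd <- vapply(seq_len(P), function(p) {
    x <- switch(substr(par$name[p], 1, 1),
                d = unlist(lapply(dat, `[[`, "xd")),
                a = unlist(lapply(dat, `[[`, "xa")),
                z = unlist(lapply(dat, `[[`, "xz")))
    if (grepl("1$", par$name[p])) max(stats::sd(x), 1e-6) else 1
  }, numeric(1))

  loglik_j <- function(j, psi_row) {
    a <- psi_to_args(psi_row, pos)
    wiener_loglik_sum(dat[[j]]$rt, dat[[j]]$stop, dat[[j]]$xd, dat[[j]]$xa,
                      dat[[j]]$xz, a["d0"], a["d1"], a["a0"], a["a1"],
                      a["z0"], a["z1"], a["ter"], mcmc$err)
  }

  # Initialization: modest drift, boundary near softplus^{-1}(1.5), centered
  # start, non-decision time at half the participant's fastest response.
  psi <- matrix(0, J, P)
  for (p in seq_len(P)) {
    psi[, p] <- switch(par$name[p],
      d0 = stats::rnorm(J, 0, 0.3),
      d1 = stats::rnorm(J, 0, 0.2 / cov_sd[p]),
      a0 = stats::rnorm(J, 1.2, 0.2),
      a1 = stats::rnorm(J, 0, 0.05 / cov_sd[p]),
      z0 = stats::rnorm(J, 0, 0.15),
      z1 = stats::rnorm(J, 0, 0.05 / cov_sd[p]),
      ter = ub * stats::runif(J, 0.3, 0.6))
  }
  mu <- colMeans(psi)
  sigma <- pmax(apply(psi, 2, stats::sd), 0.05)
  cur_ll <- vapply(seq_len(J), function(j) loglik_j(j, psi[j, ]), numeric(1))
  if (any(!is.finite(cur_ll))) {
    for (j in which(!is.finite(cur_ll))) {   # safer fallback start
      psi[j, pos["d0"]] <- 0
      psi[j, pos["a0"]] <- 1.5
      psi[j, pos["z0"]] <- 0
      psi[j, is_ter] <- 0.2 * ub[j]
      cur_ll[j] <- loglik_j(j, psi[j, ])
    }
  }

  # log prior of one participant coefficient given its group parameters.
  # The non-decision time is hard-bounded to [0, 0.99 min RT_j]; following
  # the field convention for bounded DDM parameters, the bound acts as an
  # indicator on the joint prior (no mu/sigma-dependent renormalization), so
  # the group mean stays identified by the coefficient values themselves.
  lp_coef <- function(val, p, j, mu_p, sigma_p) {
    if (is_ter[p] && (val < 0 || val > ub[j])) return(-Inf)
    stats::dnorm(val, mu_p, sigma_p, log = TRUE)
  }
  group_lp <- function(p, mu_p, sigma_p) {
    sum(stats::dnorm(psi[, p], mu_p, sigma_p, log = TRUE)) +
      stats::dnorm(mu_p, 0, par$mu_scale[p], log = TRUE) +
      stats::dnorm(sigma_p, 0, par$sigma_scale[p], log = TRUE) + log(sigma_p)
  }

  step_psi <- matrix(rep(0.2 / cov_sd, each = J), J, P)
  step_psi[, is_ter] <- 0.1 * ub
  step_mu <- 0.2 / cov_sd
  step_mu[is_ter] <- 0.05 * stats::median(ub)
  step_lsig <- rep(0.3, P)
  acc_psi <- matrix(0, J, P); acc_mu <- numeric(P); acc_sig <- numeric(P)
  batch <- 50L

  # Intercept/slope pairs share a likelihood ridge (the predictor at the
  # participant's typical covariate is well determined, the two coefficients
  # separately are not). Extra joint proposals move along that ridge:
  # slope += delta, intercept -= delta * mean covariate.
  pairs <- list()
  for (nm in c("d", "a", "z")) {
    pi0 <- match(paste0(nm, "0"), par$name)
    pi1 <- match(paste0(nm, "1"), par$name)
    if (!is.na(pi1)) {
      xbar_j <- vapply(dat, function(x)
        mean(switch(nm, d = x$xd, a = x$xa, z = x$xz)), numeric(1))
      pairs[[length(pairs) + 1L]] <- list(int = pi0, slo = pi1,
                                          xbar = xbar_j)
    }
  }
  step_pair <- matrix(0.1 / pmax(cov_sd[vapply(pairs, `[[`, 0L, "slo")], 1e-12),
                      J, length(pairs), byrow = TRUE)
  acc_pair <- matrix(0, J, max(1L, length(pairs)))

  n_keep <- mcmc$iter - mcmc$warmup
  group_out <- matrix(NA_real_, n_keep, 2L * P)
  colnames(group_out) <- c(paste0("mu_", par$name), paste0("sigma_", par$name))
  psi_keep_at <- mcmc$warmup +
    thin_index(n_keep, max(1L, keep_psi))
  psi_out <- array(NA_real_, c(length(psi_keep_at), J, P))
  kp <- 0L

  for (it in seq_len(mcmc$iter)) {
    for (j in seq_len(J)) {
      for (p in seq_len(P)) {
        prop <- psi[j, p] + stats::rnorm(1, 0, step_psi[j, p])
        lp0 <- lp_coef(psi[j, p], p, j, mu[p], sigma[p])
        lp1 <- lp_coef(prop, p, j, mu[p], sigma[p])
        if (is.finite(lp1)) {
          cand <- psi[j, ]; cand[p] <- prop
          ll1 <- loglik_j(j, cand)
          if (log(stats::runif(1)) < (ll1 + lp1) - (cur_ll[j] + lp0)) {
            psi[j, p] <- prop; cur_ll[j] <- ll1
            acc_psi[j, p] <- acc_psi[j, p] + 1
          }
        }
      }
    }
    for (q in seq_along(pairs)) {
      pr <- pairs[[q]]
      for (j in seq_len(J)) {
        delta <- stats::rnorm(1, 0, step_pair[j, q])
        cand <- psi[j, ]
        cand[pr$slo] <- cand[pr$slo] + delta
        cand[pr$int] <- cand[pr$int] - delta * pr$xbar[j]
        lp0 <- stats::dnorm(psi[j, pr$int], mu[pr$int], sigma[pr$int], TRUE) +
          stats::dnorm(psi[j, pr$slo], mu[pr$slo], sigma[pr$slo], TRUE)
        lp1 <- stats::dnorm(cand[pr$int], mu[pr$int], sigma[pr$int], TRUE) +
          stats::dnorm(cand[pr$slo], mu[pr$slo], sigma[pr$slo], TRUE)
        ll1 <- loglik_j(j, cand)
        if (log(stats::runif(1)) < (ll1 + lp1) - (cur_ll[j] + lp0)) {
          psi[j, ] <- cand; cur_ll[j] <- ll1
          acc_pair[j, q] <- acc_pair[j, q] + 1
        }
      }
    }
    # group-level ridge move: shear all participants and the group means
    # along the shared intercept/slope ridge (volume-preserving map)
    for (q in seq_along(pairs)) {
      pr <- pairs[[q]]
      delta <- stats::rnorm(1, 0, stats::median(step_pair[, q]) / sqrt(J))
      cand_psi <- psi
      cand_psi[, pr$slo] <- cand_psi[, pr$slo] + delta
      cand_psi[, pr$int] <- cand_psi[, pr$int] - delta * pr$xbar
      cand_mu <- mu
      cand_mu[pr$slo] <- cand_mu[pr$slo] + delta
      cand_mu[pr$int] <- cand_mu[pr$int] - delta * mean(pr$xbar)
      lp0 <- sum(stats::dnorm(psi[, pr$int], mu[pr$int], sigma[pr$int], TRUE)) +
        sum(stats::dnorm(psi[, pr$slo], mu[pr$slo], sigma[pr$slo], TRUE)) +
        stats::dnorm(mu[pr$int], 0, par$mu_scale[pr$int], TRUE) +
        stats::dnorm(mu[pr$slo], 0, par$mu_scale[pr$slo], TRUE)
      lp1 <- sum(stats::dnorm(cand_psi[, pr$int], cand_mu[pr$int],
                              sigma[pr$int], TRUE)) +
        sum(stats::dnorm(cand_psi[, pr$slo], cand_mu[pr$slo],
                         sigma[pr$slo], TRUE)) +
        stats::dnorm(cand_mu[pr$int], 0, par$mu_scale[pr$int], TRUE) +
        stats::dnorm(cand_mu[pr$slo], 0, par$mu_scale[pr$slo], TRUE)
      ll1 <- vapply(seq_len(J), function(j) loglik_j(j, cand_psi[j, ]),
                    numeric(1))
      if (log(stats::runif(1)) < (sum(ll1) + lp1) - (sum(cur_ll) + lp0)) {
        psi <- cand_psi; mu <- cand_mu; cur_ll <- ll1
      }
    }
    for (p in seq_len(P)) {
      prop <- mu[p] + stats::rnorm(1, 0, step_mu[p])
      if (log(stats::runif(1)) < group_lp(p, prop, sigma[p]) -
          group_lp(p, mu[p], sigma[p])) {
        mu[p] <- prop; acc_mu[p] <- acc_mu[p] + 1
      }
      prop <- sigma[p] * exp(stats::rnorm(1, 0, step_lsig[p]))
      if (log(stats::runif(1)) < group_lp(p, mu[p], prop) -
          group_lp(p, mu[p], sigma[p])) {
        sigma[p] <- prop; acc_sig[p] <- acc_sig[p] + 1
      }
    }
    if (it <= mcmc$warmup && it %% batch == 0L) {
      f <- function(acc) exp(pmin(pmax(acc / batch - 0.44, -0.5), 0.5))
      step_psi <- step_psi * f(acc_psi)
      step_mu <- step_mu * f(acc_mu)
      step_lsig <- pmin(step_lsig * f(acc_sig), 2)
      if (length(pairs)) step_pair <- step_pair * f(acc_pair)
      acc_psi[] <- 0; acc_mu[] <- 0; acc_sig[] <- 0; acc_pair[] <- 0
    }
    if (it > mcmc$warmup) {
      group_out[it - mcmc$warmup, ] <- c(mu, sigma)
      if (kp < length(psi_keep_at) && it == psi_keep_at[kp + 1L]) {
        kp <- kp + 1L
        psi_out[kp, , ] <- psi
      }
    }
  }
  list(group = group_out, psi = psi_out, par_names = par$name)
}

#' Fit a hierarchical diffusion decision model variant
#'
#' Joint choice/RT likelihood via the Wiener first-passage density, with the
#' variant's trial-wise links: drift `d0 + d1 x`, threshold
#' `softplus(a0 + a1 x)`, starting point `Phi(z0 + z1 x)`, plus a
#' per-participant non-decision time bounded above by 99% of that
#' participant's fastest response. "Stop" maps to the upper boundary.
#' Separate parameter sets (including hyper-parameters) are estimated for
#' each condition. Participant coefficients are drawn from group normals with
#' `Normal(0,10)`/`HalfNormal(0,10)` hyper-priors (drift, threshold,
#' non-decision time) and `Normal(0,0.8)`/`HalfNormal(0,0.5)` (starting
#' point).
#'
#' @param trials canonical trial table with positive `rt` and stop/continue
#'   `choice` for every modeled row.
#' @param variant a [ddm_model_space()] row or `variant_id` string.
#' @param mcmc a [ddm_mcmc_settings()].
#' @return Object of class `ddm_fit`: per-condition `fits` (group draw
#'   matrix, thinned participant-coefficient array, `rhat` of group
#'   parameters, pointwise log-likelihood matrix, participant ids, data),
#'   the pooled `loglik` matrix (draws x all trials) for [waic()],
#'   `conditions`, `variant`, `mcmc`.
#' @export
fit_ddm <- function(trials, variant, mcmc = ddm_mcmc_settings()) {
  if (is.character(variant)) variant <- ddm_variant(variant)
  d <- trials[trials$choice %in% c("stop", "continue") & !is.na(trials$rt), ,
              drop = FALSE]
  if (any(d$rt <= 0)) stop("all modeled RTs must be positive")
  conditions <- unique(d$condition_label)
  par <- ddm_par_table(variant)
  keep_psi_chain <- max(1L, ceiling(mcmc$keep / mcmc$chains))
  fits <- list()
  for (ci in seq_along(conditions)) {
    dc <- d[d$condition_label == conditions[ci], , drop = FALSE]
    ids <- unique(dc$participant_id)
    dat <- lapply(ids, function(id) {
      g <- dc[dc$participant_id == id, , drop = FALSE]
      list(rt = g$rt, stop = as.integer(g$choice == "stop"),
           xd = modulator_covariate(variant$drift_modulator, g$cum_sum,
                                    g$decision_index),
           xa = modulator_covariate(variant$threshold_modulator, g$cum_sum,
                                    g$decision_index),
           xz = modulator_covariate(variant$start_modulator, g$cum_sum,
                                    g$decision_index),
           minrt = min(g$rt))
    })
    chains <- lapply(seq_len(mcmc$chains), function(ch) {
      set.seed((mcmc$seed + 1009L * ci + 7919L * ch) %% 2147483647L)
      run_ddm_chain(dat, par, mcmc, keep_psi_chain)
    })
    group <- do.call(rbind, lapply(chains, `[[`, "group"))
    psi <- do.call(abind1, lapply(chains, `[[`, "psi"))
    rhat <- rhat_values(coda::mcmc.list(
      lapply(chains, function(ch) coda::mcmc(ch$group))))
    # pointwise log-likelihood over retained participant draws
    ordc <- order(match(dc$participant_id, ids))
    ll <- matrix(NA_real_, dim(psi)[1], nrow(dc))
    pos <- stats::setNames(match(c("d0", "d1", "a0", "a1", "z0", "z1", "ter"),
                                 par$name),
                           c("d0", "d1", "a0", "a1", "z0", "z1", "ter"))
    col0 <- 0L
    for (j in seq_along(ids)) {
      nj <- length(dat[[j]]$rt)
      for (r in seq_len(dim(psi)[1])) {
        a <- psi_to_args(psi[r, j, ], pos)
        ll[r, col0 + seq_len(nj)] <-
          wiener_loglik_vec(dat[[j]]$rt, dat[[j]]$stop, dat[[j]]$xd,
                            dat[[j]]$xa, dat[[j]]$xz, a["d0"], a["d1"],
                            a["a0"], a["a1"], a["z0"], a["z1"], a["ter"],
                            mcmc$err)
      }
      col0 <- col0 + nj
    }
    # rows of dc in participant-block order, for aligning ll columns
    dc_blocked <- dc[order(match(dc$participant_id, ids)), , drop = FALSE]
    fits[[conditions[ci]]] <- list(
      group = group, psi = psi, par_names = par$name, rhat = rhat,
      loglik = ll, participants = ids, data = dc_blocked, dat = dat)
  }
  loglik_all <- do.call(cbind, lapply(fits, `[[`, "loglik"))
  structure(list(fits = fits, conditions = conditions, variant = variant,
                 par_names = par$name, loglik = loglik_all, mcmc = mcmc),
            class = "ddm_fit")
}

# rbind along the first dimension of 3-d arrays
abind1 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(NA_real_, c(sum(vapply(xs, function(x) dim(x)[1], numeric(1))),
                           d[2], d[3]))
  at <- 0L
  for (x in xs) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("Hierarchical DDM fit, variant '%s' (%d condition(s))\n",
              x$variant$variant_id, length(x$conditions)))
  for (cl in x$conditions) {
    f <- x$fits[[cl]]
    mu_d0 <- f$group[, "mu_d0"]
    cat(sprintf("  %s: mu_d0 mean %.3f; max group R-hat %.3f; %d participants\n",
                cl, mean(mu_d0), max(f$rhat, na.rm = TRUE),
                length(f$participants)))
  }
  invisible(x)
}

#' Group-level coefficient summary of a DDM fit
#'
#' @param fit a `ddm_fit`.
#' @return Data frame: condition, parameter, mean, 95% HDI, R-hat; plus the
#'   derived group indifference point (`-mu_d0/mu_d1` per draw) when the
#'   drift is modulated by the cumulative sum.
#' @export
ddm_group_summary <- function(fit) {
  rows <- list()
  for (cl in fit$conditions) {
    f <- fit$fits[[cl]]
    for (p in colnames(f$group)) {
      h <- hdi(f$group[, p])
      rows[[length(rows) + 1L]] <- data.frame(
        condition_label = cl, parameter = p, mean = mean(f$group[, p]),
        lower = h[1], upper = h[2], rhat = unname(f$rhat[p]),
        stringsAsFactors = FALSE)
    }
    if (fit$variant$drift_modulator == "cumulative_sum") {
      ip <- ip_from_drift(f$group[, "mu_d0"], f$group[, "mu_d1"])
      h <- hdi(ip)
      rows[[length(rows) + 1L]] <- data.frame(
        condition_label = cl, parameter = "ip", mean = mean(ip),
        lower = h[1], upper = h[2], rhat = NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Widely applicable information criterion
#'
#' `WAIC = -2 * sum_i [ log mean_d exp(ll_di) - var_d(ll_di) ]` over trials
#' `i` and posterior draws `d`, with the effective number of parameters
#' `p_waic = sum_i var_d(ll_di)`. The standard error scales the trial-wise
#' dispersion of the pointwise contributions by `sqrt(n)`.
#'
#' @param loglik pointwise log-likelihood matrix (draws x trials) or an
#'   object with a `loglik` element (e.g. a `ddm_fit`).
#' @return List with `waic`, `se`, `p_waic`, `elpd`, and the `pointwise`
#'   per-trial contributions (on the -2 log scale).
#' @export
waic <- function(loglik) {
  if (is.list(loglik) && !is.null(loglik$loglik)) loglik <- loglik$loglik
  if (!is.matrix(loglik) || any(!is.finite(loglik))) {
    stop("loglik must be a finite draws x trials matrix")
  }
  # column-wise log-mean-exp, guarded against underflow
  m <- apply(loglik, 2, max)
  lpd <- m + log(colMeans(exp(sweep(loglik, 2, m))))
  pw <- if (nrow(loglik) > 1L) apply(loglik, 2, stats::var) else
    numeric(ncol(loglik))
  pointwise <- -2 * (lpd - pw)
  n <- ncol(loglik)
  list(waic = sum(pointwise), se = sqrt(n * stats::var(pointwise)),
       p_waic = sum(pw), elpd = sum(lpd - pw), pointwise = pointwise)
}

#' Fit and compare DDM variants by WAIC
#'
#' Fits each requested variant to the same trials and ranks them by WAIC.
#' The difference SE against the best model uses the paired pointwise
#' contributions; a variant is "not credibly worse" than the best when its
#' WAIC difference does not exceed that SE.
#'
#' @param trials canonical trial table.
#' @param variant_ids character vector of variant ids (default: all 19).
#' @param mcmc a [ddm_mcmc_settings()].
#' @return List with `table` (variant, modulators, waic, se, p_waic, rank,
#'   delta_waic, delta_se, not_credibly_worse) and `fits` (named list of
#'   `ddm_fit` objects).
#' @export
compare_ddm_variants <- function(trials,
                                 variant_ids = ddm_model_space()$variant_id,
                                 mcmc = ddm_mcmc_settings()) {
  fits <- list(); ws <- list()
  for (v in variant_ids) {
    fits[[v]] <- fit_ddm(trials, v, mcmc)
    ws[[v]] <- waic(fits[[v]])
  }
  space <- ddm_model_space()
  tab <- do.call(rbind, lapply(variant_ids, function(v) {
    row <- space[space$variant_id == v, ]
    data.frame(variant_id = v, drift_modulator = row$drift_modulator,
               threshold_modulator = row$threshold_modulator,
               start_modulator = row$start_modulator,
               waic = ws[[v]]$waic, se = ws[[v]]$se, p_waic = ws[[v]]$p_waic,
               stringsAsFactors = FALSE)
  }))
  tab$rank <- rank(tab$waic, ties.method = "first")
  best <- variant_ids[which.min(tab$waic)]
  tab$delta_waic <- tab$waic - min(tab$waic)
  tab$delta_se <- vapply(variant_ids, function(v) {
    if (v == best) return(0)
    dvec <- ws[[v]]$pointwise - ws[[best]]$pointwise
    sqrt(length(dvec) * stats::var(dvec))
  }, numeric(1))
  tab$not_credibly_worse <- tab$delta_waic <= tab$delta_se
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}

#' Posterior predictive checks of a DDM fit
#'
#' Simulates replicated datasets from retained posterior draws, buckets
#' decisions by the model-implied probability of stopping (analytic Wiener
#' absorption probability at posterior-mean participant coefficients), and
#' summarizes replicated mean RT per bucket with the observed means plus the
#' maximum-conflict (p near .5) versus maximum-p(stop) contrast. Also reports
#' per-participant fractions of decisions past the DDM-derived indifference
#' point (`-d0/d1` at posterior means) when the drift is modulated by the
#' cumulative sum.
#'
#' @param fit a `ddm_fit`.
#' @param bins number of p(stop) bins.
#' @param n_draws replicated datasets to simulate.
#' @return List with `table`, `contrast` (as in
#'   [rt_posterior_predictive_by_pstop()]) and `past_ip` (per participant x
#'   condition fraction past the participant's DDM IP, with the group IP
#'   HDI).
#' @export
ddm_posterior_predictive <- function(fit, bins = 10, n_draws = 50L) {
  tabs <- list(); ctrs <- list(); past <- list()
  breaks <- seq(0, 1, length.out = bins + 1)
  pos <- stats::setNames(match(c("d0", "d1", "a0", "a1", "z0", "z1", "ter"),
                               fit$par_names),
                         c("d0", "d1", "a0", "a1", "z0", "z1", "ter"))
  for (cl in fit$conditions) {
    f <- fit$fits[[cl]]
    d <- f$data
    jidx <- match(d$participant_id, f$participants)
    psi_mean <- apply(f$psi, c(2, 3), mean)
    args_mean <- t(vapply(seq_along(f$participants),
                          function(j) psi_to_args(psi_mean[j, ], pos),
                          numeric(7)))
    xd <- unlist(lapply(f$dat, `[[`, "xd"))
    xa <- unlist(lapply(f$dat, `[[`, "xa"))
    xz <- unlist(lapply(f$dat, `[[`, "xz"))
    v_m <- args_mean[jidx, "d0"] + args_mean[jidx, "d1"] * xd
    a_m <- softplus(args_mean[jidx, "a0"] + args_mean[jidx, "a1"] * xa)
    w_m <- stats::pnorm(args_mean[jidx, "z0"] + args_mean[jidx, "z1"] * xz)
    p_stop <- wiener_p_stop(v_m, a_m, pmin(pmax(w_m, 1e-9), 1 - 1e-9))
    bin <- cut(p_stop, breaks, include.lowest = TRUE, labels = FALSE)
    ridx <- thin_index(dim(f$psi)[1], n_draws)
    rep_means <- matrix(NA_real_, length(ridx), bins)
    for (r in seq_along(ridx)) {
      A <- t(vapply(seq_along(f$participants),
                    function(j) psi_to_args(f$psi[ridx[r], j, ], pos),
                    numeric(7)))
      v <- A[jidx, "d0"] + A[jidx, "d1"] * xd
      a <- softplus(A[jidx, "a0"] + A[jidx, "a1"] * xa)
      w <- pmin(pmax(stats::pnorm(A[jidx, "z0"] + A[jidx, "z1"] * xz),
                     1e-9), 1 - 1e-9)
      sim <- rwiener_trials(v, a, A[jidx, "ter"], w)
      rep_means[r, ] <- vapply(seq_len(bins), function(b) {
        j <- bin == b
        if (any(j)) mean(sim$rt[j]) else NA_real_
      }, numeric(1))
    }
    obs <- vapply(seq_len(bins), function(b) {
      j <- bin == b
      if (any(j)) mean(d$rt[j]) else NA_real_
    }, numeric(1))
    nb <- vapply(seq_len(bins), function(b) sum(bin == b), numeric(1))
    hd <- apply(rep_means, 2, function(v)
      if (all(is.na(v))) c(NA_real_, NA_real_) else hdi(v))
    tabs[[cl]] <- data.frame(
      condition_label = cl, bin = seq_len(bins),
      p_stop_mid = (breaks[-1] + breaks[-length(breaks)]) / 2, n = nb,
      observed_mean_rt = obs,
      predicted_mean_rt = colMeans(rep_means, na.rm = TRUE),
      predicted_lower = hd[1, ], predicted_upper = hd[2, ],
      stringsAsFactors = FALSE)
    nonempty <- which(nb > 0)
    b_conf <- nonempty[which.min(abs(tabs[[cl]]$p_stop_mid[nonempty] - 0.5))]
    b_stop <- nonempty[which.max(tabs[[cl]]$p_stop_mid[nonempty])]
    diffs <- rep_means[, b_conf] - rep_means[, b_stop]
    hc <- hdi(diffs)
    ctrs[[cl]] <- data.frame(
      condition_label = cl, bin_conflict = b_conf, bin_stop = b_stop,
      predicted_diff = mean(diffs, na.rm = TRUE), diff_lower = hc[1],
      diff_upper = hc[2], observed_diff = obs[b_conf] - obs[b_stop],
      stringsAsFactors = FALSE)
    if (fit$variant$drift_modulator == "cumulative_sum") {
      ipg <- ip_from_drift(f$group[, "mu_d0"], f$group[, "mu_d1"])
      hip <- hdi(ipg)
      past[[cl]] <- do.call(rbind, lapply(seq_along(f$participants),
        function(j) {
          ipj <- -args_mean[j, "d0"] / args_mean[j, "d1"]
          sel <- d$participant_id == f$participants[j]
          data.frame(condition_label = cl,
                     participant_id = f$participants[j], ip = ipj,
                     fraction_past_ip = fraction_past_ip(d$cum_sum[sel], ipj),
                     group_ip_lower = hip[1], group_ip_upper = hip[2],
                     stringsAsFactors = FALSE)
        }))
    }
  }
  list(table = do.call(rbind, tabs), contrast = do.call(rbind, ctrs),
       past_ip = if (length(past)) do.call(rbind, past) else NULL)
}
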