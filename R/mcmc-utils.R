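#' MCMC settings for the hierarchical regressions
#'
#' Defaults follow the regression fitting recipe: 2 chains of 2000 iterations
#' each with the first half discarded as warmup.
#'
#' @param chains number of chains.
#' @param iter iterations per chain (including warmup).
#' @param warmup iterations discarded per chain.
#' @param seed integer seed; chain c uses `seed + c`.
#' @return List of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 2, iter = 2000, warmup = floor(iter / 2),
                          seed = 1L) {
  stopifnot(chains >= 1, iter > warmup, warmup >= 0)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 warmup = as.integer(warmup), seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' Highest-density interval
#'
#' Shortest interval containing `prob` posterior mass, from sorted draws.
#'
#' @param x numeric vector of draws.
#' @param prob mass to cover.
#' @return Numeric `c(lower, upper)`.
#' @export
hdi <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L) return(c(NA_real_, NA_real_))
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

# Split-free Gelman-Rubin R-hat per monitored parameter from a coda
# mcmc.list; single-chain fits fall back to a split of that chain.
rhat_values <- function(samples) {
  if (coda::nchain(samples) == 1L) {
    one <- samples[[1]]
    half <- floor(nrow(one) / 2)
    samples <- coda::mcmc.list(coda::mcmc(one[seq_len(half), , drop = FALSE]),
                               coda::mcmc(one[half + seq_len(half), , drop = FALSE]))
  }
  keep <- apply(as.matrix(samples[[1]]), 2, function(v) stats::var(v) > 0) |
    apply(as.matrix(samples[[length(samples)]]), 2, function(v) stats::var(v) > 0)
  out <- rep(NA_real_, coda::nvar(samples))
  names(out) <- coda::varnames(samples)
  if (any(keep)) {
    gd <- try(coda::gelman.diag(samples[, keep, drop = FALSE],
                                autoburnin = FALSE, multivariate = FALSE),
              silent = TRUE)
    if (!inherits(gd, "try-error")) out[keep] <- gd$psrf[, 1]
  }
  out
}

# Run a JAGS model reproducibly and return list(draws = stacked matrix,
# samples = mcmc.list, rhat = named vector).
run_jags <- function(model_string, data, monitor, mcmc, inits_extra = NULL) {
  # block samplers for the correlated regression coefficients
  suppressMessages(try(rjags::load.module("glm", quiet = TRUE), silent = TRUE))
  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    c(list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = (mcmc$seed + 17L * ch) %% 2147483646L + 1L),
      inits_extra)
  })
  n_adapt <- min(500L, mcmc$warmup)
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = mcmc$chains,
                          n.adapt = n_adapt, quiet = TRUE)
  burn <- mcmc$warmup - n_adapt
  if (burn > 0) stats::update(jm, n.iter = burn, progress.bar = "none")
  samples <- rjags::coda.samples(jm, variable.names = monitor,
                                 n.iter = mcmc$iter - mcmc$warmup,
                                 progress.bar = "none")
  list(draws = do.call(rbind, lapply(samples, as.matrix)),
       samples = samples, rhat = rhat_values(samples))
}

# Column names of indexed JAGS nodes; JAGS drops the bracket index on
# length-1 vectors ("mu" instead of "mu[1]").
jcols <- function(draws, name, idx) {
  cols <- sprintf("%s[%d]", name, idx)
  absent <- !(cols %in% colnames(draws))
  cols[absent & cols == sprintf("%s[1]", name) &
         name %in% colnames(draws)] <- name
  if (any(!(cols %in% colnames(draws)))) {
    stop("monitored parameter columns not found for ", name)
  }
  cols
}

# Thin row indices of a draw matrix down to at most n_keep rows.
thin_index <- function(n_draws, n_keep) {
  if (n_draws <= n_keep) return(seq_len(n_draws))
  unique(round(seq(1, n_draws, length.out = n_keep)))
}
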