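# Shared fixtures and independent oracles, built in code at test time.

# Small random valid dataset with one covariate in each design matrix.
make_ds <- function(n = 8, seed = 1, p_cens = 0.4, L = NULL) {
  set.seed(seed)
  w <- rbinom(n, 1, 0.5)
  x <- rnorm(n)
  times <- rexp(n, rate = 0.5) + 0.05
  if (!is.null(L)) times <- pmin(times, L)
  events <- rbinom(n, 1, 1 - p_cens)
  survival_data(times, events,
                latency = cbind(`(Intercept)` = 1, x = x),
                incidence = cbind(`(Intercept)` = 1, w = w),
                follow_up_limit = L)
}

rand_params <- function(ds, seed = 2, family = "weibull") {
  set.seed(seed)
  cure_params(beta = rnorm(ds$q, 0, 0.7), alpha = rnorm(ds$p, 0, 0.5),
              shape = runif(1, 0.6, 1.6), family = family)
}

# Brute-force marginalization oracle: sum of exp(complete log-likelihood)
# over every admissible latent configuration (u free only where c = 0).
enum_obs_loglik <- function(ds, params) {
  free <- which(ds$events == 0)
  k <- length(free)
  u0 <- rep(1L, ds$n)
  total <- 0
  for (m in seq_len(2^k) - 1L) {
    u <- u0
    if (k > 0) u[free] <- as.integer(intToBits(m))[seq_len(k)]
    total <- total + exp(complete_loglik(ds, params, u))
  }
  log(total)
}

short_control <- function(seed = 1, burnin = 300, iterations = 1200,
                          thin = 2) {
  chain_control(burnin = burnin, iterations = iterations, thin = thin,
                seed = seed)
}
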