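test_that("prior and control specifications are validated", {
  expect_error(cure_prior(s1 = -1), "positive")
  expect_error(chain_control(iterations = 10, thin = 10), "at least 2")
  expect_error(chain_control(burnin = -5), "burnin")
  bad <- cure_prior(B = matrix(c(1, 2, 2, 1), 2))  # not PD
  ds <- make_ds(n = 6, seed = 1)
  expect_error(curemix:::.realize_prior(bad, 2, 2), "positive definite")
})

test_that("latent conditional: events forced susceptible, Bayes ratio right", {
  # intercept-only: pi = logit^-1(0.573) = 0.6394, exponential Ss(1) = e^-1
  ds <- survival_data(c(1, 1), c(1, 0))
  pars <- cure_params(0.573, 0, 1)
  p1 <- curemix:::.latent_prob(ds, pars)
  expect_equal(p1[1], 1)
  pi <- plogis(0.573); ss <- exp(-1)
  expect_equal(p1[2], pi * ss / ((1 - pi) + pi * ss), tolerance = 1e-12)
  expect_equal(p1[2], 0.3948, tolerance = 5e-4)
  # censoring at t -> 0+ carries no information: P(U=1) -> pi
  ds0 <- survival_data(1e-12, 0)
  expect_equal(curemix:::.latent_prob(ds0, pars)[1], pi, tolerance = 1e-9)
  set.seed(1)
  u <- curemix:::.sample_latent(ds, pars)
  expect_equal(u[1], 1L)
})

test_that("block targets are consistent with the complete likelihood", {
  ds <- make_ds(n = 15, seed = 7, p_cens = 0.5)
  pars <- rand_params(ds, 8)
  set.seed(9)
  u <- curemix:::.sample_latent(ds, pars)
  pr <- curemix:::.realize_prior(cure_prior(), ds$q, ds$p)

  # beta target: log-ratio equals complete-loglik difference + prior ratio
  b1 <- pars$beta; b2 <- b1 + rnorm(ds$q, 0, 0.3)
  lt_diff <- curemix:::.lt_beta(b2, ds$Z, u, pr$beta) -
    curemix:::.lt_beta(b1, ds$Z, u, pr$beta)
  ll_diff <- complete_loglik(ds, cure_params(b2, pars$alpha, pars$shape), u) -
    complete_loglik(ds, cure_params(b1, pars$alpha, pars$shape), u)
  prior_diff <- sum(dnorm(b2, 0, 10, log = TRUE)) -
    sum(dnorm(b1, 0, 10, log = TRUE))
  expect_equal(lt_diff, ll_diff + prior_diff, tolerance = 1e-9)

  # alpha target likewise (latency terms only involve u = 1 subjects)
  idx <- u == 1
  a1 <- pars$alpha; a2 <- a1 + rnorm(ds$p, 0, 0.3)
  lt_diff <- curemix:::.lt_alpha(a2, ds$X[idx, , drop = FALSE],
                                 ds$times[idx], ds$events[idx], pars$shape,
                                 "weibull", pr$alpha) -
    curemix:::.lt_alpha(a1, ds$X[idx, , drop = FALSE], ds$times[idx],
                        ds$events[idx], pars$shape, "weibull", pr$alpha)
  ll_diff <- complete_loglik(ds, cure_params(pars$beta, a2, pars$shape), u) -
    complete_loglik(ds, cure_params(pars$beta, a1, pars$shape), u)
  prior_diff <- sum(dnorm(a2, 0, 10, log = TRUE)) -
    sum(dnorm(a1, 0, 10, log = TRUE))
  expect_equal(lt_diff, ll_diff + prior_diff, tolerance = 1e-9)

  # shape target on the log scale: complete-loglik difference + Gamma prior
  # ratio + log-Jacobian
  mu_s <- exp(drop(ds$X[idx, , drop = FALSE] %*% pars$alpha))
  r1 <- pars$shape; r2 <- r1 * 1.3
  lt_diff <- curemix:::.lt_logshape(log(r2), mu_s, ds$times[idx],
                                    ds$events[idx], "weibull", 0.01, 0.01) -
    curemix:::.lt_logshape(log(r1), mu_s, ds$times[idx], ds$events[idx],
                           "weibull", 0.01, 0.01)
  ll_diff <- complete_loglik(ds, cure_params(pars$beta, pars$alpha, r2), u) -
    complete_loglik(ds, cure_params(pars$beta, pars$alpha, r1), u)
  prior_diff <- dgamma(r2, 0.01, rate = 0.01, log = TRUE) -
    dgamma(r1, 0.01, rate = 0.01, log = TRUE)
  expect_equal(lt_diff, ll_diff + prior_diff + (log(r2) - log(r1)),
               tolerance = 1e-9)
})

test_that("acceptance log-ratios are antisymmetric (detailed balance)", {
  ds <- make_ds(n = 10, seed = 11)
  pr <- curemix:::.realize_prior(cure_prior(), ds$q, ds$p)
  set.seed(12)
  u <- rbinom(10, 1, 0.7); u[ds$events == 1] <- 1L
  for (k in 1:5) {
    x <- rnorm(ds$q); y <- rnorm(ds$q)
    fwd <- curemix:::.lt_beta(y, ds$Z, u, pr$beta) -
      curemix:::.lt_beta(x, ds$Z, u, pr$beta)
    bwd <- curemix:::.lt_beta(x, ds$Z, u, pr$beta) -
      curemix:::.lt_beta(y, ds$Z, u, pr$beta)
    expect_equal(fwd + bwd, 0, tolerance = 1e-10)
    expect_equal(exp(fwd) * exp(bwd), 1, tolerance = 1e-10)
  }
})

test_that("empty susceptible set reduces conditionals to the prior", {
  pr <- curemix:::.realize_prior(cure_prior(a = 1, A = 4), 1, 2)
  a <- c(0.3, -0.8)
  quad <- -0.5 * sum((a - 1) * (pr$alpha$prec %*% (a - 1)))
  expect_equal(curemix:::.lt_alpha(a, matrix(0, 0, 2), numeric(0),
                                   numeric(0), 1, "weibull", pr$alpha),
               quad)
})

test_that("alpha conditional mode sits at the exponential rate MLE", {
  # intercept-only alpha, r = 1, everyone susceptible and observed:
  # the conditional is maximized at log(sum c / sum t) under a diffuse prior
  set.seed(13)
  tt <- rexp(40, 0.7)
  ds <- survival_data(tt, rep(1, 40))
  pr <- curemix:::.realize_prior(cure_prior(A = 1e6), 1, 1)
  grid <- seq(-3, 3, length.out = 4001)
  lt <- vapply(grid, function(a)
    curemix:::.lt_alpha(a, ds$X, ds$times, ds$events, 1, "weibull",
                        pr$alpha), 0)
  expect_equal(grid[which.max(lt)], log(sum(ds$events) / sum(ds$times)),
               tolerance = 3e-3)
})

test_that("shape conditional matches a grid-normalized quadrature oracle", {
  # all subjects susceptible and observed, alpha fixed: compare the MH draws
  # of r against the density derived independently from the complete
  # likelihood + Gamma prior on a grid (total variation distance)
  set.seed(14)
  n <- 60
  tt <- (rexp(n) / exp(0.2))^(1 / 1.3)   # Weibull times, mu = e^0.2, r = 1.3
  ds <- survival_data(tt, rep(1, n))
  u <- rep(1L, n)
  s1 <- 2; s2 <- 1
  alpha0 <- 0.2
  mu_s <- rep(exp(alpha0), n)

  # independent density: complete likelihood as a function of r only,
  # normalized on a fine grid
  grid <- seq(0.5, 2.6, length.out = 4000)
  ll <- vapply(grid, function(r)
    complete_loglik(ds, cure_params(beta = 10, alpha = alpha0, shape = r), u) +
      dgamma(r, s1, rate = s2, log = TRUE), 0)
  dens <- exp(ll - max(ll)); dens <- dens / sum(dens)
  cdf <- cumsum(dens)
  # 20 equal-probability bins from the oracle cdf
  edges <- grid[findInterval(seq(0.05, 0.95, by = 0.05), cdf) + 1L]

  # MH sampling of the same conditional via the package's target
  set.seed(15)
  ls <- log(1); draws <- numeric(30000)
  lt <- curemix:::.lt_logshape(ls, mu_s, ds$times, ds$events, "weibull",
                               s1, s2)
  for (i in seq_along(draws)) {
    st <- curemix:::.mh_step(ls, lt, function(l)
      curemix:::.lt_logshape(l, mu_s, ds$times, ds$events, "weibull",
                             s1, s2), matrix(1), 0.3)
    ls <- st$x; lt <- st$lt
    draws[i] <- exp(ls)
  }
  draws <- draws[seq(2001, length(draws), by = 4)]
  counts <- tabulate(findInterval(draws, edges) + 1L, nbins = 20L)
  tv <- 0.5 * sum(abs(counts / sum(counts) - 0.05))
  expect_lt(tv, 0.06)
  # and the posterior mean is in the right place
  expect_equal(mean(draws), sum(grid * dens), tolerance = 0.03)
})

test_that("chains are reproducible and satisfy their invariants", {
  ds <- make_ds(n = 40, seed = 16, p_cens = 0.45, L = 10)
  ctl <- short_control(seed = 3)
  ch1 <- run_cure_chain(ds, control = ctl)
  ch2 <- run_cure_chain(ds, control = ctl)
  expect_identical(ch1$draws, ch2$draws)
  expect_identical(ch1$deviance, ch2$deviance)

  expect_true(all(ch1$draws[, "shape"] > 0))
  expect_true(all(is.finite(ch1$deviance)))
  expect_true(all(ch1$accept_rates >= 0 & ch1$accept_rates <= 1,
                  na.rm = TRUE))
  # latent admissibility: observed events are always susceptible
  expect_true(all(ch1$latent_mean[ds$events == 1] == 1))
  expect_equal(nrow(ch1$draws), 600)
})

test_that("vanishing proposal scale freezes the chain with full acceptance", {
  ds <- make_ds(n = 20, seed = 17)
  init <- cure_params(beta = c(0.2, 0), alpha = c(-0.5, 0), shape = 1)
  ch <- run_cure_chain(ds, init = init,
                       control = chain_control(burnin = 50, iterations = 400,
                                               thin = 1, seed = 4,
                                               adapt = FALSE,
                                               scales = list(beta = 1e-9,
                                                             alpha = 1e-9,
                                                             shape = 1e-9)))
  expect_true(all(ch$accept_rates > 0.999, na.rm = TRUE))
  expect_equal(unname(colMeans(ch$draws)[1:2]), init$beta, tolerance = 1e-5)
})

test_that("exponential family has no shape block", {
  ds <- make_ds(n = 25, seed = 18)
  ch <- run_cure_chain(ds, family = "exponential",
                       control = short_control(seed = 5, burnin = 100,
                                               iterations = 300))
  expect_false("shape" %in% colnames(ch$draws))
  expect_equal(ncol(ch$draws), ds$q + ds$p)
})

test_that("divergent initialization is reported, not silently absorbed", {
  ds <- make_ds(n = 10, seed = 19)
  expect_error(run_cure_chain(ds, init = cure_params(c(0, 0), c(0, 0), -1),
                              control = short_control()),
               "shape")
})
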