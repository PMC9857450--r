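# A minimal hand-built chain object for summary-level tests.
fake_chain <- function(draws, model = "cure", family = "weibull",
                       q = NULL, p = NULL, dev = NULL) {
  draws <- as.matrix(draws)
  has_beta <- any(grepl("^incidence\\.", colnames(draws)))
  has_alpha <- any(grepl("^latency\\.", colnames(draws)))
  has_shape <- "shape" %in% colnames(draws)
  structure(list(draws = draws, deviance = dev,
                 model = model, family = family,
                 has = c(beta = has_beta, alpha = has_alpha,
                         shape = has_shape),
                 dims = c(q = if (is.null(q)) sum(grepl("^incidence\\.",
                                                        colnames(draws)))
                          else q,
                          p = if (is.null(p)) sum(grepl("^latency\\.",
                                                        colnames(draws)))
                          else p)),
            class = "cure_chain")
}

test_that("posterior summaries use equal-tailed empirical quantiles", {
  d <- matrix(rep(2.5, 20), dimnames = list(NULL, "incidence.a"))
  s <- posterior_summary(fake_chain(d))
  expect_equal(s$mean, 2.5)
  expect_equal(s$lower, 2.5)
  expect_equal(s$upper, 2.5)

  d <- matrix((1:1000) / 1000, dimnames = list(NULL, "latency.b"))
  s <- posterior_summary(fake_chain(d), level = 0.9)
  # type-7 interpolated quantiles: 0.05095 / 0.95005 for this grid
  expect_equal(s$lower, quantile((1:1000) / 1000, 0.05, names = FALSE))
  expect_equal(s$lower, 0.05, tolerance = 0.02)
  expect_equal(s$upper, 0.95, tolerance = 0.02)
  expect_equal(s$median, 0.5005)

  expect_error(posterior_summary(fake_chain(d), level = 1.2), "level")
  expect_error(posterior_summary(matrix(numeric(0), 0, 1)), "no retained")
})

test_that("OR/HR tables exponentiate coefficients and preserve ordering", {
  set.seed(21)
  n <- 500
  draws <- cbind("incidence.(Intercept)" = rnorm(n, 0.5, 0.1),
                 "incidence.np" = rnorm(n, 0.532, 0.05),
                 "latency.(Intercept)" = rnorm(n, 0.6, 0.2),
                 "latency.np" = rnorm(n, 1.097, 0.1),
                 "latency.zero" = rep(0, n),
                 shape = rexp(n) + 0.5)
  tab <- odds_hazard_ratios(fake_chain(draws))
  expect_setequal(tab$parameter, c("np", "np", "zero"))
  np_or <- tab[tab$type == "OR" & tab$parameter == "np", ]
  expect_equal(np_or$estimate, exp(mean(draws[, "incidence.np"])))
  expect_equal(np_or$lower, exp(quantile(draws[, "incidence.np"], 0.025,
                                         names = FALSE)))
  expect_true(np_or$lower < np_or$estimate & np_or$estimate < np_or$upper)
  # zero coefficient -> unit ratio
  expect_equal(tab[tab$parameter == "zero", "estimate"], 1)
  # mean-of-exp dominates exp-of-mean (Jensen)
  expect_gte(np_or$mean_of_exp, np_or$estimate)
  # intercepts excluded by default, included on request
  tab2 <- odds_hazard_ratios(fake_chain(draws), include_intercept = TRUE)
  expect_equal(nrow(tab2), nrow(tab) + 2)
})

test_that("DIC identities hold on fitted chains", {
  ds <- make_ds(n = 30, seed = 22, p_cens = 0.4)
  ch <- run_cure_chain(ds, control = short_control(seed = 6))
  d <- dic(ch)
  expect_equal(d$DIC, 2 * d$Dbar - d$Dhat)
  expect_equal(d$pD, d$Dbar - d$Dhat)
  expect_equal(d$Dbar, mean(ch$deviance))
  # an (essentially) constant chain has pD ~ 0 and DIC ~ D(theta)
  init <- curemix:::.default_init(ds, "weibull", "cure")
  chc <- run_cure_chain(ds, init = init,
                        control = chain_control(burnin = 0, iterations = 50,
                                                thin = 1, seed = 7,
                                                adapt = FALSE,
                                                scales = list(beta = 1e-10,
                                                              alpha = 1e-10,
                                                              shape = 1e-10)))
  dc <- dic(chc)
  expect_equal(dc$pD, 0, tolerance = 1e-6)
  expect_equal(dc$DIC, dc$Dhat, tolerance = 1e-6)
})

test_that("two-draw deviance arithmetic", {
  # Dbar = 12, D(theta_bar) = 11 -> pD = 1, DIC = 13
  Dbar <- mean(c(10, 14)); Dhat <- 11
  expect_equal(Dbar - Dhat, 1)
  expect_equal(2 * Dbar - Dhat, 13)
})

test_that("horizon probabilities: limits, monotonicity, pi at infinity", {
  set.seed(23)
  n <- 300
  draws <- cbind("incidence.(Intercept)" = rep(0.573, n),
                 "latency.(Intercept)" = rnorm(n, 0, 0.3),
                 shape = runif(n, 0.7, 1.3))
  ch <- fake_chain(draws)
  x <- matrix(1, 1, 1); z <- matrix(1, 1, 1)
  expect_equal(predict_event_probability(ch, x, z, Inf)$mean,
               plogis(0.573), tolerance = 1e-12)
  expect_equal(predict_event_probability(ch, x, z, Inf)$mean, 0.6394,
               tolerance = 1e-4)
  expect_lt(predict_event_probability(ch, x, z, 1e-9)$mean, 1e-5)
  # monotone in the horizon for every draw
  p3 <- curemix:::.event_prob_draws(ch, x, z, 3)
  p10 <- curemix:::.event_prob_draws(ch, x, z, 10)
  pinf <- curemix:::.event_prob_draws(ch, x, z, Inf)
  expect_true(all(p3 < p10 & p10 < pinf))
  expect_error(predict_event_probability(ch, x, z, -1), "horizon")
})

test_that("group probabilities: two methods, bias under dependence", {
  # independent covariates: the two methods agree within Monte-Carlo error;
  # strongly dependent covariates: method 2's counterfactual averaging is
  # visibly biased relative to method 1
  set.seed(24)
  n <- 1500
  make_fit <- function(rho) {
    a <- rbinom(n, 1, 0.5)
    b <- ifelse(runif(n) < rho, a, rbinom(n, 1, 0.5))
    pi <- plogis(-0.3 + 1.5 * a + 1.5 * b)
    u <- rbinom(n, 1, pi)
    tt <- ifelse(u == 1, pmin(rexp(n, 1.2), 20), 20)
    ev <- as.integer(u == 1 & tt < 20)
    df <- data.frame(time = pmax(tt, 1e-6), event = ev, a = a, b = b)
    curemix(survival::Surv(time, event) ~ 1, cureform = ~ a + b, data = df,
            control = chain_control(burnin = 300, iterations = 1500,
                                    thin = 3, seed = 8))
  }
  fit_ind <- make_fit(0)
  g1 <- group_probability(fit_ind, list(a = 1), horizon = Inf, method = 1)
  g2 <- group_probability(fit_ind, list(a = 1), horizon = Inf, method = 2)
  expect_lt(abs(g1$mean - g2$mean), 0.04)
  expect_equal(g1$n_used, sum(fit_ind$ds$Z[, "a"] == 1))
  expect_equal(g2$n_used, n)

  fit_dep <- make_fit(0.9)
  d1 <- group_probability(fit_dep, list(a = 1), horizon = Inf, method = 1)
  d2 <- group_probability(fit_dep, list(a = 1), horizon = Inf, method = 2)
  expect_gt(abs(d1$mean - d2$mean), abs(g1$mean - g2$mean))

  # a group definition covering every subject: the two methods coincide
  ds_all <- survival_data(c(1, 2, 3, 4), c(1, 0, 1, 0),
                          incidence = cbind(`(Intercept)` = rep(1, 4),
                                            a = rep(1, 4)))
  ch_all <- run_cure_chain(ds_all, control = short_control(seed = 30,
                                                           burnin = 50,
                                                           iterations = 100))
  fit_all <- structure(list(chain = ch_all, ds = ds_all), class = "curemix")
  m1 <- group_probability(fit_all, list(a = 1), horizon = 2, method = 1)
  m2 <- group_probability(fit_all, list(a = 1), horizon = 2, method = 2)
  expect_equal(m1$mean, m2$mean)
  expect_equal(m1$sd_individuals, m2$sd_individuals)

  expect_error(group_probability(fit_ind, list(a = 99), method = 1),
               "non-empty")
  expect_error(group_probability(fit_ind, list(zzz = 1)), "unknown group")
})

test_that("effective size and mcse behave sanely", {
  set.seed(25)
  iid <- rnorm(2000)
  expect_gt(curemix:::.ess(iid), 1000)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.9), 2000))
  expect_lt(curemix:::.ess(ar), 500)
  expect_gt(curemix:::.mcse(ar), curemix:::.mcse(iid))
})
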