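#' Fit a Bayesian mixture cure rate model
#'
#' The population is modeled as a mixture of susceptibles, who eventually
#' experience the event, and non-susceptibles ("cured"), who never do. The
#' marginal survival function is improper:
#' \deqn{S(t \mid x, z) = (1 - \pi(z)) + \pi(z) S_s(t \mid x),
#'   \qquad \pi(z) = \mathrm{logit}^{-1}(z'\beta),}
#' with a parametric latency distribution \eqn{S_s} (Weibull by default)
#' whose rate is \eqn{\mu = \exp(x'\alpha)} and shape \eqn{r}. Posterior
#' sampling uses the latent-indicator Metropolis-within-Gibbs sampler of
#' [run_cure_chain()].
#'
#' @param formula latency (survival) sub-model:
#'   `survival::Surv(time, event) ~ covariates`. Use `~ 1` for an
#'   intercept-only latency model.
#' @param cureform one-sided formula for the incidence (susceptibility)
#'   sub-model, e.g. `~ np + age`; default intercept-only.
#' @param data data.frame holding the variables.
#' @param family latency family tag (see [latency_families]).
#' @param prior a [cure_prior].
#' @param control a [chain_control]. The defaults mirror the reference
#'   analysis (500,000 iterations); pass a smaller configuration for
#'   interactive use.
#' @param init optional [cure_params] starting values.
#' @param follow_up_limit optional administrative horizon L recorded on the
#'   dataset.
#' @return An object of class `curemix` with components `chain` (the
#'   `cure_chain`), `ds` (the [survival_data]), `formula`, `cureform`,
#'   `family`, `call`, and the terms needed for [predict.curemix()].
#' @seealso [summary.curemix()], [predict.curemix()], [odds_hazard_ratios()],
#'   [dic()], [cure_compare()], [km_fit()]
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(
#'   n = 150, beta = c(0.4, 0.8), alpha = c(0.1, 0.4), shape = 1,
#'   covariates = list(w = list(type = "binary", p = 0.5)),
#'   follow_up = 15, seed = 7))
#' df <- data.frame(time = coh$dataset$times, event = coh$dataset$events,
#'                  w = coh$covariates$w)
#' fit <- curemix(survival::Surv(time, event) ~ w, cureform = ~ w, data = df,
#'                control = chain_control(burnin = 200, iterations = 1000,
#'                                        thin = 2, seed = 1))
#' summary(fit)
curemix <- function(formula, cureform = ~1, data, family = "weibull",
                    prior = cure_prior(), control = chain_control(),
                    init = NULL, follow_up_limit = NULL) {
  cl <- match.call()
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  if (!inherits(y, "Surv"))
    stop("the left-hand side of formula must be a survival::Surv(time, ",
         "event) object")
  times <- as.numeric(y[, 1L])
  events <- as.numeric(y[, 2L])
  lat_terms <- delete.response(terms(formula, data = data))
  X <- model.matrix(lat_terms, data)
  cure_terms <- terms(cureform, data = data)
  Z <- model.matrix(cure_terms, data)

  ds <- survival_data(times, events, latency = X, incidence = Z,
                      follow_up_limit = follow_up_limit)
  chain <- run_cure_chain(ds, family = family, prior = prior, init = init,
                          control = control, model = "cure")
  structure(list(call = cl, formula = formula, cureform = cureform,
                 family = family, ds = ds, chain = chain,
                 lat_terms = lat_terms, cure_terms = cure_terms,
                 prior = prior, control = control),
            class = "curemix")
}

#' @export
print.curemix <- function(x, ...) {
  cat("Bayesian mixture cure rate model (", x$family, " latency)\n",
      sep = "")
  cat("Call: "); print(x$call)
  cat("\nPosterior means:\n")
  print(round(coef(x), 4))
  if (!is.null(x$chain$dic))
    cat("\nDIC:", format(x$chain$dic$DIC, digits = 7), "\n")
  invisible(x)
}

#' @export
coef.curemix <- function(object, ...) {
  colMeans(object$chain$draws)
}

#' @rdname summary.curemix
#' @export
summary.curemix <- function(object, level = 0.95, ...) {
  out <- list(call = object$call, family = object$family,
              table = posterior_summary(object$chain, level),
              ratios = odds_hazard_ratios(object$chain, level),
              dic = object$chain$dic, accept = object$chain$accept_rates,
              level = level, n = object$ds$n,
              n_events = sum(object$ds$events),
              cure_mean = 1 - mean(plogis(
                object$chain$draws[, seq_len(object$ds$q), drop = FALSE] %*%
                  t(object$ds$Z))))
  class(out) <- "summary.curemix"
  out
}

#' Summarize a fitted mixture cure rate model
#'
#' Prints the posterior coefficient table (means, equal-tailed credible
#' intervals), the odds-ratio / hazard-ratio table, the posterior mean cure
#' fraction averaged over the sample, and DIC.
#'
#' @param object a [curemix] fit.
#' @param x a `summary.curemix` object.
#' @param level credible level.
#' @param digits digits for printing.
#' @param ... unused.
#' @export
print.summary.curemix <- function(x, digits = 4, ...) {
  cat("Bayesian mixture cure rate model (", x$family, " latency)\n",
      sep = "")
  cat("n =", x$n, "subjects,", x$n_events, "events;",
      "posterior mean cure fraction", round(x$cure_mean, 3), "\n\n")
  print(cbind(x$table[1L],
              round(x$table[, c("mean", "sd", "lower", "upper")], digits),
              ess = round(x$table$ess)), row.names = FALSE)
  if (nrow(x$ratios)) {
    cat("\nLong-term (OR) and short-term (HR) effects, exp(posterior mean) ",
        "[", 100 * x$level, "% CI]:\n", sep = "")
    r <- x$ratios
    cat(sprintf("  %-12s %s = %.2f (%.2f, %.2f)\n", r$parameter, r$type,
                r$estimate, r$lower, r$upper), sep = "")
  }
  if (!is.null(x$dic))
    cat("\nDIC =", format(x$dic$DIC, digits = 7),
        " (Dbar =", format(x$dic$Dbar, digits = 7),
        ", pD =", format(x$dic$pD, digits = 4), ")\n")
  invisible(x)
}

# Design matrices for new data through the stored terms.
.newdata_designs <- function(object, newdata) {
  if (is.null(newdata)) return(list(X = object$ds$X, Z = object$ds$Z))
  list(X = model.matrix(object$lat_terms, newdata),
       Z = model.matrix(object$cure_terms, newdata))
}

#' Predict event probabilities from a fitted cure model
#'
#' Posterior summaries of \eqn{P(T \le h \mid x, z) = \pi(z) F_s(h \mid x)}
#' per subject and horizon. `type = "incidence"` returns the susceptibility
#' probability \eqn{\pi(z)} (the `horizon = Inf` limit); `type = "survival"`
#' returns the population survival \eqn{1 - \pi F_s}.
#'
#' @param object a [curemix] fit.
#' @param newdata optional data.frame; default: the training data designs.
#' @param horizon numeric vector of positive horizons (may include `Inf`).
#' @param type `"risk"`, `"survival"`, or `"incidence"`.
#' @param level credible level.
#' @param ... unused.
#' @return data.frame with columns `horizon`, `row`, `mean`, `median`,
#'   `lower`, `upper`.
#' @export
predict.curemix <- function(object, newdata = NULL, horizon = Inf,
                            type = c("risk", "survival", "incidence"),
                            level = 0.95, ...) {
  type <- match.arg(type)
  dm <- .newdata_designs(object, newdata)
  if (type == "incidence") horizon <- Inf
  out <- NULL
  for (h in horizon) {
    res <- predict_event_probability(object$chain, dm$X, dm$Z, h, level)
    if (type == "survival") {
      res <- data.frame(mean = 1 - res$mean, median = 1 - res$median,
                        lower = 1 - res$upper, upper = 1 - res$lower)
    }
    out <- rbind(out, cbind(horizon = h, row = seq_len(nrow(res)), res))
  }
  rownames(out) <- NULL
  out
}

#' Trace and density plots for a fitted cure model
#'
#' @param x a [curemix] fit.
#' @param parameters optional character vector of draw column names.
#' @param ... unused.
#' @export
plot.curemix <- function(x, parameters = NULL, ...) {
  draws <- x$chain$draws
  if (is.null(parameters)) parameters <- colnames(draws)
  parameters <- intersect(parameters, colnames(draws))
  old <- par(mfrow = c(length(parameters), 2),
             mar = c(2.5, 2.5, 1.5, 0.5), mgp = c(1.5, 0.4, 0))
  on.exit(par(old))
  for (pnm in parameters) {
    v <- draws[, pnm]
    plot(v, type = "l", xlab = "retained draw", ylab = pnm, main = pnm,
         cex.main = 0.9)
    plot(density(v), main = "", xlab = pnm)
    abline(v = mean(v), lty = 2)
  }
  invisible(x)
}

#' Simulate cohorts from the posterior of a fitted cure model
#'
#' Posterior-predictive replication: for each of `nsim` replicates a
#' parameter draw is taken from the retained posterior sample and a cohort
#' with the fit's own design matrices is generated from the mixture model
#' under those parameters (administrative censoring at the recorded
#' follow-up limit, or at the maximum observed time when none was set).
#'
#' @param object a [curemix] fit.
#' @param nsim number of replicate cohorts.
#' @param seed optional seed.
#' @param ... unused.
#' @return list of `nsim` [survival_data] objects.
#' @export
simulate.curemix <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  chain <- object$chain
  X <- object$ds$X; Z <- object$ds$Z
  L <- if (!is.null(object$ds$follow_up_limit)) object$ds$follow_up_limit
       else max(object$ds$times)
  n <- nrow(X)
  out <- vector("list", nsim)
  rows <- sample.int(nrow(chain$draws), nsim, replace = TRUE)
  for (s in seq_len(nsim)) {
    pars <- .chain_params(chain, chain$draws[rows[s], ])
    pi_i <- plogis(drop(Z %*% pars$beta))
    u <- rbinom(n, 1L, pi_i)
    tt <- rep(Inf, n)
    if (any(u == 1L))
      tt[u == 1L] <- .lat_rtime(sum(u), exp(drop(X[u == 1L, , drop = FALSE]
                                                 %*% pars$alpha)),
                                pars$family, pars$shape)
    ev <- as.integer(u == 1L & tt <= L)
    obs <- pmax(pmin(tt, L), .Machine$double.xmin)
    out[[s]] <- survival_data(obs, ev, latency = X, incidence = Z,
                              follow_up_limit = L)
  }
  out
}

#' Residual diagnostics for a fitted cure model
#'
#' Cox-Snell style residuals at the posterior mean parameters:
#' \eqn{e_i = -\log S(t_i \mid x_i, z_i)} under the fitted population
#' (mixture) survival function. Under a well-specified model the residuals
#' of the uncensored subjects behave like a censored standard exponential
#' sample.
#'
#' @param object a [curemix] fit.
#' @param ... unused.
#' @return numeric vector of residuals.
#' @export
residuals.curemix <- function(object, ...) {
  pars <- .chain_params(object$chain, colMeans(object$chain$draws))
  ds <- object$ds
  pi_i <- plogis(drop(ds$Z %*% pars$beta))
  mu <- exp(drop(ds$X %*% pars$alpha))
  S <- (1 - pi_i) + pi_i *
    exp(.lat_logsurv(ds$times, mu, pars$family, pars$shape))
  -log(S)
}
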