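# Elementwise log(exp(a) + exp(b)) that tolerates -Inf in either argument;
# used for the censored mixture term log[(1 - pi) + pi * S_s].
.lse2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Parameter point of a mixture cure rate model
#'
#' Bundles one point \eqn{(\beta, \alpha, r)} of the parameter space:
#' incidence coefficients (including intercept), latency coefficients
#' (including intercept), the positive latency shape, and the latency family
#' tag.
#'
#' @param beta numeric vector of incidence coefficients (length q).
#' @param alpha numeric vector of latency coefficients (length p).
#' @param shape positive latency shape (Weibull r = 1/sigma); ignored for the
#'   exponential family.
#' @param family latency family tag (see [latency_families]).
#' @return object of class `cure_params`.
#' @export
#' @examples
#' cure_params(beta = 0.573, alpha = 0.665, shape = 0.87)
cure_params <- function(beta, alpha, shape = 1, family = "weibull") {
  family <- match.arg(family, .FAMILIES)
  if (family != "exponential") .check_family(family, shape)
  structure(list(beta = as.numeric(beta), alpha = as.numeric(alpha),
                 shape = if (family == "exponential") 1 else as.numeric(shape),
                 family = family),
            class = "cure_params")
}

#' @export
print.cure_params <- function(x, ...) {
  cat("Mixture cure rate parameters (", x$family, " latency)\n", sep = "")
  cat("  beta  (incidence):", format(x$beta, digits = 4), "\n")
  cat("  alpha (latency):  ", format(x$alpha, digits = 4), "\n")
  if (x$family != "exponential") cat("  shape:", format(x$shape, digits = 4), "\n")
  invisible(x)
}

.check_params_dims <- function(ds, params) {
  if (length(params$beta) != ds$q)
    stop("beta has length ", length(params$beta), " but the dataset has q = ",
         ds$q, " incidence covariates")
  if (length(params$alpha) != ds$p)
    stop("alpha has length ", length(params$alpha), " but the dataset has ",
         "p = ", ds$p, " latency covariates")
}

#' Incidence probability of being susceptible
#'
#' Computes \eqn{\pi(z) = \mathrm{logit}^{-1}(z'\beta)}, overflow-safely: the
#' result is strictly inside (0, 1) for finite linear predictors and never
#' underflows to exactly 0 or 1.
#'
#' @param z numeric vector (length q) or matrix (n x q) of incidence
#'   covariates (including intercept column).
#' @param beta coefficient vector of length q.
#' @return probability/ies of susceptibility in (0, 1).
#' @export
#' @examples
#' incidence_prob(1, 0.573)  # intercept-only
incidence_prob <- function(z, beta) {
  eta <- if (is.matrix(z)) {
    if (ncol(z) != length(beta))
      stop("dimension mismatch: z has ", ncol(z), " columns but beta has ",
           length(beta), " elements")
    drop(z %*% beta)
  } else {
    if (length(z) != length(beta))
      stop("dimension mismatch: z has length ", length(z), " but beta has ",
           "length ", length(beta))
    sum(z * beta)
  }
  plogis(eta)
}

#' Population (marginal) survival function of the mixture
#'
#' \eqn{S(t|x,z) = (1 - \pi(z)) + \pi(z) S_s(t|x)}: an improper survival
#' function that plateaus at the cure probability \eqn{1 - \pi(z)} as
#' \eqn{t \to \infty}. With \eqn{\pi = 1} it reduces to the standard (proper)
#' parametric survival model.
#'
#' @param t positive time(s).
#' @param x latency covariate vector (length p).
#' @param z incidence covariate vector (length q).
#' @param params a [cure_params] object.
#' @return survival probability/ies in (0, 1].
#' @export
population_survival <- function(t, x, z, params) {
  pi <- incidence_prob(z, params$beta)
  mu <- link_mu(x, params$alpha)
  (1 - pi) + pi * latency_survival(t, mu, params$family, params$shape)
}

# Per-subject log-likelihood terms, shared by the observed likelihood and the
# deviance. Returns list(logpi, log1mpi, logf, logS).
.loglik_parts <- function(ds, params) {
  eta <- drop(ds$Z %*% params$beta)
  mu <- exp(drop(ds$X %*% params$alpha))
  list(logpi = plogis(eta, log.p = TRUE),
       log1mpi = plogis(-eta, log.p = TRUE),
       logf = .lat_logdens(ds$times, mu, params$family, params$shape),
       logS = .lat_logsurv(ds$times, mu, params$family, params$shape))
}

#' Observed-data log-likelihood of the mixture cure rate model
#'
#' Each uncensored subject contributes \eqn{\log[\pi(z_i) f_s(t_i|x_i)]};
#' each censored subject contributes
#' \eqn{\log[(1-\pi(z_i)) + \pi(z_i) S_s(t_i|x_i)]}, accumulated with
#' log-sum-exp so the censored mixture term does not cancel catastrophically
#' when \eqn{\pi \approx 1} and \eqn{S_s \approx 0}. Infinite \eqn{z'\beta}
#' (i.e. \eqn{\pi} pinned to exactly 1) is supported and recovers the
#' standard no-cure parametric likelihood exactly.
#'
#' @param ds a [survival_data] object.
#' @param params a [cure_params] object.
#' @return scalar log-likelihood.
#' @export
obs_loglik <- function(ds, params) {
  .check_params_dims(ds, params)
  pt <- .loglik_parts(ds, params)
  c_i <- ds$events
  terms <- ifelse(c_i == 1,
                  pt$logpi + pt$logf,
                  .lse2(pt$log1mpi, pt$logpi + pt$logS))
  if (any(is.nan(terms)) || any(terms == Inf)) {
    bad <- which(is.nan(terms) | terms == Inf)[1L]
    stop("non-finite log-likelihood contribution for subject ", bad)
  }
  sum(terms)
}

#' Complete-data log-likelihood given latent susceptibility indicators
#'
#' The latent indicator \eqn{U_i} is 1 for susceptible subjects and 0 for
#' non-susceptible ones; observed events force \eqn{U_i = 1}. The
#' complete-data log-likelihood is
#' \deqn{\sum_i u_i \log\pi_i + (1-u_i)(1-c_i)\log(1-\pi_i)
#'   + u_i c_i \log f_s(t_i) + u_i (1-c_i) \log S_s(t_i).}
#' Marginalizing \eqn{U} over its admissible configurations recovers
#' [obs_loglik()] exactly.
#'
#' @param ds a [survival_data] object.
#' @param params a [cure_params] object.
#' @param u binary vector of latent indicators with `u[i] == 1` wherever
#'   `ds$events[i] == 1`.
#' @return scalar log-likelihood.
#' @export
complete_loglik <- function(ds, params, u) {
  .check_params_dims(ds, params)
  u <- as.numeric(u)
  if (length(u) != ds$n) stop("u must have length n = ", ds$n)
  if (any(!(u %in% c(0, 1)))) stop("u must be binary")
  bad <- which(ds$events == 1 & u == 0)
  if (length(bad))
    stop("latent indicator u = 0 for subject ", bad[1L],
         " with an observed event (c = 1 forces u = 1)")
  pt <- .loglik_parts(ds, params)
  c_i <- ds$events
  # 0 * -Inf guards: only include terms whose weight is positive
  w <- function(wt, val) sum(val[wt > 0] * wt[wt > 0])
  w(u, pt$logpi) + w((1 - u) * (1 - c_i), pt$log1mpi) +
    w(u * c_i, pt$logf) + w(u * (1 - c_i), pt$logS)
}

#' Log-likelihood of the standard (no-cure) parametric survival model
#'
#' The special case \eqn{\pi(z) \equiv 1} of the mixture:
#' \eqn{\sum_i c_i \log f_s(t_i) + (1-c_i)\log S_s(t_i)}.
#'
#' @inheritParams obs_loglik
#' @param alpha latency coefficient vector.
#' @param shape positive latency shape.
#' @param family latency family tag.
#' @return scalar log-likelihood.
#' @export
standard_loglik <- function(ds, alpha, shape = 1, family = "weibull") {
  if (length(alpha) != ds$p)
    stop("alpha has length ", length(alpha), " but the dataset has p = ",
         ds$p, " latency covariates")
  mu <- exp(drop(ds$X %*% alpha))
  sum(ifelse(ds$events == 1,
             .lat_logdens(ds$times, mu, family, shape),
             .lat_logsurv(ds$times, mu, family, shape)))
}
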