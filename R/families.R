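#' Parametric latency families for the susceptible sub-population
#'
#' Survival, density and hazard functions of the time-to-event distribution
#' for susceptible subjects, under the covariate link
#' \eqn{\mu_i = \exp(x_i'\alpha)}. Families and their parameterizations:
#'
#' * `weibull`: \eqn{S(t) = \exp(-\mu t^r)}, shape \eqn{r = 1/\sigma > 0}.
#'   Reduces to the exponential when \eqn{r = 1}. The hazard
#'   \eqn{h(t) = \mu r t^{r-1}} is decreasing iff \eqn{r < 1}, constant iff
#'   \eqn{r = 1}, increasing iff \eqn{r > 1}.
#' * `exponential`: \eqn{S(t) = \exp(-\mu t)}; no shape parameter.
#' * `lognormal`: \eqn{S(t) = 1 - \Phi((\log t - \log\mu)/\sigma)};
#'   \eqn{\log\mu = x'\alpha} is the log-time location.
#' * `loglogistic`: \eqn{S(t) = [1 + \exp((\log t - \log\mu)/\sigma)]^{-1}}.
#' * `gompertz`: \eqn{S(t) = \exp(-(\mu/\sigma)(e^{\sigma t} - 1))} with rate
#'   \eqn{\mu} and positive shape \eqn{\sigma} — hazard
#'   \eqn{h(t) = \mu e^{\sigma t}}. This parameterization is our
#'   interpretation of the (ambiguously printed) textbook form; the Gompertz
#'   family is provided with the common interface but is not exercised by the
#'   simulation-based validation suite.
#'
#' All computations are carried out in log space where overflow threatens
#' (large \eqn{t^r}).
#'
#' @param t positive time(s).
#' @param mu positive rate/location parameter(s), typically [link_mu()].
#' @param family family tag: one of `"weibull"`, `"exponential"`,
#'   `"lognormal"`, `"loglogistic"`, `"gompertz"`.
#' @param shape positive shape/scale parameter (r for Weibull, \eqn{\sigma}
#'   for lognormal/loglogistic/Gompertz); ignored for the exponential.
#' @return numeric vector: survival in (0, 1], density > 0, or hazard > 0.
#' @name latency_families
NULL

.FAMILIES <- c("weibull", "exponential", "lognormal", "loglogistic",
               "gompertz")

.check_family <- function(family, shape) {
  family <- match.arg(family, .FAMILIES)
  if (family != "exponential") {
    if (is.null(shape) || !is.numeric(shape) || length(shape) != 1L ||
        !is.finite(shape) || shape <= 0)
      stop("family '", family, "' requires a strictly positive shape ",
           "parameter")
  }
  family
}

.check_tmu <- function(t, mu) {
  if (any(!is.finite(t)) || any(t <= 0)) stop("t must be strictly positive")
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be strictly positive")
}

#' Covariate link for the latency rate
#'
#' Computes \eqn{\mu = \exp(x'\alpha)} for a single covariate vector or
#' row-wise for a design matrix.
#'
#' @param x numeric vector (length p) or matrix (n x p) of latency covariates.
#' @param alpha numeric coefficient vector of length p.
#' @return positive scalar or vector of rates.
#' @export
#' @examples
#' link_mu(c(1, 0.5), c(0.2, -0.3))
link_mu <- function(x, alpha) {
  if (is.matrix(x)) {
    if (ncol(x) != length(alpha))
      stop("dimension mismatch: x has ", ncol(x), " columns but alpha has ",
           length(alpha), " elements")
    return(exp(drop(x %*% alpha)))
  }
  if (length(x) != length(alpha))
    stop("dimension mismatch: x has length ", length(x), " but alpha has ",
         "length ", length(alpha))
  exp(sum(x * alpha))
}

# log S_s(t | mu, shape) for each family; vectorized over t and mu.
.lat_logsurv <- function(t, mu, family, shape) {
  switch(family,
    weibull = -mu * exp(shape * log(t)),
    exponential = -mu * t,
    lognormal = pnorm((log(t) - log(mu)) / shape, lower.tail = FALSE,
                      log.p = TRUE),
    loglogistic = plogis((log(t) - log(mu)) / shape, lower.tail = FALSE,
                         log.p = TRUE),
    gompertz = -(mu / shape) * expm1(shape * t)
  )
}

# log f_s(t | mu, shape) for each family.
.lat_logdens <- function(t, mu, family, shape) {
  switch(family,
    weibull = log(mu) + log(shape) + (shape - 1) * log(t) -
      mu * exp(shape * log(t)),
    exponential = log(mu) - mu * t,
    lognormal = dlnorm(t, meanlog = log(mu), sdlog = shape, log = TRUE),
    loglogistic = dlogis((log(t) - log(mu)) / shape, log = TRUE) -
      log(shape) - log(t),
    gompertz = log(mu) + shape * t - (mu / shape) * expm1(shape * t)
  )
}

#' @rdname latency_families
#' @export
latency_survival <- function(t, mu, family = "weibull", shape = 1) {
  family <- .check_family(family, shape)
  .check_tmu(t, mu)
  exp(.lat_logsurv(t, mu, family, shape))
}

#' @rdname latency_families
#' @export
latency_density <- function(t, mu, family = "weibull", shape = 1) {
  family <- .check_family(family, shape)
  .check_tmu(t, mu)
  exp(.lat_logdens(t, mu, family, shape))
}

#' @rdname latency_families
#' @export
latency_hazard <- function(t, mu, family = "weibull", shape = 1) {
  family <- .check_family(family, shape)
  .check_tmu(t, mu)
  exp(.lat_logdens(t, mu, family, shape) - .lat_logsurv(t, mu, family, shape))
}

# Draw event times: inverse-cdf sampling, closed form for every family.
.lat_rtime <- function(n, mu, family, shape) {
  e <- rexp(n)
  switch(family,
    weibull = exp(log(e / mu) / shape),
    exponential = e / mu,
    lognormal = exp(log(mu) + shape * rnorm(n)),
    loglogistic = exp(log(mu) + shape * qlogis(runif(n))),
    gompertz = log1p(shape * e / mu) / shape
  )
}
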