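#' Prior specification for the mixture cure rate model
#'
#' Independent priors \eqn{\beta \sim N_q(b, B)}, \eqn{\alpha \sim N_p(a, A)}
#' and \eqn{\sigma = 1/r \sim \mathrm{IG}(s_1, s_2)} on the Weibull scale —
#' equivalently a Gamma(shape \eqn{s_1}, rate \eqn{s_2}) prior placed
#' directly on the shape \eqn{r}. Defaults are diffuse (mean 0, variance 100
#' normals; \eqn{s_1 = s_2 = 0.01}) for use when no prior information is
#' available.
#'
#' @param b,a prior means: scalars (recycled) or vectors of length q / p.
#' @param B,A prior covariances: scalar (times identity), vector (diagonal),
#'   or full symmetric positive-definite matrix.
#' @param s1,s2 positive shape and rate of the Gamma prior on the latency
#'   shape parameter r.
#' @return object of class `cure_prior`.
#' @export
cure_prior <- function(b = 0, B = 100, a = 0, A = 100, s1 = 0.01, s2 = 0.01) {
  if (!is.numeric(s1) || s1 <= 0 || !is.numeric(s2) || s2 <= 0)
    stop("s1 and s2 must be strictly positive")
  structure(list(b = b, B = B, a = a, A = A, s1 = s1, s2 = s2),
            class = "cure_prior")
}

# Expand a (mean, cov) prior spec to dimension d; returns mean, cov, chol
# factor L (cov = L L') and precision.
.realize_normal <- function(m, V, d, label) {
  m <- rep_len(as.numeric(m), d)
  if (is.matrix(V)) {
    if (nrow(V) != d || ncol(V) != d)
      stop("prior covariance ", label, " must be ", d, "x", d)
  } else if (length(V) == 1L) {
    V <- diag(as.numeric(V), d)
  } else if (length(V) == d) {
    V <- diag(as.numeric(V), d)
  } else stop("prior covariance ", label, " has incompatible length")
  R <- tryCatch(chol(V), error = function(e)
    stop("prior covariance ", label, " is not positive definite"))
  list(mean = m, cov = V, L = t(R), prec = chol2inv(R))
}

.realize_prior <- function(prior, q, p) {
  list(beta = .realize_normal(prior$b, prior$B, q, "B"),
       alpha = .realize_normal(prior$a, prior$A, p, "A"),
       s1 = prior$s1, s2 = prior$s2)
}

#' MCMC chain configuration
#'
#' Defaults mirror the reference analysis settings (burn-in 10,000; 500,000
#' iterations thinned by 100, retaining 5,000 draws); validation studies and
#' examples use much shorter chains. Proposal scales adapt during burn-in
#' only (Robbins-Monro on the log scale, targeting about 20-40% acceptance,
#' combined with the empirical covariance of burn-in draws) and are frozen
#' afterwards so the post-burn-in kernel preserves the posterior.
#'
#' @param burnin non-negative number of burn-in iterations (discarded).
#' @param iterations positive number of post-burn-in iterations.
#' @param thin keep every `thin`-th draw; `floor(iterations/thin)` must be
#'   at least 2.
#' @param seed optional integer seed for full reproducibility.
#' @param adapt adapt proposal scales/covariances during burn-in.
#' @param scales optional named list (`beta`, `alpha`, `shape`) of fixed
#'   proposal standard-deviation multipliers, used as starting values (or as
#'   final values when `adapt = FALSE`).
#' @param target_accept acceptance rate targeted by burn-in adaptation.
#' @return object of class `chain_control`.
#' @export
chain_control <- function(burnin = 10000, iterations = 500000, thin = 100,
                          seed = NULL, adapt = TRUE, scales = NULL,
                          target_accept = 0.3) {
  if (burnin < 0 || iterations < 1 || thin < 1)
    stop("burnin must be >= 0; iterations and thin must be >= 1")
  if (floor(iterations / thin) < 2)
    stop("floor(iterations/thin) must be at least 2 retained draws")
  structure(list(burnin = as.integer(burnin),
                 iterations = as.integer(iterations), thin = as.integer(thin),
                 seed = seed, adapt = isTRUE(adapt), scales = scales,
                 target_accept = target_accept),
            class = "chain_control")
}

## ---- conditional log-targets (internal; unit-tested directly) ----

# Incidence-block conditional: sum over susceptibles of log pi plus sum over
# imputed non-susceptibles of log(1 - pi), plus the N(b, B) log prior
# (additive constants dropped). Admissibility (u = 1 wherever c = 1) makes
# the (1-u)(1-c) weight equal to the indicator u == 0.
.lt_beta <- function(beta, Z, u, prior_n, like = TRUE) {
  d <- beta - prior_n$mean
  lp <- -0.5 * sum(d * (prior_n$prec %*% d))
  if (like) {
    eta <- drop(Z %*% beta)
    lp <- lp + sum(plogis(eta[u == 1], log.p = TRUE)) +
      sum(plogis(-eta[u == 0], log.p = TRUE))
  }
  lp
}

# Latency-coefficient conditional, restricted to subjects with u = 1.
.lt_alpha <- function(alpha, Xs, ts, cs, shape, family, prior_n, like = TRUE) {
  d <- alpha - prior_n$mean
  lp <- -0.5 * sum(d * (prior_n$prec %*% d))
  if (like && length(ts)) {
    mu <- exp(drop(Xs %*% alpha))
    lp <- lp + sum(.lat_logdens(ts[cs == 1], mu[cs == 1], family, shape)) +
      sum(.lat_logsurv(ts[cs == 0], mu[cs == 0], family, shape))
  }
  if (is.nan(lp)) -Inf else lp
}

# Shape conditional on the log scale: Gamma(s1, rate s2) prior on r plus the
# log-Jacobian of r = exp(log r), i.e. s1 * log r - s2 * r up to a constant.
.lt_logshape <- function(ls, mu_s, ts, cs, family, s1, s2, like = TRUE) {
  shape <- exp(ls)
  lp <- s1 * ls - s2 * shape
  if (like && length(ts)) {
    lp <- lp + sum(.lat_logdens(ts[cs == 1], mu_s[cs == 1], family, shape)) +
      sum(.lat_logsurv(ts[cs == 0], mu_s[cs == 0], family, shape))
  }
  if (is.nan(lp)) -Inf else lp
}

# Latent-indicator conditional: P(U=1 | c=0) = pi * Ss / [(1-pi) + pi * Ss],
# computed in log space; observed events are susceptible with probability 1.
.latent_prob <- function(ds, params) {
  eta <- drop(ds$Z %*% params$beta)
  mu <- exp(drop(ds$X %*% params$alpha))
  lognum <- plogis(eta, log.p = TRUE) +
    .lat_logsurv(ds$times, mu, params$family, params$shape)
  logden <- .lse2(plogis(-eta, log.p = TRUE), lognum)
  p1 <- exp(lognum - logden)
  p1[ds$events == 1] <- 1
  p1
}

.sample_latent <- function(ds, params) {
  p1 <- .latent_prob(ds, params)
  u <- rbinom(ds$n, 1L, p1)
  u[ds$events == 1] <- 1L
  u
}

## ---- adaptive random-walk machinery ----

.adapt_new <- function(d, scale) {
  list(d = d, lscale = log(scale), L = diag(1, d),
       mean = numeric(d), M2 = matrix(0, d, d), count = 0L, n_acc = 0L,
       n_try = 0L)
}

.adapt_update <- function(ad, x, acc, target) {
  ad$count <- ad$count + 1L
  delta <- x - ad$mean
  ad$mean <- ad$mean + delta / ad$count
  ad$M2 <- ad$M2 + tcrossprod(delta, x - ad$mean)
  gain <- (ad$count + 10)^-0.6
  ad$lscale <- ad$lscale + gain * ((if (acc) 1 else 0) - target)
  if (ad$count > 10 * ad$d && ad$count %% 25 == 0L) {
    cv <- ad$M2 / (ad$count - 1L)
    cv <- cv + diag(1e-6 * (mean(diag(cv)) + 1e-12), ad$d)
    R <- tryCatch(chol(cv), error = function(e) NULL)
    if (!is.null(R)) ad$L <- t(R)
  }
  ad
}

# One symmetric Gaussian random-walk Metropolis step.
.mh_step <- function(x, lt_x, ltfun, L, scale) {
  prop <- x + scale * drop(L %*% rnorm(length(x)))
  lt_p <- ltfun(prop)
  if (is.nan(lt_p)) lt_p <- -Inf
  if (lt_p - lt_x > log(runif(1L))) list(x = prop, lt = lt_p, acc = TRUE)
  else list(x = x, lt = lt_x, acc = FALSE)
}

## ---- default initialization ----

# Deterministic, cheap starting values inside the support: beta from a
# logistic regression of the event indicator on Z; (alpha, shape) from a
# censored parametric regression fit (survreg), falling back to the
# exponential-rate moment estimate log(sum(c)/sum(t)) with shape 1.
.default_init <- function(ds, family, model) {
  q <- ds$q; p <- ds$p
  beta <- numeric(q)
  if (model %in% c("cure", "logistic")) {
    beta <- tryCatch({
      fit <- suppressWarnings(glm.fit(ds$Z, ds$events,
                                      family = binomial()))
      b <- coef(fit); b[!is.finite(b)] <- 0
      pmin(pmax(b, -5), 5)
    }, error = function(e) numeric(q))
  }
  alpha <- numeric(p)
  shape <- 1
  rate0 <- if (sum(ds$events) > 0) sum(ds$events) / sum(ds$times)
           else 1 / mean(ds$times)
  alpha[1L] <- log(rate0)
  if (model != "logistic") {
    sr_dist <- switch(family, weibull = "weibull", exponential = "exponential",
                      lognormal = "lognormal", loglogistic = "loglogistic",
                      NULL)
    if (!is.null(sr_dist) && sum(ds$events) >= 2) {
      fit <- tryCatch(suppressWarnings(
        survreg(Surv(ds$times, ds$events) ~ ds$X - 1, dist = sr_dist)),
        error = function(e) NULL)
      if (!is.null(fit) && all(is.finite(coef(fit)))) {
        sig <- fit$scale
        if (family %in% c("weibull", "exponential")) {
          # survreg: S(t) = exp(-(t e^{-x'gamma})^{1/sigma})
          #        = exp(-e^{-x'gamma/sigma} t^{1/sigma})
          alpha <- -coef(fit) / sig
          shape <- if (family == "exponential") 1 else 1 / sig
        } else {
          # lognormal/loglogistic: location on log-time scale is x'gamma,
          # ours is log mu = x'alpha
          alpha <- coef(fit)
          shape <- sig
        }
        names(alpha) <- NULL
      }
    }
  }
  cure_params(beta = beta, alpha = alpha,
              shape = max(min(shape, 20), 0.05), family = family)
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' One iteration of the sampler performs, in order: (1) an exact draw of each
#' latent susceptibility indicator \eqn{U_i} from its conditional
#' \eqn{P(U_i = 1 \mid c_i = 0) = \pi S_s / [(1-\pi) + \pi S_s]} (observed
#' events are susceptible with probability 1); (2) a multivariate Gaussian
#' random-walk Metropolis update of the incidence block \eqn{\beta};
#' (3) likewise for the latency block \eqn{\alpha}, whose conditional
#' involves only subjects currently imputed susceptible; (4) a Metropolis
#' update of \eqn{\log r} (symmetric in log space, Jacobian included), so the
#' shape stays positive by construction. Proposal scales and covariances
#' adapt during burn-in only.
#'
#' @param ds a [survival_data] object.
#' @param family latency family tag; the exponential family has no shape
#'   block (r fixed at 1).
#' @param prior a [cure_prior].
#' @param init optional [cure_params] starting point; defaults to a
#'   deterministic data-based initialization.
#' @param control a [chain_control].
#' @param model `"cure"` (the mixture model), `"standard"` (no-cure
#'   parametric survival: \eqn{\pi \equiv 1}, u fixed at 1, no incidence
#'   block or latent step), or `"logistic"` (Bayesian logistic regression of
#'   a binary outcome on Z: incidence block only).
#' @param prior_only if `TRUE`, the likelihood is switched off and the
#'   sampler targets the prior — a "sample the prior" correctness check for
#'   the Metropolis machinery. Deviance is not recorded in this mode.
#' @return object of class `cure_chain`: retained `draws` (matrix with named
#'   columns), per-draw `deviance` (\eqn{-2 \times} observed log-likelihood),
#'   `latent_mean` (per-subject posterior mean of \eqn{U_i}), post-burn-in
#'   `accept_rates` per block, `dic` components, and the configuration echo.
#' @export
run_cure_chain <- function(ds, family = "weibull", prior = cure_prior(),
                           init = NULL, control = chain_control(),
                           model = c("cure", "standard", "logistic"),
                           prior_only = FALSE) {
  model <- match.arg(model)
  validate_survival_data(ds)
  stopifnot(inherits(prior, "cure_prior"), inherits(control, "chain_control"))
  family <- match.arg(family, .FAMILIES)
  if (!is.null(control$seed)) set.seed(control$seed)

  q <- ds$q; p <- ds$p
  pr <- .realize_prior(prior, q, p)
  if (is.null(init)) init <- .default_init(ds, family, model)
  stopifnot(inherits(init, "cure_params"))
  .check_params_dims(ds, init)
  if (init$shape <= 0) stop("init shape must be > 0")

  has_shape <- family != "exponential" && model != "logistic"
  has_beta <- model != "standard"
  has_alpha <- model != "logistic"
  has_latent <- model == "cure" && !prior_only
  like <- !prior_only

  t_i <- ds$times; c_i <- ds$events
  Z <- ds$Z; X <- ds$X
  beta <- init$beta; alpha <- init$alpha; lshape <- log(init$shape)

  u <- if (model == "cure") {
    if (prior_only) rep(1L, ds$n) else .sample_latent(ds, init)
  } else if (model == "logistic") as.integer(c_i) else rep(1L, ds$n)

  # proposal machinery per block
  sc0 <- function(nm, d) {
    s <- control$scales[[nm]]
    if (!is.null(s)) s else if (prior_only) 2.38 / sqrt(d) else 0.25 / sqrt(d)
  }
  ad_b <- if (has_beta) .adapt_new(q, sc0("beta", q))
  ad_a <- if (has_alpha) .adapt_new(p, sc0("alpha", p))
  ad_s <- if (has_shape) .adapt_new(1L, sc0("shape", 1L))

  n_ret <- control$iterations %/% control$thin
  n_par <- (if (has_beta) q else 0L) + (if (has_alpha) p else 0L) +
    (if (has_shape) 1L else 0L)
  par_names <- c(if (has_beta) paste0("incidence.", colnames(Z)),
                 if (has_alpha) paste0("latency.", colnames(X)),
                 if (has_shape) "shape")
  draws <- matrix(NA_real_, n_ret, n_par, dimnames = list(NULL, par_names))
  dev <- rep(NA_real_, n_ret)
  u_sum <- numeric(ds$n)
  acc_post <- c(beta = 0, alpha = 0, shape = 0)
  try_post <- c(beta = 0, alpha = 0, shape = 0)

  total <- control$burnin + control$iterations
  ridx <- 0L

  deviance_at <- function(pars) {
    switch(model,
      cure = -2 * obs_loglik(ds, pars),
      standard = -2 * standard_loglik(ds, pars$alpha, pars$shape, family),
      logistic = {
        eta <- drop(Z %*% pars$beta)
        -2 * sum(plogis(eta[c_i == 1], log.p = TRUE),
                 plogis(-eta[c_i == 0], log.p = TRUE))
      })
  }

  for (iter in seq_len(total)) {
    in_burn <- iter <= control$burnin
    shape <- exp(lshape)

    if (has_latent) {
      u <- .sample_latent(ds, cure_params(beta, alpha, shape, family))
    }
    idx <- if (model == "cure") which(u == 1L) else seq_len(ds$n)
    Xs <- X[idx, , drop = FALSE]; ts <- t_i[idx]; cs <- c_i[idx]

    if (has_beta) {
      lt_cur <- .lt_beta(beta, Z, u, pr$beta, like)
      st <- .mh_step(beta, lt_cur,
                     function(bb) .lt_beta(bb, Z, u, pr$beta, like),
                     ad_b$L, exp(ad_b$lscale))
      beta <- st$x
      if (in_burn && control$adapt)
        ad_b <- .adapt_update(ad_b, beta, st$acc, control$target_accept)
      if (!in_burn) {
        try_post["beta"] <- try_post["beta"] + 1
        acc_post["beta"] <- acc_post["beta"] + st$acc
      }
    }

    if (has_alpha) {
      lt_cur <- .lt_alpha(alpha, Xs, ts, cs, shape, family, pr$alpha, like)
      st <- .mh_step(alpha, lt_cur,
                     function(aa) .lt_alpha(aa, Xs, ts, cs, shape, family,
                                            pr$alpha, like),
                     ad_a$L, exp(ad_a$lscale))
      alpha <- st$x
      if (in_burn && control$adapt)
        ad_a <- .adapt_update(ad_a, alpha, st$acc, control$target_accept)
      if (!in_burn) {
        try_post["alpha"] <- try_post["alpha"] + 1
        acc_post["alpha"] <- acc_post["alpha"] + st$acc
      }
    }

    if (has_shape) {
      mu_s <- exp(drop(Xs %*% alpha))
      lt_cur <- .lt_logshape(lshape, mu_s, ts, cs, family, pr$s1, pr$s2, like)
      st <- .mh_step(lshape, lt_cur,
                     function(ll) .lt_logshape(ll, mu_s, ts, cs, family,
                                               pr$s1, pr$s2, like),
                     ad_s$L, exp(ad_s$lscale))
      lshape <- st$x
      if (in_burn && control$adapt)
        ad_s <- .adapt_update(ad_s, lshape, st$acc, control$target_accept)
      if (!in_burn) {
        try_post["shape"] <- try_post["shape"] + 1
        acc_post["shape"] <- acc_post["shape"] + st$acc
      }
    }

    if (!in_burn && (iter - control$burnin) %% control$thin == 0L) {
      ridx <- ridx + 1L
      draws[ridx, ] <- c(if (has_beta) beta, if (has_alpha) alpha,
                         if (has_shape) exp(lshape))
      if (like) {
        dv <- deviance_at(cure_params(beta, alpha, exp(lshape), family))
        if (!is.finite(dv))
          stop("divergent (non-finite) deviance at iteration ", iter)
        dev[ridx] <- dv
      }
      u_sum <- u_sum + u
    }
  }
  draws <- draws[seq_len(ridx), , drop = FALSE]
  dev <- dev[seq_len(ridx)]

  res <- structure(list(
    draws = draws, deviance = dev, latent_mean = u_sum / ridx,
    accept_rates = ifelse(try_post > 0, acc_post / pmax(try_post, 1),
                          NA_real_),
    model = model, family = family, prior = prior, control = control,
    init = init, ds = ds,
    has = c(beta = has_beta, alpha = has_alpha, shape = has_shape),
    dims = c(q = q, p = p)), class = "cure_chain")

  if (like) {
    theta_bar <- colMeans(draws)
    pars_bar <- .chain_params(res, theta_bar)
    dhat <- deviance_at(pars_bar)
    if (!is.finite(dhat))
      stop("non-finite deviance at the posterior mean parameters")
    dbar <- mean(dev)
    res$dic <- list(Dbar = dbar, Dhat = dhat, pD = dbar - dhat,
                    DIC = 2 * dbar - dhat)
  }
  res
}

# Rebuild a cure_params from one row (or the column means) of the draw matrix.
.chain_params <- function(chain, theta) {
  q <- chain$dims["q"]; p <- chain$dims["p"]
  i <- 0L
  beta <- if (chain$has["beta"]) theta[seq_len(q)] else numeric(0)
  if (chain$has["beta"]) i <- q
  alpha <- if (chain$has["alpha"]) theta[i + seq_len(p)] else numeric(0)
  if (chain$has["alpha"]) i <- i + p
  shape <- if (chain$has["shape"]) theta[i + 1L] else 1
  cure_params(beta = if (length(beta)) beta else 0,
              alpha = if (length(alpha)) alpha else 0,
              shape = shape, family = chain$family)
}

#' @export
print.cure_chain <- function(x, ...) {
  cat("MCMC chain (", x$model, " model, ", x$family, " latency): ",
      nrow(x$draws), " retained draws of ", ncol(x$draws),
      " parameters\n", sep = "")
  ar <- x$accept_rates[!is.na(x$accept_rates)]
  if (length(ar))
    cat("  acceptance rates:",
        paste(names(ar), format(ar, digits = 2), collapse = ", "), "\n")
  if (!is.null(x$dic))
    cat("  DIC:", format(x$dic$DIC, digits = 6), "(pD =",
        format(x$dic$pD, digits = 3), ")\n")
  invisible(x)
}
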