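# Effective sample size via the initial positive sequence of autocorrelations.
.ess <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf[-1L]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1L] - 1L)]
  max(1, n / (1 + 2 * sum(rho)))
}

# Monte-Carlo standard error of the mean by non-overlapping batch means.
.mcse <- function(x) {
  n <- length(x)
  nb <- max(2L, floor(sqrt(n)))
  bs <- n %/% nb
  if (bs < 2L) return(sd(x) / sqrt(n))
  bm <- colMeans(matrix(x[seq_len(nb * bs)], nrow = bs))
  sd(bm) / sqrt(nb)
}

#' Posterior summary of retained MCMC draws
#'
#' Posterior mean, median, standard deviation and equal-tailed credible
#' interval per parameter (empirical quantiles, type-7 interpolation — R's
#' default), plus effective sample size and batch-means Monte-Carlo standard
#' error.
#'
#' @param chain a `cure_chain` (or the draw matrix itself).
#' @param level credible level in (0, 1); default 0.95.
#' @return data.frame with one row per parameter.
#' @export
posterior_summary <- function(chain, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must be a single number strictly between 0 and 1")
  draws <- if (inherits(chain, "cure_chain")) chain$draws else as.matrix(chain)
  if (nrow(draws) < 1L) stop("no retained draws to summarize")
  a <- (1 - level) / 2
  data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    median = apply(draws, 2, median),
    sd = apply(draws, 2, sd),
    lower = apply(draws, 2, quantile, probs = a, type = 7),
    upper = apply(draws, 2, quantile, probs = 1 - a, type = 7),
    ess = apply(draws, 2, .ess),
    mcse = apply(draws, 2, .mcse),
    row.names = NULL)
}

#' @export
summary.cure_chain <- function(object, level = 0.95, ...) {
  out <- list(table = posterior_summary(object, level), dic = object$dic,
              accept = object$accept_rates, level = level,
              model = object$model, family = object$family)
  class(out) <- "summary.cure_chain"
  out
}

#' @export
print.summary.cure_chain <- function(x, digits = 4, ...) {
  cat("Posterior summary (", x$model, " model, ", x$family,
      " latency), ", 100 * x$level, "% equal-tailed credible intervals\n\n",
      sep = "")
  print(cbind(x$table[1L],
              round(x$table[, c("mean", "median", "sd", "lower", "upper")],
                    digits),
              ess = round(x$table$ess)), row.names = FALSE)
  if (!is.null(x$dic))
    cat("\nDIC =", format(x$dic$DIC, digits = 7),
        " (Dbar =", format(x$dic$Dbar, digits = 7),
        ", pD =", format(x$dic$pD, digits = 4), ")\n")
  invisible(x)
}

#' Odds ratios (incidence) and hazard-ratio-scale effects (latency)
#'
#' For each incidence coefficient the long-term effect is reported as an odds
#' ratio, and for each latency coefficient the short-term effect on the
#' hazard-ratio scale: primary convention `exp(posterior mean of the
#' coefficient)` with the credible interval mapped through `exp` (exp is
#' monotone so the interval endpoints transform directly). The posterior mean
#' of `exp(coefficient)` is also reported (`mean_of_exp`), since the two
#' conventions differ under Jensen's inequality and published tables do not
#' always say which was used.
#'
#' @param object a `cure_chain` or [curemix] fit.
#' @param level credible level.
#' @param include_intercept report intercept rows too (default `FALSE`).
#' @return data.frame with columns `parameter`, `type` (`"OR"` or `"HR"`),
#'   `estimate`, `lower`, `upper`, `mean_of_exp`.
#' @export
odds_hazard_ratios <- function(object, level = 0.95,
                               include_intercept = FALSE) {
  chain <- if (inherits(object, "curemix")) object$chain else object
  stopifnot(inherits(chain, "cure_chain"))
  tab <- posterior_summary(chain, level)
  is_inc <- grepl("^incidence\\.", tab$parameter)
  is_lat <- grepl("^latency\\.", tab$parameter)
  keep <- (is_inc | is_lat)
  if (!include_intercept)
    keep <- keep & !grepl("\\(Intercept\\)$", tab$parameter)
  tab <- tab[keep, , drop = FALSE]
  if (!nrow(tab)) return(data.frame())
  moe <- colMeans(exp(chain$draws[, tab$parameter, drop = FALSE]))
  data.frame(
    parameter = sub("^(incidence|latency)\\.", "", tab$parameter),
    type = ifelse(grepl("^incidence\\.", tab$parameter), "OR", "HR"),
    estimate = exp(tab$mean),
    lower = exp(tab$lower),
    upper = exp(tab$upper),
    mean_of_exp = unname(moe),
    row.names = NULL)
}

#' Deviance information criterion
#'
#' \eqn{\bar D} is the posterior mean of the per-draw deviance
#' \eqn{D(\Theta) = -2 \log f(y \mid \Theta)};
#' \eqn{D(\bar\Theta)} is the deviance at the posterior-mean parameters;
#' the effective number of parameters is \eqn{p_D = \bar D - D(\bar\Theta)}
#' and \eqn{\mathrm{DIC} = \bar D + p_D = 2\bar D - D(\bar\Theta)}. Lower
#' values indicate better-fitting models.
#'
#' @param object a `cure_chain` or [curemix] fit.
#' @return list with components `Dbar`, `Dhat`, `pD`, `DIC`.
#' @export
dic <- function(object) {
  chain <- if (inherits(object, "curemix")) object$chain else object
  stopifnot(inherits(chain, "cure_chain"))
  if (is.null(chain$dic))
    stop("chain carries no deviance (was it run with prior_only = TRUE?)")
  chain$dic
}

# Per-draw event probabilities P(T <= horizon | x, z) = pi(z) * Fs(h | x)
# for each row of (Xnew, Znew); horizon = Inf gives pi(z). Returns a
# draws x nrow matrix.
.event_prob_draws <- function(chain, Xnew, Znew, horizon) {
  q <- chain$dims["q"]; p <- chain$dims["p"]
  nd <- nrow(chain$draws)
  betas <- if (chain$has["beta"])
    chain$draws[, seq_len(q), drop = FALSE] else NULL
  off <- if (chain$has["beta"]) q else 0L
  alphas <- if (chain$has["alpha"])
    chain$draws[, off + seq_len(p), drop = FALSE] else NULL
  shapes <- if (chain$has["shape"]) chain$draws[, "shape"] else rep(1, nd)

  pi_d <- if (is.null(betas)) matrix(1, nd, nrow(Znew))
          else plogis(betas %*% t(Znew))
  if (!is.finite(horizon)) return(pi_d)
  if (horizon <= 0) stop("horizon must be > 0")
  eta <- alphas %*% t(Xnew)              # nd x n matrix of log mu
  Fs <- matrix(NA_real_, nd, ncol(eta))
  for (d in seq_len(nd)) {
    Fs[d, ] <- 1 - exp(.lat_logsurv(horizon, exp(eta[d, ]), chain$family,
                                    shapes[d]))
  }
  pi_d * Fs
}

#' Posterior event probability by a fixed horizon
#'
#' For each retained draw computes
#' \eqn{P(T \le h \mid x, z) = \pi(z) F_s(h \mid x)} — the (improper)
#' population cdf of the mixture — and summarizes over draws. An infinite
#' horizon gives the eventual-event (susceptibility) probability
#' \eqn{\pi(z)}.
#'
#' @param chain a `cure_chain` from the cure model.
#' @param x latency covariate vector or matrix (rows = subjects).
#' @param z incidence covariate vector or matrix.
#' @param horizon positive scalar horizon, or `Inf`.
#' @param level credible level.
#' @return data.frame with one row per subject: `mean`, `median`, `lower`,
#'   `upper`.
#' @export
predict_event_probability <- function(chain, x, z, horizon = Inf,
                                      level = 0.95) {
  stopifnot(inherits(chain, "cure_chain"))
  Xnew <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  Znew <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  pr <- .event_prob_draws(chain, Xnew, Znew, horizon)
  a <- (1 - level) / 2
  data.frame(mean = colMeans(pr),
             median = apply(pr, 2, median),
             lower = apply(pr, 2, quantile, probs = a),
             upper = apply(pr, 2, quantile, probs = 1 - a))
}

#' Group-level event probabilities, two estimation methods
#'
#' Estimates the mean probability of an event by `horizon` for a group
#' defined by fixing one or more covariates (e.g. `NP = 0`):
#'
#' * method 1: average the per-individual predicted probabilities over the
#'   subjects that actually belong to the group;
#' * method 2: set the group-defining covariates to their stipulated values
#'   for *all* subjects (keeping everything else at its observed value) and
#'   average over the whole sample.
#'
#' Method 2 uses the entire sample, but when the group-defining covariates
#' are correlated with the remaining ones the counterfactual profiles it
#' averages over need not resemble real group members, which biases the
#' estimate; the bias grows with the dependence. Comparing the two methods
#' quantifies that bias. The dispersion reported (`sd_individuals`) is the
#' standard deviation of per-individual posterior-mean probabilities across
#' the subjects averaged over — a spread across individuals, not a credible
#' interval.
#'
#' @param fit a [curemix] fit (the fitted model supplies both design
#'   matrices and the original subjects).
#' @param group named list of covariate values defining the group, e.g.
#'   `list(NP = 0)`. Names must match design-matrix columns.
#' @param horizon positive scalar or `Inf`.
#' @param method 1 or 2 (default 2).
#' @param level credible level for the posterior interval of the group mean.
#' @return one-row data.frame: `mean`, `lower`, `upper`, `sd_individuals`,
#'   `n_used`, `method`.
#' @export
group_probability <- function(fit, group, horizon = Inf, method = 2,
                              level = 0.95) {
  stopifnot(inherits(fit, "curemix"))
  chain <- fit$chain
  X <- fit$ds$X; Z <- fit$ds$Z
  if (!length(names(group)) || any(!nzchar(names(group))))
    stop("group must be a named list of covariate values")
  known <- union(colnames(X), colnames(Z))
  bad <- setdiff(names(group), known)
  if (length(bad))
    stop("unknown group covariate(s): ", paste(bad, collapse = ", "))

  if (method == 1) {
    sel <- rep(TRUE, nrow(Z))
    for (v in names(group)) {
      col <- if (v %in% colnames(Z)) Z[, v] else X[, v]
      sel <- sel & (col == group[[v]])
    }
    if (!any(sel)) stop("no subjects satisfy the group definition ",
                        "(method 1 requires a non-empty group)")
    Xg <- X[sel, , drop = FALSE]; Zg <- Z[sel, , drop = FALSE]
  } else if (method == 2) {
    Xg <- X; Zg <- Z
    for (v in names(group)) {
      if (v %in% colnames(Xg)) Xg[, v] <- group[[v]]
      if (v %in% colnames(Zg)) Zg[, v] <- group[[v]]
    }
  } else stop("method must be 1 or 2")

  pr <- .event_prob_draws(chain, Xg, Zg, horizon)   # draws x n_used
  gmean <- rowMeans(pr)                              # per-draw group mean
  a <- (1 - level) / 2
  data.frame(mean = mean(gmean),
             lower = quantile(gmean, a, names = FALSE),
             upper = quantile(gmean, 1 - a, names = FALSE),
             sd_individuals = sd(colMeans(pr)),
             n_used = ncol(pr),
             method = method)
}
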