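#' Kaplan-Meier product-limit estimate with cure-plateau readout
#'
#' Nonparametric estimate \eqn{\hat S(t) = \prod_{t_j \le t} (1 - d_j/n_j)}
#' with Greenwood variance and log-scale confidence bands (computed by
#' [survival::survfit()]; ties between events and censorings at the same time
#' follow the standard convention, events first). The survival level at the
#' last observed event time (`plateau`) is the empirical signature of the
#' cure fraction: in a split-population cohort with long follow-up it
#' estimates the population mean of \eqn{1 - \pi(z)}.
#'
#' The bands are frequentist (Greenwood) confidence intervals; some published
#' figures label such KM bands "credible intervals", but no prior enters
#' here.
#'
#' @param ds a [survival_data] object.
#' @param level confidence level for the bands (default 0.95).
#' @param conf_type passed to `survfit` (`"log"` default; `"plain"` gives
#'   untransformed Greenwood bands).
#' @return object of class `km_estimate`: a data.frame-backed list with
#'   `time`, `n_risk`, `n_event`, `survival`, `std_err`, `lower`, `upper`
#'   at every distinct observed time, plus `plateau` (survival at the last
#'   event time; 1 if no events) and `n`.
#' @export
#' @examples
#' ds <- survival_data(c(1, 2, 3), c(1, 1, 1))
#' km_fit(ds)$table$survival  # 2/3, 1/3, 0
km_fit <- function(ds, level = 0.95, conf_type = "log") {
  validate_survival_data(ds)
  sf <- survfit(Surv(ds$times, ds$events) ~ 1, conf.int = level,
                conf.type = conf_type)
  tab <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    survival = sf$surv, std_err = sf$std.err,
                    lower = sf$lower, upper = sf$upper)
  ev <- tab$n_event > 0
  plateau <- if (any(ev)) tab$survival[max(which(ev))] else 1
  structure(list(table = tab, plateau = plateau, n = ds$n, level = level,
                 conf_type = conf_type),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("Kaplan-Meier estimate: n =", x$n, "subjects,",
      sum(x$table$n_event), "events\n")
  cat("  plateau (survival at last event time):",
      format(x$plateau, digits = 4), "\n")
  invisible(x)
}

#' @export
as.data.frame.km_estimate <- function(x, ...) x$table

#' @export
plot.km_estimate <- function(x, col = "black", band_col = "grey80",
                             xlab = "time", ylab = "survival", add = FALSE,
                             ...) {
  tab <- x$table
  t0 <- c(0, tab$time); s0 <- c(1, tab$survival)
  if (!add) {
    plot(t0, s0, type = "n", ylim = c(0, 1), xlab = xlab, ylab = ylab, ...)
    lo <- c(1, pmax(tab$lower, 0)); hi <- c(1, pmin(tab$upper, 1))
    ok <- is.finite(lo) & is.finite(hi)
    polygon(c(t0[ok], rev(t0[ok])), c(lo[ok], rev(hi[ok])),
            col = band_col, border = NA)
  }
  lines(t0, s0, type = "s", col = col)
  invisible(x)
}

#' Stratified Kaplan-Meier estimates
#'
#' Splits the sample on one covariate and fits a KM curve per stratum. Split
#' rules: `"nonzero"` compares `variable > 0` vs `variable == 0` (natural for
#' count covariates), `"median"` compares `variable >= median` vs
#' `< median` (continuous covariates; ties go to the upper stratum),
#' `"levels"` makes one stratum per distinct value (binary covariates).
#'
#' @param ds a [survival_data] object.
#' @param variable name of a covariate column present in either design
#'   matrix.
#' @param split `"nonzero"`, `"median"`, or `"levels"`.
#' @param level confidence level for the bands.
#' @return named list of `km_estimate` objects (strata partition the
#'   sample); empty strata are dropped with a warning.
#' @export
km_by_group <- function(ds, variable, split = c("nonzero", "median",
                                                "levels"), level = 0.95) {
  split <- match.arg(split)
  validate_survival_data(ds)
  col <- if (variable %in% colnames(ds$Z)) ds$Z[, variable]
         else if (variable %in% colnames(ds$X)) ds$X[, variable]
         else stop("covariate '", variable, "' not found in either design ",
                   "matrix")
  groups <- switch(split,
    nonzero = ifelse(col > 0, paste0(variable, ">0"), paste0(variable, "=0")),
    median = {
      m <- median(col)
      ifelse(col >= m, paste0(variable, ">=median"),
             paste0(variable, "<median"))
    },
    levels = paste0(variable, "=", col))
  out <- list()
  for (g in sort(unique(groups))) {
    sel <- groups == g
    if (!any(sel)) { warning("empty stratum ", g, " omitted"); next }
    sub <- survival_data(ds$times[sel], ds$events[sel],
                         latency = ds$X[sel, , drop = FALSE],
                         incidence = ds$Z[sel, , drop = FALSE],
                         follow_up_limit = ds$follow_up_limit)
    out[[g]] <- km_fit(sub, level = level)
  }
  out
}
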