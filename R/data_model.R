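#' Construct a right-censored survival dataset with split covariate roles
#'
#' Container for the data of a mixture cure rate analysis: one row per
#' subject, an observed time, an event indicator, and two (possibly
#' overlapping) design matrices — one for the incidence (logistic) sub-model
#' and one for the latency (time-to-event) sub-model. Intercepts are explicit
#' columns of the design matrices, never implicit, so that intercept-only
#' model variants are purely a matter of matrix construction.
#'
#' @param times positive numeric vector of observed times (event or censoring),
#'   one time unit throughout (e.g. years).
#' @param events integer/numeric vector in \{0, 1\}; 1 = event observed,
#'   0 = right-censored.
#' @param latency numeric matrix (n x p) of latency covariates \eqn{x_i},
#'   including the intercept column. `NULL` gives an intercept-only matrix.
#' @param incidence numeric matrix (n x q) of incidence covariates \eqn{z_i},
#'   including the intercept column. `NULL` gives an intercept-only matrix.
#' @param follow_up_limit optional positive scalar L: the administrative
#'   follow-up horizon. If given, all times must be <= L.
#' @param transforms optional list recording centering/scaling applied to
#'   covariate columns (as produced by [read_survival_data()] with
#'   `standardize = TRUE`), used to back-transform coefficients.
#'
#' @return An object of class `survival_data`: a list with elements `times`,
#'   `events`, `X` (latency design), `Z` (incidence design),
#'   `follow_up_limit`, `transforms`, and `n`, `p`, `q`.
#' @export
#' @examples
#' ds <- survival_data(times = c(1, 2, 3), events = c(1, 0, 1))
#' ds$n
survival_data <- function(times, events, latency = NULL, incidence = NULL,
                          follow_up_limit = NULL, transforms = NULL) {
  times <- as.numeric(times)
  events <- as.numeric(events)
  n <- length(times)
  if (n < 1L) stop("dataset must contain at least one subject")
  if (is.null(latency)) {
    latency <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  if (is.null(incidence)) {
    incidence <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  latency <- as.matrix(latency)
  incidence <- as.matrix(incidence)
  if (is.null(colnames(latency)))
    colnames(latency) <- paste0("x", seq_len(ncol(latency)))
  if (is.null(colnames(incidence)))
    colnames(incidence) <- paste0("z", seq_len(ncol(incidence)))

  ds <- structure(
    list(times = times, events = events, X = latency, Z = incidence,
         follow_up_limit = follow_up_limit, transforms = transforms,
         n = n, p = ncol(latency), q = ncol(incidence)),
    class = "survival_data")
  validate_survival_data(ds)
  ds
}

#' Validate a survival_data object
#'
#' Checks the dataset invariants: equal row counts, strictly positive times,
#' \{0,1\} events, no missing values, and times within the follow-up limit.
#' Violations raise an error naming the first offending row; nothing is ever
#' imputed or clamped (the latency density is undefined at t <= 0).
#'
#' @param ds a `survival_data` object.
#' @return `ds`, invisibly, if valid.
#' @export
validate_survival_data <- function(ds) {
  stopifnot(inherits(ds, "survival_data"))
  n <- ds$n
  if (length(ds$events) != n || nrow(ds$X) != n || nrow(ds$Z) != n)
    stop("times, events, latency and incidence matrices must all have ", n,
         " rows")
  bad <- which(!is.finite(ds$times))
  if (length(bad) == 0L) bad <- which(ds$times <= 0)
  if (length(bad))
    stop("non-positive or missing time at row ", bad[1L],
         " (times must be strictly > 0)")
  bad <- which(!(ds$events %in% c(0, 1)))
  if (length(bad))
    stop("event indicator not in {0, 1} at row ", bad[1L])
  if (anyNA(ds$X) || any(!is.finite(ds$X))) {
    bad <- which(!complete.cases(ds$X) | rowSums(!is.finite(ds$X)) > 0)
    stop("missing/non-finite latency covariate at row ", bad[1L],
         " (missing values are rejected, not imputed)")
  }
  if (anyNA(ds$Z) || any(!is.finite(ds$Z))) {
    bad <- which(!complete.cases(ds$Z) | rowSums(!is.finite(ds$Z)) > 0)
    stop("missing/non-finite incidence covariate at row ", bad[1L],
         " (missing values are rejected, not imputed)")
  }
  if (!is.null(ds$follow_up_limit)) {
    L <- ds$follow_up_limit
    if (!is.numeric(L) || length(L) != 1L || L <= 0)
      stop("follow_up_limit must be a positive scalar")
    bad <- which(ds$times > L)
    if (length(bad))
      stop("time exceeds follow-up limit L = ", L, " at row ", bad[1L])
  }
  invisible(ds)
}

#' @export
print.survival_data <- function(x, ...) {
  ev <- sum(x$events)
  cat("Right-censored survival dataset: n =", x$n, "subjects,",
      ev, "events,", x$n - ev, "censored\n")
  cat("  latency covariates  (p =", x$p, "):",
      paste(colnames(x$X), collapse = ", "), "\n")
  cat("  incidence covariates (q =", x$q, "):",
      paste(colnames(x$Z), collapse = ", "), "\n")
  if (!is.null(x$follow_up_limit))
    cat("  follow-up limit L =", x$follow_up_limit, "\n")
  invisible(x)
}

# Delimiter auto-detection between tab and comma, from the header line.
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a right-censored dataset from a delimited text file
#'
#' Reads a CSV/TSV file with a header row (delimiter auto-detected between
#' comma and tab) and assigns column roles. Explicit intercept columns are
#' prepended to both design matrices.
#'
#' @param path file path to a delimited text file with a header.
#' @param time_col,event_col names of the time and event columns.
#' @param latency_cols,incidence_cols character vectors of covariate column
#'   names for the latency and incidence sub-models (either may be `NULL` for
#'   an intercept-only design; columns may appear in both).
#' @param standardize if `TRUE`, continuous covariates (more than two distinct
#'   values) are centered and scaled; the transform parameters are stored in
#'   the returned object's `transforms` so coefficients can be
#'   back-transformed to the original scale.
#' @param follow_up_limit optional administrative follow-up horizon L.
#' @param sep field delimiter; `NULL` (default) auto-detects "," vs tab.
#' @return a [survival_data] object.
#' @export
read_survival_data <- function(path, time_col = "time", event_col = "event",
                               latency_cols = NULL, incidence_cols = NULL,
                               standardize = FALSE, follow_up_limit = NULL,
                               sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- .detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  needed <- unique(c(time_col, event_col, latency_cols, incidence_cols))
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  if (!is.numeric(df[[time_col]]))
    stop("time column '", time_col, "' must be numeric")
  if (!is.numeric(df[[event_col]]))
    stop("event column '", event_col, "' must be numeric 0/1")

  covs <- unique(c(latency_cols, incidence_cols))
  transforms <- NULL
  if (standardize && length(covs)) {
    transforms <- list()
    for (v in covs) {
      col <- df[[v]]
      if (is.numeric(col) && length(unique(col)) > 2L) {
        m <- mean(col); s <- sd(col)
        if (s > 0) {
          df[[v]] <- (col - m) / s
          transforms[[v]] <- c(center = m, scale = s)
        }
      }
    }
    if (!length(transforms)) transforms <- NULL
  }

  mk <- function(cols) {
    mat <- cbind(`(Intercept)` = rep(1, nrow(df)),
                 if (length(cols)) as.matrix(df[cols]) else NULL)
    storage.mode(mat) <- "double"
    mat
  }
  survival_data(times = df[[time_col]], events = df[[event_col]],
                latency = mk(latency_cols), incidence = mk(incidence_cols),
                follow_up_limit = follow_up_limit, transforms = transforms)
}

#' Write a survival dataset to a delimited text file
#'
#' Writes `time`, `event` and the (non-intercept) covariate columns of both
#' design matrices, merged by name, so that [read_survival_data()] with the
#' same role assignment round-trips the dataset exactly up to float formatting.
#'
#' @param ds a [survival_data] object.
#' @param path output file path.
#' @param sep field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_survival_data <- function(ds, path, sep = ",") {
  validate_survival_data(ds)
  out <- data.frame(time = ds$times, event = ds$events, check.names = FALSE)
  for (mat in list(ds$X, ds$Z)) {
    keep <- setdiff(colnames(mat), "(Intercept)")
    for (v in keep) {
      if (!is.null(out[[v]])) {
        if (!isTRUE(all.equal(out[[v]], unname(mat[, v]))))
          stop("covariate '", v, "' differs between design matrices; ",
               "rename one of the columns before writing")
      } else {
        out[[v]] <- mat[, v]
      }
    }
  }
  ok <- tryCatch({
    write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("could not write ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}
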