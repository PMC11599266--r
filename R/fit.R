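#' Pseudo individual-patient data
#'
#' A `pseudo_ipd` is a data frame of right-censored event records with columns
#' `time` (months, strictly positive) and `event` (1 = event, 0 = censored).
#' It is the unit of exchange between the Kaplan-Meier reconstruction step and
#' maximum-likelihood fitting.
#'
#' @param time Numeric vector of strictly positive follow-up times in months.
#' @param event Integer/logical vector, 1 (TRUE) for an observed event,
#'   0 (FALSE) for censoring.
#' @return A data frame of class `pseudo_ipd`.
#' @export
pseudo_ipd <- function(time, event) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (length(time) != length(event)) {
    stop("'time' and 'event' must have the same length", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("all follow-up times must be finite and strictly positive", call. = FALSE)
  }
  if (!all(event %in% c(0L, 1L))) {
    stop("'event' must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  if (sum(event) < 1L) {
    stop("at least one event record is required", call. = FALSE)
  }
  structure(data.frame(time = time, event = event),
            class = c("pseudo_ipd", "data.frame"))
}

#' Read/write pseudo-IPD as CSV
#'
#' The on-disk dialect has header `time_months,event` with `event` in `{0,1}`.
#'
#' @param data A [pseudo_ipd()] object.
#' @param path File path.
#' @return `read_ipd` returns a [pseudo_ipd()]; `write_ipd` returns `path`
#'   invisibly.
#' @export
write_ipd <- function(data, path) {
  stopifnot(inherits(data, "pseudo_ipd"))
  utils::write.csv(
    data.frame(time_months = data$time, event = data$event),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_ipd
#' @export
read_ipd <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_months", "event") %in% names(df))) {
    stop("IPD CSV must have columns 'time_months' and 'event'", call. = FALSE)
  }
  pseudo_ipd(df$time_months, df$event)
}

#' Fit a parametric survival family by maximum likelihood
#'
#' Maximizes the right-censored log-likelihood
#' \eqn{\sum_{events} \log f(t_i) + \sum_{censored} \log S(t_i)} for one
#' family, via [flexsurv::flexsurvreg()]. Estimated parameters are mapped back
#' onto the package's (shape, scale) convention (see
#' [parametric_survival()]).
#'
#' AIC and BIC follow the usual definitions
#' \eqn{AIC = -2\ell + 2k} and \eqn{BIC = -2\ell + k \log n}, with `k` the
#' number of free parameters (1 for exponential, 2 otherwise) and `n` the
#' number of records.
#'
#' A fit that fails to converge is returned as an explicit failure
#' (`converged = FALSE`, criteria `NA`) rather than an error or a silent
#' `NaN`, so that fitting all six families never aborts on one pathological
#' family.
#'
#' @param data A [pseudo_ipd()] object with at least one event (and at least
#'   two distinct times for two-parameter families).
#' @param family A family name from [surv_families()].
#' @return An object of class `surv_fit`: a list with elements `model`
#'   ([parametric_survival()] or `NULL`), `family`, `loglik`, `aic`, `bic`,
#'   `n`, `converged`.
#' @export
fit_mle <- function(data, family) {
  stopifnot(inherits(data, "pseudo_ipd"))
  family <- match.arg(family, surv_families())
  if (sum(data$event) < 1L) stop("cannot fit: no events in data", call. = FALSE)
  k <- n_surv_params(family)
  if (k == 2L && length(unique(data$time)) < 2L) {
    stop("two-parameter families need at least two distinct times", call. = FALSE)
  }
  n <- nrow(data)
  dist <- switch(family,
    exponential = "exp", weibull = "weibull", lognormal = "lnorm",
    loglogistic = "llogis", gompertz = "gompertz", gamma = "gamma"
  )
  failure <- structure(
    list(model = NULL, family = family, loglik = NA_real_, aic = NA_real_,
         bic = NA_real_, n = n, converged = FALSE),
    class = "surv_fit"
  )
  fit <- tryCatch(
    flexsurv::flexsurvreg(
      survival::Surv(data$time, data$event) ~ 1, dist = dist,
      control = list(reltol = 1e-10)
    ),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(fit) || any(!is.finite(fit$res[, "est"])) || !is.finite(fit$loglik)) {
    return(failure)
  }
  est <- stats::setNames(fit$res[, "est"], rownames(fit$res))
  model <- switch(family,
    exponential = parametric_survival("exponential", scale = est[["rate"]]),
    weibull     = parametric_survival("weibull", est[["shape"]], est[["scale"]]),
    lognormal   = parametric_survival("lognormal", est[["meanlog"]], est[["sdlog"]]),
    loglogistic = parametric_survival("loglogistic", est[["shape"]], est[["scale"]]),
    gompertz    = parametric_survival("gompertz", est[["shape"]], est[["rate"]]),
    gamma       = parametric_survival("gamma", est[["shape"]], est[["rate"]])
  )
  structure(
    list(model = model, family = family, loglik = fit$loglik,
         aic = -2 * fit$loglik + 2 * k,
         bic = -2 * fit$loglik + k * log(n),
         n = n, converged = TRUE),
    class = "surv_fit"
  )
}

#' @export
print.surv_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<surv_fit> %s: did not converge (n = %d)\n", x$family, x$n))
  } else {
    cat(sprintf(
      "<surv_fit> %s(shape = %.4g, scale = %.4g): loglik %.3f, AIC %.2f, BIC %.2f, n = %d\n",
      x$family, x$model$shape, x$model$scale, x$loglik, x$aic, x$bic, x$n))
  }
  invisible(x)
}

#' Fit all six families to one dataset
#'
#' @param data A [pseudo_ipd()] object.
#' @param families Families to fit; defaults to all of [surv_families()].
#' @return A list of `surv_fit` objects, named by family, in canonical order.
#' @export
fit_all <- function(data, families = surv_families()) {
  families <- match.arg(families, surv_families(), several.ok = TRUE)
  fits <- lapply(families, function(f) fit_mle(data, f))
  names(fits) <- families
  fits
}

#' Select the best fit by information criterion
#'
#' Returns the converged fit with the minimal AIC or BIC. Exact ties are
#' broken deterministically by the canonical family order of
#' [surv_families()].
#'
#' @param fits A non-empty list of `surv_fit` objects.
#' @param criterion `"aic"` or `"bic"`.
#' @return The selected `surv_fit`.
#' @export
select_best <- function(fits, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  if (length(fits) == 0L) stop("no fits supplied", call. = FALSE)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!all(ok)) {
    warning(sprintf("dropping %d non-converged fit(s): %s", sum(!ok),
                    paste(vapply(fits[!ok], `[[`, "", "family"), collapse = ", ")))
    fits <- fits[ok]
  }
  if (length(fits) == 0L) stop("no converged fits to select from", call. = FALSE)
  crit <- vapply(fits, `[[`, numeric(1), criterion)
  fam_rank <- match(vapply(fits, `[[`, "", "family"), surv_families())
  fits[[order(crit, fam_rank)[1L]]]
}

#' Tabulate a list of fits
#'
#' One row per family: `family, shape, scale, loglik, aic, bic`, mirroring
#' the CSV export dialect.
#'
#' @param fits A list of `surv_fit` objects.
#' @param path Optional CSV path; if given the table is also written there.
#' @return A data frame.
#' @export
fit_table <- function(fits, path = NULL) {
  df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(
      family = f$family,
      shape = if (f$converged) f$model$shape else NA_real_,
      scale = if (f$converged) f$model$scale else NA_real_,
      loglik = f$loglik, aic = f$aic, bic = f$bic, n = f$n,
      converged = f$converged
    )
  }))
  rownames(df) <- NULL
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  df
}

#' Least-squares fit on the log-cumulative-hazard scale (cross-check)
#'
#' An alternative estimator that regresses the curve coordinates directly:
#' for each digitized point, the empirical cumulative hazard
#' \eqn{-\log S} is computed and family parameters are found by minimizing
#' squared error on the log-cumulative-hazard scale. Useful as an independent
#' cross-check of the IPD-MLE route; not used in the main pipeline.
#'
#' @param curve A [digitized_curve()] object.
#' @param family A family name from [surv_families()].
#' @return A [parametric_survival()] object.
#' @export
fit_curve_lsq <- function(curve, family) {
  stopifnot(inherits(curve, "digitized_curve"))
  family <- match.arg(family, surv_families())
  pts <- curve$points
  keep <- pts$survival > 0 & pts$survival < 1 & pts$time > 0
  if (sum(keep) < 2L) stop("need at least two interior points", call. = FALSE)
  tt <- pts$time[keep]
  y <- log(-log(pts$survival[keep]))
  obj <- function(par) {
    m <- tryCatch(
      switch(family,
        exponential = parametric_survival("exponential", scale = exp(par[1])),
        lognormal   = parametric_survival("lognormal", par[1], exp(par[2])),
        gompertz    = parametric_survival("gompertz", par[1], exp(par[2])),
        parametric_survival(family, exp(par[1]), exp(par[2]))
      ),
      error = function(e) NULL
    )
    if (is.null(m)) return(1e10)
    yhat <- log(cum_hazard(m, tt))
    if (any(!is.finite(yhat))) return(1e10)
    sum((y - yhat)^2)
  }
  init <- switch(family,
    exponential = 0, lognormal = c(log(stats::median(tt)), 0), gompertz = c(0.1, -2),
    c(0, log(stats::median(tt)))
  )
  opt <- stats::optim(init, obj, control = list(maxit = 2000, reltol = 1e-12))
  par <- opt$par
  switch(family,
    exponential = parametric_survival("exponential", scale = exp(par[1])),
    lognormal   = parametric_survival("lognormal", par[1], exp(par[2])),
    gompertz    = parametric_survival("gompertz", par[1], exp(par[2])),
    parametric_survival(family, exp(par[1]), exp(par[2]))
  )
}
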