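#' Parametric survival distributions
#'
#' A `parametric_survival` object represents one of six parametric survival
#' families by a (shape, scale) pair. The pair is mapped onto each family's
#' conventional parameters as follows:
#'
#' * `exponential` — `scale` is the rate; `shape` is unused (`NA`).
#' * `weibull` — `shape`/`scale` as in [stats::pweibull()],
#'   \eqn{S(t) = \exp(-(t/\lambda)^k)}.
#' * `lognormal` — `shape` is the meanlog and `scale` the sdlog of the
#'   event-time distribution, both on the log-month scale. This is the
#'   convention used for fitted oncology curves in the shipped configuration
#'   (e.g. a meanlog of 2.398 puts the median at `exp(2.398) = 11.0` months).
#' * `loglogistic` — `shape`/`scale` as in [flexsurv::pllogis()],
#'   \eqn{S(t) = 1/(1 + (t/\lambda)^k)}.
#' * `gompertz` — `shape` is the Gompertz rate parameter \eqn{\gamma} (may be
#'   negative) and `scale` the baseline hazard \eqn{\lambda}:
#'   \eqn{S(t) = \exp(-(\lambda/\gamma)(e^{\gamma t} - 1))}. With a negative
#'   shape the survival function plateaus above zero (a defective
#'   distribution); this is permitted and documented rather than an error.
#' * `gamma` — `shape` and rate (`scale` slot holds the rate), as in
#'   [stats::pgamma()].
#'
#' Time is in months everywhere. Cycle lengths given in days are converted at
#' 1 month = 30.4375 days.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`, `"gompertz"`, `"gamma"`.
#' @param shape,scale Numeric parameters, interpreted per family as above.
#'   For the exponential family pass the rate as `scale` and omit `shape`.
#' @return An object of class `parametric_survival`.
#' @examples
#' os <- parametric_survival("lognormal", shape = 2.398, scale = 0.808)
#' surv_prob(os, c(0, 6, 12, 24))
#' @export
parametric_survival <- function(family, shape = NA_real_, scale) {
  family <- match.arg(family, surv_families())
  shape <- as.numeric(shape)
  scale <- as.numeric(scale)
  if (length(shape) != 1L || length(scale) != 1L) {
    stop("'shape' and 'scale' must be single numbers", call. = FALSE)
  }
  check_surv_params(family, shape, scale)
  structure(
    list(family = family, shape = shape, scale = scale, time_unit = "months"),
    class = "parametric_survival"
  )
}

#' The supported survival families, in canonical order
#'
#' The order is also the deterministic tie-break used by [select_best()].
#' @return Character vector of family names.
#' @export
surv_families <- function() {
  c("exponential", "weibull", "lognormal", "loglogistic", "gompertz", "gamma")
}

# number of free parameters per family (exponential has only a rate)
n_surv_params <- function(family) {
  if (family == "exponential") 1L else 2L
}

check_surv_params <- function(family, shape, scale) {
  bad <- function(msg) stop(sprintf("invalid %s parameters: %s", family, msg),
                            call. = FALSE)
  if (!is.finite(scale)) bad("scale must be finite")
  switch(family,
    exponential = if (scale <= 0) bad("rate (scale) must be > 0"),
    weibull = {
      if (!is.finite(shape) || shape <= 0) bad("shape must be > 0")
      if (scale <= 0) bad("scale must be > 0")
    },
    lognormal = {
      if (!is.finite(shape)) bad("meanlog (shape) must be finite")
      if (scale <= 0) bad("sdlog (scale) must be > 0")
    },
    loglogistic = {
      if (!is.finite(shape) || shape <= 0) bad("shape must be > 0")
      if (scale <= 0) bad("scale must be > 0")
    },
    gompertz = {
      if (!is.finite(shape)) bad("shape must be finite")
      if (scale <= 0) bad("rate (scale) must be > 0")
    },
    gamma = {
      if (!is.finite(shape) || shape <= 0) bad("shape must be > 0")
      if (scale <= 0) bad("rate (scale) must be > 0")
    }
  )
  invisible(TRUE)
}

#' @export
print.parametric_survival <- function(x, ...) {
  cat(sprintf("<parametric_survival> %s(shape = %s, scale = %s), time in %s\n",
              x$family, format(x$shape), format(x$scale), x$time_unit))
  invisible(x)
}

check_time <- function(t) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("time 't' must be finite and >= 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Survival, density, hazard and quantile functions
#'
#' `surv_prob()` evaluates \eqn{S(t)}, `surv_density()` the density
#' \eqn{f(t) = -dS/dt}, `cum_hazard()` the cumulative hazard
#' \eqn{H(t) = -\log S(t)}, and `surv_quantile()` the inverse of the event-time
#' CDF (used for inverse-transform simulation).
#'
#' `cum_hazard()` returns `Inf` where \eqn{S(t) = 0}; this sentinel is the
#' documented behaviour, not an error.
#'
#' @param model A [parametric_survival()] object.
#' @param t Vector of times in months, all `>= 0`.
#' @param p Vector of probabilities in `[0, 1]` (for `surv_quantile`).
#' @return Numeric vector the length of `t` (or `p`).
#' @export
surv_prob <- function(model, t) {
  stopifnot(inherits(model, "parametric_survival"))
  check_time(t)
  s <- with(model, switch(family,
    exponential = stats::pexp(t, rate = scale, lower.tail = FALSE),
    weibull     = stats::pweibull(t, shape = shape, scale = scale, lower.tail = FALSE),
    lognormal   = stats::plnorm(t, meanlog = shape, sdlog = scale, lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = shape, scale = scale, lower.tail = FALSE),
    gompertz    = flexsurv::pgompertz(t, shape = shape, rate = scale, lower.tail = FALSE),
    gamma       = stats::pgamma(t, shape = shape, rate = scale, lower.tail = FALSE)
  ))
  pmin(pmax(s, 0), 1)
}

#' @rdname surv_prob
#' @export
surv_density <- function(model, t) {
  stopifnot(inherits(model, "parametric_survival"))
  check_time(t)
  with(model, switch(family,
    exponential = stats::dexp(t, rate = scale),
    weibull     = stats::dweibull(t, shape = shape, scale = scale),
    lognormal   = stats::dlnorm(t, meanlog = shape, sdlog = scale),
    loglogistic = flexsurv::dllogis(t, shape = shape, scale = scale),
    gompertz    = flexsurv::dgompertz(t, shape = shape, rate = scale),
    gamma       = stats::dgamma(t, shape = shape, rate = scale)
  ))
}

#' @rdname surv_prob
#' @export
cum_hazard <- function(model, t) {
  -log(surv_prob(model, t))
}

#' @rdname surv_prob
#' @export
surv_quantile <- function(model, p) {
  stopifnot(inherits(model, "parametric_survival"))
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]", call. = FALSE)
  with(model, switch(family,
    exponential = stats::qexp(p, rate = scale),
    weibull     = stats::qweibull(p, shape = shape, scale = scale),
    lognormal   = stats::qlnorm(p, meanlog = shape, sdlog = scale),
    loglogistic = flexsurv::qllogis(p, shape = shape, scale = scale),
    gompertz    = flexsurv::qgompertz(p, shape = shape, rate = scale),
    gamma       = stats::qgamma(p, shape = shape, rate = scale)
  ))
}

#' Restricted (truncated) mean survival time
#'
#' Numerically integrates \eqn{S(t)} from 0 to `horizon` months.
#'
#' @param model A [parametric_survival()] object.
#' @param horizon Upper integration limit in months.
#' @return Mean survival in months, restricted to `[0, horizon]`.
#' @export
restricted_mean_survival <- function(model, horizon) {
  stopifnot(inherits(model, "parametric_survival"), horizon > 0)
  stats::integrate(function(t) surv_prob(model, t), 0, horizon,
                   rel.tol = 1e-9, subdivisions = 500L)$value
}
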