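#' Model configuration
#'
#' Settings of the cohort state-transition model: cycle length, time horizon,
#' annual discount rate, willingness-to-pay threshold, optional half-cycle
#' correction, and the occupancy construction (`"markov"` builds per-cycle
#' transition matrices from conditional event probabilities; `"partitioned"`
#' reads state occupancy directly off the two survival curves). Both
#' constructions coincide whenever the progression-free curve lies below the
#' overall-survival curve, which holds for the shipped parameter sets.
#'
#' The number of cycles is `floor(horizon_years * 365.25 / cycle_days)`
#' (130 for the default 10-year horizon of 28-day cycles).
#'
#' The discount rate must lie in `[0, 0.08]` — the range spanned by the
#' one-way sensitivity analysis — unless `allow_extended = TRUE`.
#'
#' @param cycle_days Cycle length in days (default 28).
#' @param horizon_years Simulation horizon in years (default 10).
#' @param annual_discount Annual discount rate (default 0.05).
#' @param wtp Willingness-to-pay threshold in CNY per QALY (default 268200,
#'   three times 2023 Chinese per-capita GDP).
#' @param half_cycle_correction Logical; weight first and last cycle by 0.5
#'   in accrual (default `FALSE`).
#' @param transition_mode `"markov"` (default) or `"partitioned"`.
#' @param allow_extended Allow discount rates outside `[0, 0.08]`.
#' @return An object of class `model_config`.
#' @export
model_config <- function(cycle_days = 28, horizon_years = 10,
                         annual_discount = 0.05, wtp = 268200,
                         half_cycle_correction = FALSE,
                         transition_mode = c("markov", "partitioned"),
                         allow_extended = FALSE) {
  transition_mode <- match.arg(transition_mode)
  if (cycle_days <= 0 || horizon_years <= 0) {
    stop("'cycle_days' and 'horizon_years' must be positive", call. = FALSE)
  }
  if (!allow_extended && (annual_discount < 0 || annual_discount > 0.08)) {
    stop("'annual_discount' must lie in [0, 0.08] (set allow_extended = TRUE to override)",
         call. = FALSE)
  }
  if (wtp < 0) stop("'wtp' must be non-negative", call. = FALSE)
  structure(
    list(cycle_days = cycle_days, horizon_years = horizon_years,
         annual_discount = annual_discount, wtp = wtp,
         half_cycle_correction = isTRUE(half_cycle_correction),
         transition_mode = transition_mode,
         allow_extended = isTRUE(allow_extended)),
    class = "model_config"
  )
}

DAYS_PER_MONTH <- 30.4375

#' @rdname model_config
#' @param config A `model_config`.
#' @export
n_cycles <- function(config) {
  stopifnot(inherits(config, "model_config"))
  # tiny epsilon so an exact integer number of cycles is not floored away
  as.integer(floor(config$horizon_years * 365.25 / config$cycle_days + 1e-9))
}

# cycle length in months
cycle_months <- function(config) config$cycle_days / DAYS_PER_MONTH

# cycle length in years
cycle_years <- function(config) config$cycle_days / 365.25

#' Conditional event probability over one cycle
#'
#' The probability of the event occurring in the interval `(t - u, t]` given
#' survival to `t - u`: \eqn{1 - S(t)/S(t-u)}. This is the per-cycle
#' transition probability implied by a fitted survival curve. Note that the
#' conditional survival ratio itself, \eqn{S(t)/S(t-u)}, is the probability of
#' *remaining* event-free over the cycle — the event probability is its
#' complement.
#'
#' When the curve is numerically exhausted (`S(t - u) = 0`) the cohort has no
#' survivors to transition, and the function returns 1 with a warning.
#'
#' @param model A [parametric_survival()] object.
#' @param t Cycle-end time in months.
#' @param u Cycle width in months, `0 < u <= t`.
#' @return Probability in `[0, 1]`; equals `1 - S(u)` when `t == u`.
#' @export
conditional_event_prob <- function(model, t, u) {
  if (any(u <= 0) || any(t < u)) stop("need t >= u > 0", call. = FALSE)
  s_prev <- surv_prob(model, t - u)
  s_now <- surv_prob(model, t)
  exhausted <- s_prev <= 0
  if (any(exhausted)) {
    warning("survival exhausted (S(t-u) = 0); returning event probability 1")
  }
  p <- rep(1, length(s_now))
  p[!exhausted] <- 1 - s_now[!exhausted] / s_prev[!exhausted]
  pmin(pmax(p, 0), 1)
}

#' Per-cycle transition matrix
#'
#' Builds the 3x3 row-stochastic matrix for cycle `c` over states
#' (PFS, PD, dead). The per-cycle death probability `p_death` comes from the
#' overall-survival curve and applies equally from PFS and PD; the
#' progression probability is the excess of the PFS-exit probability over
#' death, floored at zero:
#' `p(PFS -> PD) = max(0, p_exit_pfs - p_death)`. Death is absorbing.
#'
#' @param cycle Cycle index `>= 1` (transitions happen from cycle `c - 1`
#'   to `c`; times are evaluated at cycle ends).
#' @param config A [model_config()].
#' @param os_model,pfs_model Fitted [parametric_survival()] curves.
#' @return A 3x3 matrix with dimnames `c("pfs", "pd", "dead")`.
#' @export
transition_matrix <- function(cycle, config, os_model, pfs_model) {
  stopifnot(inherits(config, "model_config"), cycle >= 1)
  u <- cycle_months(config)
  t_end <- cycle * u
  p_death <- conditional_event_prob(os_model, t_end, u)
  p_exit <- conditional_event_prob(pfs_model, t_end, u)
  p_prog <- max(0, p_exit - p_death)
  m <- rbind(
    pfs  = c(1 - p_prog - p_death, p_prog, p_death),
    pd   = c(0, 1 - p_death, p_death),
    dead = c(0, 0, 1)
  )
  colnames(m) <- rownames(m)
  if (any(m < -1e-12) || any(m > 1 + 1e-12)) {
    stop("internal consistency error: transition probability outside [0, 1]",
         call. = FALSE)
  }
  m[] <- pmin(pmax(m, 0), 1)
  m
}

#' Build the cohort trace
#'
#' Simulates the whole cohort, starting entirely in the progression-free
#' state, over `n_cycles(config)` cycles. In `"markov"` mode memberships
#' evolve by the per-cycle [transition_matrix()]; in `"partitioned"` mode they
#' are read directly off the curves
#' (`pfs = S_PFS`, `dead = 1 - S_OS`, `pd = max(0, S_OS - S_PFS)`).
#'
#' If the progressed-state occupancy has to be floored at zero (progression-
#' free curve above overall survival) in more than 5% of cycles, a warning
#' flags the curve-crossing pathology; the trace is still returned.
#'
#' @param config A [model_config()].
#' @param os_model,pfs_model Fitted [parametric_survival()] curves.
#' @return A data frame of class `cohort_trace` with one row per cycle
#'   (including cycle 0): `cycle`, `t_months`, `pfs`, `pd`, `dead`,
#'   `new_deaths` (probability mass entering death that cycle).
#' @export
build_trace <- function(config, os_model, pfs_model) {
  stopifnot(inherits(config, "model_config"),
            inherits(os_model, "parametric_survival"),
            inherits(pfs_model, "parametric_survival"))
  nc <- n_cycles(config)
  u <- cycle_months(config)
  t_months <- (0:nc) * u
  clamped <- 0L
  if (config$transition_mode == "partitioned") {
    s_os <- surv_prob(os_model, t_months)
    s_pfs <- surv_prob(pfs_model, t_months)
    pfs <- s_pfs
    dead <- 1 - s_os
    pd_raw <- s_os - s_pfs
    clamped <- sum(pd_raw < -1e-12)
    pd <- pmax(0, pd_raw)
    # flooring pd redistributes the (small) negative mass into pfs so that
    # occupancies still sum to one
    pfs <- 1 - dead - pd
  } else {
    pfs <- pd <- dead <- numeric(nc + 1L)
    pfs[1L] <- 1
    state <- c(1, 0, 0)
    for (cc in seq_len(nc)) {
      m <- transition_matrix(cc, config, os_model, pfs_model)
      if (m["pfs", "pd"] == 0) {
        p_exit <- conditional_event_prob(pfs_model, cc * u, u)
        p_death <- conditional_event_prob(os_model, cc * u, u)
        if (p_exit < p_death - 1e-12) clamped <- clamped + 1L
      }
      state <- as.vector(state %*% m)
      pfs[cc + 1L] <- state[1L]
      pd[cc + 1L] <- state[2L]
      dead[cc + 1L] <- state[3L]
    }
  }
  if (clamped > 0.05 * nc) {
    warning(sprintf(
      "progressed-state occupancy floored at zero in %d of %d cycles: PFS curve exceeds OS curve (curve-crossing pathology)",
      clamped, nc))
  }
  structure(
    data.frame(cycle = 0:nc, t_months = t_months, pfs = pfs, pd = pd,
               dead = dead, new_deaths = c(dead[1L], diff(dead))),
    class = c("cohort_trace", "data.frame")
  )
}

#' Write a cohort trace as CSV
#'
#' Columns: `cycle,t_months,pfs,pd,dead,new_deaths`.
#'
#' @param trace A `cohort_trace`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
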