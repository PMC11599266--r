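#' Digitized Kaplan-Meier curve
#'
#' Holds coordinates read off a published Kaplan-Meier plot: a sequence of
#' (time, survival) points, optionally accompanied by a numbers-at-risk table.
#' Validation rejects physically impossible digitizations: non-increasing
#' times, survival outside `[0, 1]`, survival that rises between points, or a
#' first point that does not start near (0, 1) — the first point must have
#' survival in `[0.98, 1]` at time `<= 0.5` months, otherwise the digitization
#' missed the origin.
#'
#' @param time Numeric vector of strictly increasing times (months, `>= 0`).
#' @param survival Numeric vector of survival probabilities, non-increasing.
#' @param arm Text label for the treatment arm.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param at_risk Optional data frame with columns `time` and `n_risk`
#'   (numbers at risk at given times).
#' @return An object of class `digitized_curve`.
#' @export
digitized_curve <- function(time, survival, arm = "", endpoint = c("OS", "PFS"),
                            at_risk = NULL) {
  endpoint <- match.arg(endpoint)
  time <- as.numeric(time)
  survival <- as.numeric(survival)
  if (length(time) != length(survival) || length(time) < 2L) {
    stop("need >= 2 (time, survival) points of equal length", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("times must be finite and >= 0", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    i <- which(diff(time) <= 0)[1L] + 1L
    stop(sprintf("times must be strictly increasing; point %d (t = %g) violates this",
                 i, time[i]), call. = FALSE)
  }
  if (any(survival < 0 | survival > 1)) {
    i <- which(survival < 0 | survival > 1)[1L]
    stop(sprintf("survival must lie in [0, 1]; point %d (S = %g) violates this",
                 i, survival[i]), call. = FALSE)
  }
  if (any(diff(survival) > 0)) {
    i <- which(diff(survival) > 0)[1L] + 1L
    stop(sprintf("survival must be non-increasing; point %d (t = %g, S = %g) rises above the previous point",
                 i, time[i], survival[i]), call. = FALSE)
  }
  if (survival[1L] < 0.98 || time[1L] > 0.5) {
    stop(sprintf(paste0("first point (t = %g, S = %g) must have survival in ",
                        "[0.98, 1] at time <= 0.5: curve appears mis-digitized"),
                 time[1L], survival[1L]), call. = FALSE)
  }
  if (!is.null(at_risk)) {
    at_risk <- as.data.frame(at_risk)
    if (!all(c("time", "n_risk") %in% names(at_risk))) {
      stop("'at_risk' needs columns 'time' and 'n_risk'", call. = FALSE)
    }
    if (any(diff(at_risk$time) <= 0) || any(at_risk$n_risk < 0) ||
        any(diff(at_risk$n_risk) > 0)) {
      stop("'at_risk' must have strictly increasing times and non-increasing, non-negative counts",
           call. = FALSE)
    }
  }
  structure(
    list(arm = arm, endpoint = endpoint,
         points = data.frame(time = time, survival = survival),
         at_risk = at_risk),
    class = "digitized_curve"
  )
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat(sprintf("<digitized_curve> %s %s: %d points over [%g, %g] months%s\n",
              x$arm, x$endpoint, nrow(x$points), min(x$points$time),
              max(x$points$time),
              if (is.null(x$at_risk)) "" else " (+ at-risk table)"))
  invisible(x)
}

#' Read/write digitized curves as CSV
#'
#' The curve dialect has header `time_months,survival`; the optional at-risk
#' sidecar has header `time_months,n_risk`.
#'
#' @param path Curve CSV path.
#' @param at_risk_path Optional at-risk sidecar CSV path.
#' @param arm,endpoint Labels passed to [digitized_curve()].
#' @param curve A [digitized_curve()] (for writing).
#' @return `read_digitized_curve` returns a [digitized_curve()];
#'   `write_digitized_curve` returns `path` invisibly.
#' @export
read_digitized_curve <- function(path, at_risk_path = NULL, arm = "",
                                 endpoint = c("OS", "PFS")) {
  df <- utils::read.csv(path)
  if (!all(c("time_months", "survival") %in% names(df))) {
    stop("curve CSV must have columns 'time_months' and 'survival'", call. = FALSE)
  }
  at_risk <- NULL
  if (!is.null(at_risk_path)) {
    ar <- utils::read.csv(at_risk_path)
    if (!all(c("time_months", "n_risk") %in% names(ar))) {
      stop("at-risk CSV must have columns 'time_months' and 'n_risk'", call. = FALSE)
    }
    at_risk <- data.frame(time = ar$time_months, n_risk = ar$n_risk)
  }
  digitized_curve(df$time_months, df$survival, arm = arm, endpoint = endpoint,
                  at_risk = at_risk)
}

#' @rdname read_digitized_curve
#' @export
write_digitized_curve <- function(curve, path, at_risk_path = NULL) {
  stopifnot(inherits(curve, "digitized_curve"))
  utils::write.csv(
    data.frame(time_months = curve$points$time, survival = curve$points$survival),
    path, row.names = FALSE, quote = FALSE
  )
  if (!is.null(at_risk_path) && !is.null(curve$at_risk)) {
    utils::write.csv(
      data.frame(time_months = curve$at_risk$time, n_risk = curve$at_risk$n_risk),
      at_risk_path, row.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}

# n at risk at each curve time, from the sidecar table (step interpolation);
# NA beyond the table's last reporting time, where the balance is unknown
at_risk_at <- function(at_risk, times, total_n) {
  f <- stats::stepfun(at_risk$time, c(total_n, at_risk$n_risk), right = FALSE)
  v <- f(times)
  v[times > max(at_risk$time)] <- NA_real_
  v
}

#' Allocate events and censorings to inter-point intervals
#'
#' The bookkeeping core of pseudo-IPD reconstruction. For each interval
#' between adjacent digitized points, the number of events is inferred from
#' the relative survival drop applied to the current at-risk count, and
#' censorings from the at-risk balance
#' `censored = n_risk(start) - n_risk(end) - events` when an at-risk table is
#' available (the standard published-KM reconstruction balance). Without an
#' at-risk table, censoring is assumed to occur only after the last digitized
#' time (administrative censoring at curve end), so the at-risk count declines
#' by events alone.
#'
#' @param curve A [digitized_curve()] object.
#' @param total_n Total number of patients the curve represents.
#' @return A data frame with one row per interval: `t_start`, `t_end`,
#'   `n_risk` (at interval start), `events`, `censorings`, plus one final row
#'   for the residual mass censored at curve end.
#' @export
interval_event_allocation <- function(curve, total_n) {
  stopifnot(inherits(curve, "digitized_curve"))
  total_n <- as.integer(total_n)
  if (total_n < 10L) stop("'total_n' must be >= 10", call. = FALSE)
  pts <- curve$points
  # anchor at (0, 1) if the digitization starts fractionally later
  if (pts$time[1L] > 0) pts <- rbind(data.frame(time = 0, survival = 1), pts)
  K <- nrow(pts) - 1L
  have_risk <- !is.null(curve$at_risk)
  if (have_risk) {
    n_at <- round(at_risk_at(curve$at_risk, pts$time, total_n))
  }
  out <- data.frame(t_start = pts$time[-(K + 1L)], t_end = pts$time[-1L],
                    n_risk = NA_real_, events = NA_real_, censorings = NA_real_)
  n_run <- total_n
  for (i in seq_len(K)) {
    s0 <- pts$survival[i]; s1 <- pts$survival[i + 1L]
    n_start <- if (have_risk && !is.na(n_at[i])) n_at[i] else n_run
    if (n_start > n_run) n_start <- n_run  # at-risk table cannot exceed remaining mass
    d <- if (s0 <= 0) 0L else as.integer(round(n_start * (1 - s1 / s0)))
    d <- min(max(d, 0L), n_start)
    if (have_risk && !is.na(n_at[i + 1L])) {
      n_end_table <- n_at[i + 1L]
      # when the survival-implied events exceed the at-risk balance the
      # reconstruction honours the survival drop and lets the at-risk count
      # deplete below the table, as long as the conflict is within
      # digitization noise (5 survival points); gross conflicts mean the
      # curve and table contradict each other and are rejected
      overshoot <- d - (n_start - n_end_table)
      if (overshoot > 0) {
        gap <- if (n_start > 0) overshoot / n_start * s0 else 0
        if (gap > 0.05) {
          stop(sprintf("infeasible allocation in interval %d [%g, %g]: survival drop exceeds the at-risk balance",
                       i, pts$time[i], pts$time[i + 1L]), call. = FALSE)
        }
      }
      n_end <- min(n_end_table, n_start - d)
      cens <- n_start - n_end - d
      # patients absent from the at-risk table before interval start count as
      # censored within the interval
      cens <- cens + (n_run - n_start)
    } else {
      cens <- 0L
    }
    if (d + cens > n_run) {
      stop(sprintf("infeasible allocation in interval %d: %d events + %d censorings exceed %d at risk",
                   i, d, cens, n_run), call. = FALSE)
    }
    out$n_risk[i] <- n_start
    out$events[i] <- d
    out$censorings[i] <- cens
    n_run <- n_run - d - cens
  }
  # residual mass is censored at the last digitized time
  out <- rbind(out, data.frame(t_start = pts$time[K + 1L], t_end = pts$time[K + 1L],
                               n_risk = n_run, events = 0, censorings = n_run))
  out
}

#' Reconstruct pseudo individual-patient data from a digitized curve
#'
#' Converts digitized Kaplan-Meier coordinates into `total_n` event/censoring
#' records whose own Kaplan-Meier estimate tracks the input curve (within
#' about 0.02 absolute at the input time points; integer rounding makes exact
#' agreement impossible). Event counts per interval come from
#' [interval_event_allocation()]. Within an interval, event times are placed
#' by linear interpolation of the survival drop by default (evenly spaced
#' across the interval), or all at the interval midpoint with
#' `event_placement = "midpoint"`; censorings are spread evenly within their
#' interval.
#'
#' @param curve A [digitized_curve()] object.
#' @param total_n Total number of patients (`>= 10`).
#' @param event_placement `"interpolate"` (default) or `"midpoint"`.
#' @return A [pseudo_ipd()] with exactly `total_n` records.
#' @export
reconstruct_ipd <- function(curve, total_n,
                            event_placement = c("interpolate", "midpoint")) {
  event_placement <- match.arg(event_placement)
  alloc <- interval_event_allocation(curve, total_n)
  times <- numeric(0)
  events <- integer(0)
  for (i in seq_len(nrow(alloc))) {
    a <- alloc[i, ]
    if (a$events > 0) {
      et <- if (event_placement == "interpolate") {
        a$t_start + (seq_len(a$events) - 0.5) / a$events * (a$t_end - a$t_start)
      } else {
        rep((a$t_start + a$t_end) / 2, a$events)
      }
      times <- c(times, et)
      events <- c(events, rep(1L, a$events))
    }
    if (a$censorings > 0) {
      ct <- if (a$t_end > a$t_start) {
        a$t_start + (seq_len(a$censorings) - 0.5) / a$censorings * (a$t_end - a$t_start)
      } else {
        rep(a$t_end, a$censorings)
      }
      times <- c(times, ct)
      events <- c(events, rep(0L, a$censorings))
    }
  }
  # guard against zero times when the first interval starts at 0
  times <- pmax(times, 1e-6)
  pseudo_ipd(times, events)
}
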