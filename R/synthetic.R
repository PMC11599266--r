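#' Simulate individual patient data from a parametric survival model
#'
#' Event times are drawn by inverse-transform sampling from the family's
#' quantile function. Censoring has two components: a random-withdrawal
#' component (each subject is, with probability `censoring_rate`, assigned a
#' dropout time uniform on `[0, t_max]`) and an administrative component
#' (everyone still under observation at `t_max` is censored there). With
#' `censoring_rate = 0` and `t_max = Inf` every record is an event.
#'
#' @param model A [parametric_survival()] object (truth).
#' @param n Number of subjects.
#' @param censoring_rate Probability of random withdrawal, in `[0, 1)`.
#' @param t_max Administrative censoring time in months (`Inf` to disable);
#'   must be finite when `censoring_rate > 0`.
#' @param seed Optional integer seed (set for reproducibility).
#' @return A [pseudo_ipd()].
#' @export
simulate_ipd <- function(model, n, censoring_rate = 0, t_max = Inf, seed = NULL) {
  stopifnot(inherits(model, "parametric_survival"), n >= 1)
  if (censoring_rate < 0 || censoring_rate >= 1) {
    stop("'censoring_rate' must lie in [0, 1)", call. = FALSE)
  }
  if (censoring_rate > 0 && !is.finite(t_max)) {
    stop("'t_max' must be finite when 'censoring_rate' > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  t_event <- surv_quantile(model, stats::runif(n))
  c_admin <- rep(t_max, n)
  dropout <- stats::runif(n) < censoring_rate
  c_drop <- ifelse(dropout, stats::runif(n, 0, t_max), Inf)
  c_all <- pmin(c_admin, c_drop)
  time <- pmin(t_event, c_all)
  event <- as.integer(t_event <= c_all)
  time <- pmax(time, 1e-9)  # guard against zero event times from p ~ 0 draws
  if (sum(event) < 1L) {
    stop("simulation produced no events; lower the censoring", call. = FALSE)
  }
  pseudo_ipd(time, event)
}

#' Kaplan-Meier step curve of a pseudo-IPD dataset
#'
#' Product-limit estimate via [survival::survfit()], returned as a
#' [digitized_curve()] anchored at (0, 1), with the numbers-at-risk at each
#' step time attached as the at-risk table.
#'
#' @param data A [pseudo_ipd()] with at least one event.
#' @param arm,endpoint Labels for the resulting curve.
#' @return A [digitized_curve()].
#' @export
km_step <- function(data, arm = "", endpoint = c("OS", "PFS")) {
  stopifnot(inherits(data, "pseudo_ipd"))
  endpoint <- match.arg(endpoint)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(data))
  keep <- fit$n.event > 0 | fit$n.censor > 0
  tt <- c(0, fit$time[keep])
  ss <- c(1, fit$surv[keep])
  nr <- c(fit$n, fit$n.risk[keep])
  digitized_curve(tt, ss, arm = arm, endpoint = endpoint,
                  at_risk = data.frame(time = tt, n_risk = nr))
}

#' Emulate graph digitization of a survival curve
#'
#' Reads the step curve at `n_points` evenly spaced times across its span
#' (as a human digitizer picking a regular grid would), adds truncated
#' Gaussian reading error of sd `jitter_sd` to the survival values, then
#' restores monotonicity by isotonic clipping (running minimum). The origin
#' point (0, 1) is kept exact — digitizers anchor on the axis intersection.
#' The at-risk table, if present, is subsampled at the same times.
#'
#' @param curve A [digitized_curve()] (typically from [km_step()]).
#' @param n_points Number of points to keep (`>= 5`).
#' @param jitter_sd Standard deviation of the reading error on the survival
#'   axis (probability units); 0 gives an exact subsample.
#' @param seed Optional integer seed.
#' @return A [digitized_curve()] satisfying all curve invariants.
#' @export
digitize <- function(curve, n_points, jitter_sd = 0, seed = NULL) {
  stopifnot(inherits(curve, "digitized_curve"), n_points >= 5)
  if (!is.null(seed)) set.seed(as.integer(seed))
  pts <- curve$points
  grid <- seq(min(pts$time), max(pts$time), length.out = n_points)
  sf <- stats::stepfun(pts$time[-1L], pts$survival, right = FALSE)
  s <- sf(grid)
  if (jitter_sd > 0) {
    noise <- stats::rnorm(n_points, 0, jitter_sd)
    noise <- pmin(pmax(noise, -3 * jitter_sd), 3 * jitter_sd)
    s <- pmin(pmax(s + noise, 0), 1)
  }
  s[1L] <- pts$survival[1L]  # keep the anchor exact
  s <- cummin(s)
  at_risk <- NULL
  if (!is.null(curve$at_risk)) {
    rf <- stats::stepfun(curve$at_risk$time[-1L], curve$at_risk$n_risk,
                         right = FALSE)
    at_risk <- data.frame(time = grid, n_risk = rf(grid))
  }
  digitized_curve(grid, s, arm = curve$arm, endpoint = curve$endpoint,
                  at_risk = at_risk)
}

#' Ground-truth scenarios for end-to-end testing
#'
#' Generates every input the pipeline consumes — per-arm, per-endpoint
#' simulated IPD, Kaplan-Meier curves, digitized coordinate CSVs with at-risk
#' sidecars, and a full model-configuration YAML — from known parametric
#' truth, so that reconstruction, fitting and the downstream economics can be
#' validated against it.
#'
#' Presets:
#' * `"sunlight_like"` — four log-normal truths matching the shipped
#'   fitted-curve parameters (combo PFS meanlog 1.660 sdlog 0.850; combo OS
#'   2.398/0.808; mono PFS 1.110/0.644; mono OS 2.030/0.793), 246 patients
#'   per arm, 5% random withdrawal plus administrative censoring at 12
#'   months (the trial's published follow-up span), 30 digitized points with
#'   reading error sd 0.005.
#' * `"stress_crossing"` — a progression-free curve lying *above* overall
#'   survival early on (log-normal 1.9/0.5 vs 2.030/0.793, crossing near 5.4
#'   months), to exercise the occupancy clamp.
#' * `"heavy_censoring"` — 50% random withdrawal with administrative
#'   censoring at 9 months.
#'
#' @param preset One of `"sunlight_like"`, `"stress_crossing"`,
#'   `"heavy_censoring"`.
#' @param seed Integer seed (mandatory; all file content is a deterministic
#'   function of preset + seed).
#' @param dir Optional directory; when given, curve CSVs, at-risk sidecars
#'   and a scenario YAML are written there.
#' @return An object of class `scenario`: list with `preset`, `seed`,
#'   `n_per_arm`, `censoring_rate`, `t_max`, `digitization`, `truth` (nested
#'   list `arm -> endpoint -> parametric_survival`), `ipd`, `curves`
#'   (digitized), and `files` (paths, when `dir` was given).
#' @export
make_scenario <- function(preset = c("sunlight_like", "stress_crossing",
                                     "heavy_censoring"),
                          seed, dir = NULL) {
  preset <- match.arg(preset)
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  seed <- as.integer(seed)
  truth <- switch(preset,
    sunlight_like = list(
      combo = list(OS = parametric_survival("lognormal", 2.398, 0.808),
                   PFS = parametric_survival("lognormal", 1.660, 0.850)),
      mono = list(OS = parametric_survival("lognormal", 2.030, 0.793),
                  PFS = parametric_survival("lognormal", 1.110, 0.644))
    ),
    stress_crossing = list(
      combo = list(OS = parametric_survival("lognormal", 2.030, 0.793),
                   PFS = parametric_survival("lognormal", 1.9, 0.5)),
      mono = list(OS = parametric_survival("lognormal", 2.030, 0.793),
                  PFS = parametric_survival("lognormal", 1.110, 0.644))
    ),
    heavy_censoring = list(
      combo = list(OS = parametric_survival("lognormal", 2.398, 0.808),
                   PFS = parametric_survival("lognormal", 1.660, 0.850)),
      mono = list(OS = parametric_survival("lognormal", 2.030, 0.793),
                  PFS = parametric_survival("lognormal", 1.110, 0.644))
    )
  )
  censoring_rate <- switch(preset, heavy_censoring = 0.5, 0.05)
  t_max <- switch(preset, heavy_censoring = 9, 12)
  n_per_arm <- 246L
  digitization <- list(n_points = 30L, jitter_sd = 0.005)
  ipd <- list()
  curves <- list()
  i <- 0L
  for (arm in names(truth)) {
    for (ep in names(truth[[arm]])) {
      i <- i + 1L
      key <- paste(arm, ep, sep = "_")
      ipd[[key]] <- simulate_ipd(truth[[arm]][[ep]], n_per_arm, censoring_rate,
                                 t_max, seed = seed + i)
      km <- km_step(ipd[[key]], arm = arm, endpoint = ep)
      curves[[key]] <- digitize(km, digitization$n_points,
                                digitization$jitter_sd, seed = seed + 100L + i)
    }
  }
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character(0)
    for (key in names(curves)) {
      cp <- file.path(dir, paste0("curve_", key, ".csv"))
      ap <- file.path(dir, paste0("at_risk_", key, ".csv"))
      write_digitized_curve(curves[[key]], cp, ap)
      files <- c(files, cp, ap)
    }
    cfg_path <- file.path(dir, "scenario.yaml")
    cfg <- default_config_list()
    for (arm_i in seq_along(cfg$strategies)) {
      arm <- if (arm_i == 1L) "combo" else "mono"
      for (ep in c("os", "pfs")) {
        m <- truth[[arm]][[toupper(ep)]]
        cfg$strategies[[arm_i]]$survival[[ep]] <-
          list(family = m$family, shape = m$shape, scale = m$scale)
      }
    }
    cfg$scenario <- list(preset = preset, seed = seed, n_per_arm = n_per_arm,
                         censoring_rate = censoring_rate, t_max = t_max,
                         digitization = digitization)
    yaml::write_yaml(cfg, cfg_path, precision = 12)
    files <- c(files, cfg_path)
  }
  structure(
    list(preset = preset, seed = seed, n_per_arm = n_per_arm,
         censoring_rate = censoring_rate, t_max = t_max,
         digitization = digitization, truth = truth, ipd = ipd,
         curves = curves, files = files),
    class = "scenario"
  )
}
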