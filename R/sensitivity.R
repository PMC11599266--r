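#' Sensitivity-analysis parameter specification
#'
#' One uncertain model input: its baseline, its one-way range `[low, high]`
#' and its probabilistic distribution. Costs use a gamma distribution,
#' utilities and the discount rate a beta distribution on their bounded
#' support, and `"fixed"` parameters never vary.
#'
#' Both distributions are parameterized by the method of moments with
#' mean = `baseline` and sd = `(high - low) / (2 * 1.96)` (the range is read
#' as a 95% interval). For the beta, moments are matched on the parameter
#' rescaled to its `support` interval; infeasible moments (variance too large
#' for the support) are an error here, at specification time, never at
#' sampling time.
#'
#' @param name Parameter name; must match an override name of
#'   [evaluate_cea()].
#' @param baseline Base-case value.
#' @param low,high One-way range, `low <= baseline <= high`.
#' @param distribution `"gamma"`, `"beta"` or `"fixed"`.
#' @param support Length-2 numeric support for beta parameters
#'   (default `c(0, 1)`; the discount rate uses `c(0, 0.08)`).
#' @return An object of class `param_spec`.
#' @export
param_spec <- function(name, baseline, low = baseline, high = baseline,
                       distribution = c("gamma", "beta", "fixed"),
                       support = c(0, 1)) {
  distribution <- match.arg(distribution)
  if (!(low <= baseline && baseline <= high)) {
    stop(sprintf("'%s': need low <= baseline <= high", name), call. = FALSE)
  }
  spec <- structure(
    list(name = name, baseline = baseline, low = low, high = high,
         distribution = distribution, support = support),
    class = "param_spec"
  )
  if (distribution == "beta") {
    if (baseline < support[1] || baseline > support[2]) {
      stop(sprintf("'%s': baseline outside beta support [%g, %g]", name,
                   support[1], support[2]), call. = FALSE)
    }
    beta_moments(spec)  # errors now if infeasible
  }
  if (distribution == "gamma" && baseline < 0) {
    stop(sprintf("'%s': gamma-distributed parameter must be non-negative", name),
         call. = FALSE)
  }
  spec
}

spec_sd <- function(spec) (spec$high - spec$low) / (2 * 1.96)

beta_moments <- function(spec) {
  width <- spec$support[2] - spec$support[1]
  m <- (spec$baseline - spec$support[1]) / width
  s <- spec_sd(spec) / width
  if (s == 0) return(list(degenerate = TRUE))
  v <- s^2
  if (v >= m * (1 - m)) {
    stop(sprintf("'%s': sd %.4g infeasible for beta on [%g, %g] with mean %.4g",
                 spec$name, spec_sd(spec), spec$support[1], spec$support[2],
                 spec$baseline), call. = FALSE)
  }
  k <- m * (1 - m) / v - 1
  list(degenerate = FALSE, alpha = m * k, beta = (1 - m) * k)
}

#' Draw from a parameter's probabilistic distribution
#'
#' Uses the current RNG state (set the seed upstream, e.g. in [run_psa()]).
#' A degenerate specification (`sd = 0` or `distribution = "fixed"`) always
#' returns the baseline.
#'
#' @param spec A [param_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_parameter <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "param_spec"))
  if (spec$distribution == "fixed" || spec_sd(spec) == 0) {
    return(rep(spec$baseline, n))
  }
  if (spec$distribution == "gamma") {
    m <- spec$baseline; s <- spec_sd(spec)
    if (m <= 0) return(rep(m, n))
    shape <- (m / s)^2
    rate <- m / s^2
    return(stats::rgamma(n, shape = shape, rate = rate))
  }
  mo <- beta_moments(spec)
  if (isTRUE(mo$degenerate)) return(rep(spec$baseline, n))
  spec$support[1] + (spec$support[2] - spec$support[1]) *
    stats::rbeta(n, mo$alpha, mo$beta)
}

#' Default parameter specifications for a pipeline
#'
#' Builds one [param_spec()] per uncertain input: the two drug costs, the
#' five non-drug costs, the distinct adverse-event unit costs (all gamma,
#' range ±20% of baseline unless supplied), the two utilities (beta on
#' `[0, 1]`) and the discount rate (beta on `[0, 0.08]`, one-way range
#' 0 to 0.08).
#'
#' @param pipeline A [cea_pipeline()].
#' @param ranges Optional named list `name -> c(low, high)` overriding the
#'   default ±20% ranges.
#' @return A named list of `param_spec` objects.
#' @export
default_param_specs <- function(pipeline, ranges = list()) {
  stopifnot(inherits(pipeline, "cea_pipeline"))
  rng <- function(name, base, def_lo = 0.8 * base, def_hi = 1.2 * base) {
    if (name %in% names(ranges)) ranges[[name]] else c(def_lo, def_hi)
  }
  specs <- list()
  add <- function(name, base, distribution, support = c(0, 1),
                  def_lo = 0.8 * base, def_hi = 1.2 * base) {
    r <- rng(name, base, def_lo, def_hi)
    specs[[name]] <<- param_spec(name, base, r[1], r[2], distribution, support)
  }
  add(paste0("drug_cost.", pipeline$intervention$name),
      pipeline$intervention$drug_cost_per_cycle, "gamma")
  add(paste0("drug_cost.", pipeline$comparator$name),
      pipeline$comparator$drug_cost_per_cycle, "gamma")
  for (f in c("lab_per_visit", "imaging_per_visit", "supportive_per_cycle",
              "end_of_life_once", "subsequent_tx_per_cycle")) {
    add(f, pipeline$costs[[f]], "gamma")
  }
  ae <- rbind(pipeline$intervention$adverse_events, pipeline$comparator$adverse_events)
  if (nrow(ae)) {
    ae <- ae[!duplicated(ae$name), ]
    for (i in seq_len(nrow(ae))) {
      add(paste0("ae_cost.", ae$name[i]), ae$unit_cost[i], "gamma")
    }
  }
  add("u_pfs", pipeline$utils$u_pfs, "beta")
  add("u_pd", pipeline$utils$u_pd, "beta")
  add("discount", pipeline$config$annual_discount, "beta", support = c(0, 0.08),
      def_lo = 0, def_hi = 0.08)
  specs
}

#' One-way (tornado) sensitivity analysis
#'
#' Re-evaluates the full deterministic model with each parameter set to its
#' low and high value in turn, all others held at baseline, and returns
#' entries sorted by descending ICER spread.
#'
#' @param pipeline A [cea_pipeline()].
#' @param specs A list of [param_spec()] objects (default
#'   [default_param_specs()]).
#' @return A data frame of class `tornado`: `parameter`, `icer_low`
#'   (ICER at the parameter's low value), `icer_high`, `spread`, sorted by
#'   descending `spread`; the base-case ICER is attached as attribute
#'   `base_icer`.
#' @export
one_way <- function(pipeline, specs = default_param_specs(pipeline)) {
  stopifnot(inherits(pipeline, "cea_pipeline"))
  base <- evaluate_cea(pipeline)
  rows <- lapply(specs, function(sp) {
    lo <- evaluate_cea(pipeline, stats::setNames(sp$low, sp$name))
    hi <- evaluate_cea(pipeline, stats::setNames(sp$high, sp$name))
    data.frame(parameter = sp$name, icer_low = lo$icer, icer_high = hi$icer,
               spread = abs(hi$icer - lo$icer))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  class(out) <- c("tornado", "data.frame")
  attr(out, "base_icer") <- base$icer
  out
}

#' Probabilistic sensitivity analysis
#'
#' Monte-Carlo propagation of parameter uncertainty: per draw, every
#' non-fixed parameter is sampled independently from its distribution, the
#' full model is re-evaluated for both arms, and the incremental cost and
#' QALYs are recorded. Draws violating model invariants (a sampled
#' `u_pd > u_pfs`) are resampled; the resample count is reported in the
#' result. Under the shipped utility distributions about 1% of independent
#' draws are invalid, which is expected behaviour; resampling beyond
#' `max_invalid_frac` of `n_sims` (default 2%) is an error, signalling a
#' mis-specified distribution rather than ordinary utility-overlap.
#'
#' Results are reproducible: the same seed and inputs give identical samples.
#'
#' @param pipeline A [cea_pipeline()].
#' @param n_sims Number of Monte-Carlo draws (default 10000).
#' @param seed Integer RNG seed (mandatory).
#' @param specs Parameter specifications (default [default_param_specs()]).
#' @param max_invalid_frac Abort threshold for the invalid-draw resample
#'   count, as a fraction of `n_sims`.
#' @return An object of class `psa_result`: list with `samples` (data frame
#'   `draw`, `d_cost`, `d_qaly`), `base` (the deterministic `cea_result`),
#'   `n_sims`, `seed`, `n_resampled`.
#' @export
run_psa <- function(pipeline, n_sims = 10000L, seed,
                    specs = default_param_specs(pipeline),
                    max_invalid_frac = 0.02) {
  stopifnot(inherits(pipeline, "cea_pipeline"), n_sims >= 1)
  if (missing(seed)) stop("'seed' is mandatory for a reproducible PSA", call. = FALSE)
  set.seed(as.integer(seed))
  base <- evaluate_cea(pipeline)
  nm <- vapply(specs, `[[`, "", "name")
  d_cost <- d_qaly <- numeric(n_sims)
  n_resampled <- 0L
  cap <- max(1L, ceiling(max_invalid_frac * n_sims))
  for (i in seq_len(n_sims)) {
    repeat {
      draw <- vapply(specs, sample_parameter, numeric(1))
      names(draw) <- nm
      res <- tryCatch(evaluate_cea(pipeline, draw), error = function(e) NULL)
      if (!is.null(res)) break
      n_resampled <- n_resampled + 1L
      if (n_resampled > cap) {
        stop(sprintf("more than %d invalid draws (%.0f%% of n_sims): check parameter distributions",
                     cap, 100 * max_invalid_frac), call. = FALSE)
      }
    }
    d_cost[i] <- res$incremental_cost
    d_qaly[i] <- res$incremental_qalys
  }
  structure(
    list(samples = data.frame(draw = seq_len(n_sims), d_cost = d_cost,
                              d_qaly = d_qaly),
         base = base, n_sims = n_sims, seed = as.integer(seed),
         n_resampled = n_resampled),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws (seed %d, %d resampled)\n", x$n_sims,
              x$seed, x$n_resampled))
  cat(sprintf("  mean incremental cost %s, mean incremental QALYs %.4f\n",
              format(round(mean(x$samples$d_cost), 2), big.mark = ","),
              mean(x$samples$d_qaly)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability of cost-effectiveness
#' is the fraction of PSA samples with positive incremental net monetary
#' benefit, \eqn{WTP \cdot \Delta QALY - \Delta cost > 0}.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param wtp_grid Numeric WTP grid (default 0 to 1,000,000 CNY in
#'   5,000-CNY steps).
#' @return A data frame `wtp`, `p_ce`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 1e6, by = 5000)) {
  stopifnot(inherits(psa, "psa_result"), nrow(psa$samples) > 0)
  p <- vapply(wtp_grid, function(w) {
    mean(w * psa$samples$d_qaly - psa$samples$d_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, p_ce = p)
}

#' WTP at which the acceptability curve crosses a probability
#'
#' Linear interpolation of the CEAC at `prob` (default 0.5). Returns `NA`
#' when the curve never crosses.
#'
#' @param ceac_df Data frame from [ceac()].
#' @param prob Target probability.
#' @return WTP value (CNY/QALY) or `NA`.
#' @export
ceac_crossing <- function(ceac_df, prob = 0.5) {
  above <- ceac_df$p_ce >= prob
  if (!any(above) || all(above)) return(NA_real_)
  i <- which(above)[1L]
  if (i == 1L) return(ceac_df$wtp[1L])
  x0 <- ceac_df$wtp[i - 1L]; x1 <- ceac_df$wtp[i]
  y0 <- ceac_df$p_ce[i - 1L]; y1 <- ceac_df$p_ce[i]
  if (y1 == y0) return(x1)
  x0 + (prob - y0) / (y1 - y0) * (x1 - x0)
}

#' Sensitivity-analysis plots
#'
#' `plot_tornado()` draws the ranked one-way bars around the base-case ICER,
#' `plot_ce_plane()` the incremental cost-effectiveness scatter with the WTP
#' line, and `plot_ceac()` the acceptability curve.
#'
#' @param tornado A `tornado` data frame from [one_way()].
#' @param top Number of parameters to show (default all).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top = nrow(tornado)) {
  stopifnot(inherits(tornado, "tornado"))
  df <- utils::head(tornado, top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  base <- attr(tornado, "base_icer")
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low, xend = .data$icer_high,
                                       y = .data$parameter, yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = "ICER (CNY/QALY)", y = NULL,
                  title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_tornado
#' @param psa A `psa_result`.
#' @param wtp WTP threshold for the reference line (default the base
#'   config's).
#' @export
plot_ce_plane <- function(psa, wtp = psa$base$wtp) {
  stopifnot(inherits(psa, "psa_result"))
  ggplot2::ggplot(psa$samples, ggplot2::aes(x = .data$d_qaly, y = .data$d_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6, colour = "steelblue") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (CNY)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' @rdname plot_tornado
#' @param ceac_df Data frame from [ceac()].
#' @export
plot_ceac <- function(ceac_df) {
  ggplot2::ggplot(ceac_df, ggplot2::aes(x = .data$wtp, y = .data$p_ce)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Willingness to pay (CNY/QALY)",
                  y = "P(cost-effective)",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
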