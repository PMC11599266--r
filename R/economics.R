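#' Body surface area (Chinese population linear formula)
#'
#' \eqn{BSA = 0.0061 \cdot height + 0.0124 \cdot weight - 0.0099}, with height
#' in cm, weight in kg, BSA in m². This linear formula is the standard used
#' for chemotherapy dose arithmetic in Chinese pharmacoeconomic practice.
#'
#' @param height_cm Height in cm, `> 0`.
#' @param weight_kg Weight in kg, `> 0`.
#' @return Body surface area in m².
#' @examples
#' body_surface_area(164.09, 64.52)  # 1.79 m^2
#' @export
body_surface_area <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0) || any(weight_kg <= 0)) {
    stop("height and weight must be positive", call. = FALSE)
  }
  0.0061 * height_cm + 0.0124 * weight_kg - 0.0099
}

#' Sex-weighted average of a patient characteristic
#'
#' Weighted mean of a male and a female value with the trial's sex counts as
#' weights, e.g. average height/weight of the modelled cohort.
#'
#' @param male_val,female_val Characteristic value for males / females.
#' @param n_male,n_female Counts, with `n_male + n_female > 0`.
#' @return The weighted mean.
#' @examples
#' weighted_patient_profile(169.70, 158.00, 256, 236)  # 164.09 cm
#' @export
weighted_patient_profile <- function(male_val, female_val, n_male, n_female) {
  if (n_male < 0 || n_female < 0 || n_male + n_female <= 0) {
    stop("counts must be non-negative with a positive total", call. = FALSE)
  }
  (male_val * n_male + female_val * n_female) / (n_male + n_female)
}

#' Per-cycle discount factor
#'
#' \eqn{(1 + r)^{-t}} with `t` the cycle-end time in years
#' (`cycle * cycle_days / 365.25`).
#'
#' @param cycle Cycle index (vectorized), `>= 0`.
#' @param config A [model_config()].
#' @return Discount factor(s) in `(0, 1]`.
#' @export
discount_factor <- function(cycle, config) {
  stopifnot(inherits(config, "model_config"))
  if (any(cycle < 0)) stop("'cycle' must be >= 0", call. = FALSE)
  (1 + config$annual_discount)^(-(cycle * config$cycle_days / 365.25))
}

#' Strategy inputs
#'
#' One treatment arm: its per-cycle drug acquisition cost, its adverse-event
#' profile (per-patient incidences and per-event management costs), and its
#' fitted overall-survival and progression-free-survival curves.
#'
#' @param name Arm label.
#' @param drug_cost_per_cycle Drug cost per model cycle, CNY.
#' @param os_model,pfs_model [parametric_survival()] curves.
#' @param adverse_events Data frame with columns `name`, `incidence`
#'   (in `[0, 1]`) and `unit_cost` (CNY per event); may have zero rows.
#' @return An object of class `strategy_inputs`.
#' @export
strategy_inputs <- function(name, drug_cost_per_cycle, os_model, pfs_model,
                            adverse_events = data.frame(name = character(),
                                                        incidence = numeric(),
                                                        unit_cost = numeric())) {
  stopifnot(inherits(os_model, "parametric_survival"),
            inherits(pfs_model, "parametric_survival"))
  adverse_events <- as.data.frame(adverse_events)
  if (!all(c("name", "incidence", "unit_cost") %in% names(adverse_events))) {
    stop("'adverse_events' needs columns name, incidence, unit_cost", call. = FALSE)
  }
  if (drug_cost_per_cycle < 0 || any(adverse_events$unit_cost < 0)) {
    stop("costs must be non-negative", call. = FALSE)
  }
  if (any(adverse_events$incidence < 0 | adverse_events$incidence > 1)) {
    stop("adverse-event incidences must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(name = name, drug_cost_per_cycle = drug_cost_per_cycle,
         adverse_events = adverse_events,
         os_model = os_model, pfs_model = pfs_model),
    class = "strategy_inputs"
  )
}

#' Non-drug cost inputs
#'
#' Follow-up, supportive-care, end-of-life and subsequent-treatment unit
#' costs (CNY). Defaults are the shipped Chinese healthcare-system values.
#'
#' @param lab_per_visit Laboratory tests per follow-up visit.
#' @param imaging_per_visit Imaging per follow-up visit.
#' @param supportive_per_cycle Supportive treatment per cycle in the
#'   progressed state.
#' @param end_of_life_once One-time end-of-life care cost, charged to the
#'   mass entering the death state.
#' @param subsequent_tx_per_cycle Subsequent-line treatment per cycle in the
#'   progressed state.
#' @return An object of class `cost_inputs`.
#' @export
cost_inputs <- function(lab_per_visit = 317.36, imaging_per_visit = 677.70,
                        supportive_per_cycle = 2141.20,
                        end_of_life_once = 11299.00,
                        subsequent_tx_per_cycle = 7541.10) {
  vals <- c(lab_per_visit, imaging_per_visit, supportive_per_cycle,
            end_of_life_once, subsequent_tx_per_cycle)
  if (any(vals < 0)) stop("all costs must be non-negative", call. = FALSE)
  structure(
    list(lab_per_visit = lab_per_visit, imaging_per_visit = imaging_per_visit,
         supportive_per_cycle = supportive_per_cycle,
         end_of_life_once = end_of_life_once,
         subsequent_tx_per_cycle = subsequent_tx_per_cycle),
    class = "cost_inputs"
  )
}

#' Health-state utilities
#'
#' Utility weights for the progression-free and progressed states
#' (dead is fixed at 0). Must satisfy `0 <= u_pd <= u_pfs <= 1`.
#'
#' @param u_pfs Progression-free utility (default 0.84).
#' @param u_pd Progressed-disease utility (default 0.57).
#' @return An object of class `utilities`.
#' @export
utilities <- function(u_pfs = 0.84, u_pd = 0.57) {
  if (u_pd < 0 || u_pfs > 1 || u_pd > u_pfs) {
    stop("utilities must satisfy 0 <= u_pd <= u_pfs <= 1", call. = FALSE)
  }
  structure(list(u_pfs = u_pfs, u_pd = u_pd, u_dead = 0), class = "utilities")
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Per cycle `c` (cycle ends, including cycle 0 at model entry):
#' \deqn{cost(c) = pfs(c)(drug + lab + imaging) + pd(c)(subsequent + supportive)
#'   + newdeaths(c) \cdot endoflife}
#' \deqn{QALY(c) = (pfs(c) u_{pfs} + pd(c) u_{pd}) \cdot cycleyears}
#' both multiplied by the per-cycle [discount_factor()] and summed. An
#' expected adverse-event management cost
#' (\eqn{\sum incidence \cdot unitcost}) is charged once, undiscounted, at
#' model entry. Drug and follow-up costs accrue only while progression-free
#' (treatment until progression); subsequent-treatment and supportive costs
#' accrue every progressed cycle.
#'
#' With `half_cycle_correction = TRUE`, state-occupancy terms at the first
#' and last cycle get weight 0.5 (the one-time entry and death-entry costs are
#' flows, not stocks, and are never half-weighted).
#'
#' @param trace A `cohort_trace` from [build_trace()].
#' @param strategy A [strategy_inputs()].
#' @param costs A [cost_inputs()].
#' @param utils A [utilities()].
#' @param config The same [model_config()] used to build the trace.
#' @return A list with `name`, `cost` and `qalys` (both discounted totals),
#'   of class `strategy_result`.
#' @export
accrue <- function(trace, strategy, costs, utils, config) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(strategy, "strategy_inputs"),
            inherits(costs, "cost_inputs"), inherits(utils, "utilities"),
            inherits(config, "model_config"))
  if (nrow(trace) != n_cycles(config) + 1L) {
    stop("trace length does not match the configured cycle count", call. = FALSE)
  }
  df <- discount_factor(trace$cycle, config)
  w <- rep(1, nrow(trace))
  if (config$half_cycle_correction) {
    w[1L] <- 0.5
    w[length(w)] <- 0.5
  }
  pfs_cost <- strategy$drug_cost_per_cycle + costs$lab_per_visit + costs$imaging_per_visit
  pd_cost <- costs$subsequent_tx_per_cycle + costs$supportive_per_cycle
  ae_lump <- sum(strategy$adverse_events$incidence * strategy$adverse_events$unit_cost)
  state_cost <- trace$pfs * pfs_cost + trace$pd * pd_cost
  eol_cost <- trace$new_deaths * costs$end_of_life_once
  total_cost <- ae_lump + sum(df * (w * state_cost + eol_cost))
  qaly_cycle <- (trace$pfs * utils$u_pfs + trace$pd * utils$u_pd) * cycle_years(config)
  total_qalys <- sum(df * w * qaly_cycle)
  structure(list(name = strategy$name, cost = total_cost, qalys = total_qalys),
            class = "strategy_result")
}

#' Compare two strategies: increments, ICER, NMB and verdict
#'
#' Increments are computed as intervention minus comparator. When the
#' incremental QALYs are positive the ICER is the incremental cost per
#' incremental QALY; when the signs disagree the ICER is replaced by a
#' dominance flag (`"dominant"`: cheaper and more effective; `"dominated"`:
#' costlier and less effective; `"equivalent"`: no difference). The net
#' monetary benefit is \eqn{NMB = WTP \cdot \Delta QALY - \Delta cost}. The
#' verdict applies the usual decision rule: the intervention is
#' cost-effective iff its ICER is at or below the willingness-to-pay
#' threshold (or it dominates).
#'
#' @param intervention,comparator `strategy_result` objects from [accrue()].
#' @param config A [model_config()] (supplies the WTP threshold).
#' @return An object of class `cea_result`: list with per-strategy totals,
#'   `incremental_cost`, `incremental_qalys`, `icer` (`NA` when a dominance
#'   flag applies), `dominance` (`"none"`, `"dominant"`, `"dominated"`,
#'   `"equivalent"`), `nmb`, `wtp`, `cost_effective` (logical) and `verdict`
#'   (text).
#' @export
compare_strategies <- function(intervention, comparator, config) {
  stopifnot(inherits(intervention, "strategy_result"),
            inherits(comparator, "strategy_result"),
            inherits(config, "model_config"))
  d_cost <- intervention$cost - comparator$cost
  d_qaly <- intervention$qalys - comparator$qalys
  nmb <- config$wtp * d_qaly - d_cost
  tol <- 1e-9
  if (abs(d_cost) < tol && abs(d_qaly) < tol) {
    dominance <- "equivalent"; icer <- NA_real_; ce <- TRUE
  } else if (d_qaly > 0 && d_cost <= 0) {
    dominance <- "dominant"; icer <- NA_real_; ce <- TRUE
  } else if (d_qaly <= 0 && d_cost >= 0) {
    dominance <- "dominated"; icer <- NA_real_; ce <- FALSE
  } else if (d_qaly > 0) {
    dominance <- "none"; icer <- d_cost / d_qaly; ce <- icer <= config$wtp
  } else {
    # cheaper but less effective: ICER is a saving per QALY forgone;
    # cost-effective iff the saving per QALY forgone exceeds WTP
    dominance <- "none"; icer <- d_cost / d_qaly; ce <- icer > config$wtp
  }
  verdict <- if (dominance == "equivalent") {
    "strategies are equivalent"
  } else if (ce) {
    sprintf("'%s' is cost-effective vs '%s' at WTP %s/QALY",
            intervention$name, comparator$name, format(config$wtp, big.mark = ","))
  } else {
    sprintf("'%s' is not cost-effective vs '%s' at WTP %s/QALY",
            intervention$name, comparator$name, format(config$wtp, big.mark = ","))
  }
  structure(
    list(intervention = intervention, comparator = comparator,
         incremental_cost = d_cost, incremental_qalys = d_qaly,
         icer = icer, dominance = dominance, nmb = nmb, wtp = config$wtp,
         cost_effective = ce, verdict = verdict),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  cat(sprintf("  %-28s cost %14s  QALYs %6.3f\n", x$intervention$name,
              format(round(x$intervention$cost, 2), big.mark = ","),
              x$intervention$qalys))
  cat(sprintf("  %-28s cost %14s  QALYs %6.3f\n", x$comparator$name,
              format(round(x$comparator$cost, 2), big.mark = ","),
              x$comparator$qalys))
  cat(sprintf("  incremental: cost %s, QALYs %.3f\n",
              format(round(x$incremental_cost, 2), big.mark = ","),
              x$incremental_qalys))
  if (x$dominance == "none") {
    cat(sprintf("  ICER %s/QALY; NMB %s\n",
                format(round(x$icer, 2), big.mark = ","),
                format(round(x$nmb, 2), big.mark = ",")))
  } else {
    cat(sprintf("  dominance: %s; NMB %s\n", x$dominance,
                format(round(x$nmb, 2), big.mark = ",")))
  }
  cat("  ", x$verdict, "\n", sep = "")
  invisible(x)
}

#' Tabulate a comparison in base-case-table layout
#'
#' One row per strategy with columns `group`, `cost`, `incremental_cost`,
#' `qalys`, `incremental_qalys`, `icer` (increment/ICER cells empty on the
#' comparator row), values rounded to 2 decimals at serialization.
#'
#' @param result A `cea_result`.
#' @param path Optional CSV path.
#' @return A data frame.
#' @export
cea_table <- function(result, path = NULL) {
  stopifnot(inherits(result, "cea_result"))
  df <- data.frame(
    group = c(result$intervention$name, result$comparator$name),
    cost = round(c(result$intervention$cost, result$comparator$cost), 2),
    incremental_cost = c(round(result$incremental_cost, 2), NA),
    qalys = round(c(result$intervention$qalys, result$comparator$qalys), 2),
    incremental_qalys = c(round(result$incremental_qalys, 2), NA),
    icer = c(round(result$icer, 2), NA)
  )
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  df
}
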