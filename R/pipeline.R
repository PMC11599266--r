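#' Bundle a full two-strategy comparison
#'
#' A `cea_pipeline` holds everything needed to evaluate the decision model:
#' the model configuration, the two strategies (intervention first), the
#' non-drug costs and the utilities. Cohort traces are built once at
#' construction (they depend only on the survival curves and cycle
#' structure, not on prices, utilities or the discount rate) and reused by
#' the sensitivity machinery.
#'
#' @param config A [model_config()].
#' @param intervention,comparator [strategy_inputs()] objects.
#' @param costs A [cost_inputs()].
#' @param utils A [utilities()].
#' @return An object of class `cea_pipeline`.
#' @export
cea_pipeline <- function(config, intervention, comparator, costs, utils) {
  stopifnot(inherits(config, "model_config"),
            inherits(intervention, "strategy_inputs"),
            inherits(comparator, "strategy_inputs"),
            inherits(costs, "cost_inputs"), inherits(utils, "utilities"))
  structure(
    list(config = config, intervention = intervention, comparator = comparator,
         costs = costs, utils = utils,
         traces = list(
           intervention = build_trace(config, intervention$os_model,
                                      intervention$pfs_model),
           comparator = build_trace(config, comparator$os_model,
                                    comparator$pfs_model)
         )),
    class = "cea_pipeline"
  )
}

# valid override names for a pipeline
override_names <- function(pipeline) {
  ae <- unique(c(pipeline$intervention$adverse_events$name,
                 pipeline$comparator$adverse_events$name))
  c(paste0("drug_cost.", c(pipeline$intervention$name, pipeline$comparator$name)),
    "lab_per_visit", "imaging_per_visit", "supportive_per_cycle",
    "end_of_life_once", "subsequent_tx_per_cycle",
    if (length(ae)) paste0("ae_cost.", ae),
    "u_pfs", "u_pd", "discount")
}

#' Evaluate the decision model, optionally with parameter overrides
#'
#' Runs accrual for both arms and compares them. `overrides` is a named
#' numeric vector replacing selected inputs; valid names are the two
#' `drug_cost.<arm>` entries, the five [cost_inputs()] fields,
#' `ae_cost.<event>` (replaces that event's unit cost in both arms),
#' `u_pfs`, `u_pd` and `discount`. An unknown name is an error that lists the
#' valid names. Overridden utilities must still satisfy
#' `u_pd <= u_pfs`; violations raise an error (the probabilistic sensitivity
#' analysis catches these and resamples).
#'
#' @param pipeline A [cea_pipeline()].
#' @param overrides Named numeric vector (possibly empty).
#' @return A `cea_result` (see [compare_strategies()]).
#' @export
evaluate_cea <- function(pipeline, overrides = numeric(0)) {
  stopifnot(inherits(pipeline, "cea_pipeline"))
  if (length(overrides)) {
    valid <- override_names(pipeline)
    bad <- setdiff(names(overrides), valid)
    if (length(bad)) {
      stop(sprintf("unknown parameter(s) %s; valid names: %s",
                   paste(bad, collapse = ", "), paste(valid, collapse = ", ")),
           call. = FALSE)
    }
  }
  ov <- function(name, default) {
    if (name %in% names(overrides)) unname(overrides[[name]]) else default
  }
  config <- pipeline$config
  disc <- ov("discount", config$annual_discount)
  if (disc != config$annual_discount) {
    config <- model_config(config$cycle_days, config$horizon_years, disc,
                           config$wtp, config$half_cycle_correction,
                           config$transition_mode,
                           allow_extended = config$allow_extended)
  }
  costs <- cost_inputs(
    lab_per_visit = ov("lab_per_visit", pipeline$costs$lab_per_visit),
    imaging_per_visit = ov("imaging_per_visit", pipeline$costs$imaging_per_visit),
    supportive_per_cycle = ov("supportive_per_cycle", pipeline$costs$supportive_per_cycle),
    end_of_life_once = ov("end_of_life_once", pipeline$costs$end_of_life_once),
    subsequent_tx_per_cycle = ov("subsequent_tx_per_cycle",
                                 pipeline$costs$subsequent_tx_per_cycle)
  )
  utils <- utilities(u_pfs = ov("u_pfs", pipeline$utils$u_pfs),
                     u_pd = ov("u_pd", pipeline$utils$u_pd))
  adjust_strategy <- function(strat) {
    strat$drug_cost_per_cycle <- ov(paste0("drug_cost.", strat$name),
                                    strat$drug_cost_per_cycle)
    if (nrow(strat$adverse_events)) {
      for (i in seq_len(nrow(strat$adverse_events))) {
        key <- paste0("ae_cost.", strat$adverse_events$name[i])
        strat$adverse_events$unit_cost[i] <- ov(key, strat$adverse_events$unit_cost[i])
      }
    }
    strat
  }
  a <- adjust_strategy(pipeline$intervention)
  b <- adjust_strategy(pipeline$comparator)
  res_a <- accrue(pipeline$traces$intervention, a, costs, utils, config)
  res_b <- accrue(pipeline$traces$comparator, b, costs, utils, config)
  compare_strategies(res_a, res_b, config)
}
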