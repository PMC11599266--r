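#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON) model configuration carrying the cycle settings,
#' the two strategies with their fitted survival curves and adverse-event
#' profiles, all unit costs, the utilities, and the sensitivity ranges and
#' distributions. Validation is strict: unknown keys, missing required
#' fields and invariant violations (e.g. a progressed-state utility above
#' the progression-free utility, or a discount rate outside `[0, 0.08]`
#' without `allow_extended`) are rejected with messages naming the offending
#' key.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return An object of class `pipeline_config`: list with `pipeline` (a
#'   ready [cea_pipeline()]), `specs` (named [param_spec()] list for the
#'   sensitivity analyses) and `raw` (the parsed file).
#' @seealso [default_config_path()] for the shipped configuration.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  check_keys(raw, "<top level>",
             required = c("schema_version", "model", "strategies", "costs",
                          "ae_unit_costs", "utilities"),
             optional = "scenario")
  if (!identical(as.integer(raw$schema_version), 1L)) {
    stop("schema_version: only version 1 is supported", call. = FALSE)
  }
  m <- raw$model
  check_keys(m, "model",
             required = c("cycle_days", "horizon_years", "annual_discount",
                          "wtp", "half_cycle_correction", "transition_mode"),
             optional = "allow_extended")
  dist_block(m$annual_discount, "model.annual_discount")
  config <- model_config(
    cycle_days = req_num(m$cycle_days, "model.cycle_days"),
    horizon_years = req_num(m$horizon_years, "model.horizon_years"),
    annual_discount = m$annual_discount$baseline,
    wtp = req_num(m$wtp, "model.wtp"),
    half_cycle_correction = isTRUE(m$half_cycle_correction),
    transition_mode = m$transition_mode,
    allow_extended = isTRUE(m$allow_extended)
  )
  if (length(raw$strategies) != 2L) {
    stop("strategies: exactly two strategies (intervention first) are required",
         call. = FALSE)
  }
  cost_keys <- c("lab_per_visit", "imaging_per_visit", "supportive_per_cycle",
                 "end_of_life_once", "subsequent_tx_per_cycle")
  check_keys(raw$costs, "costs", required = cost_keys)
  for (k in cost_keys) dist_block(raw$costs[[k]], paste0("costs.", k))
  costs <- do.call(cost_inputs, stats::setNames(
    lapply(cost_keys, function(k) raw$costs[[k]]$baseline), cost_keys))
  check_keys(raw$utilities, "utilities", required = c("u_pfs", "u_pd"))
  dist_block(raw$utilities$u_pfs, "utilities.u_pfs")
  dist_block(raw$utilities$u_pd, "utilities.u_pd")
  if (raw$utilities$u_pd$baseline > raw$utilities$u_pfs$baseline) {
    stop("utilities: u_pd baseline exceeds u_pfs baseline", call. = FALSE)
  }
  utils <- utilities(u_pfs = raw$utilities$u_pfs$baseline,
                     u_pd = raw$utilities$u_pd$baseline)
  for (nm in names(raw$ae_unit_costs)) {
    dist_block(raw$ae_unit_costs[[nm]], paste0("ae_unit_costs.", nm))
  }
  strategies <- lapply(seq_along(raw$strategies), function(i) {
    s <- raw$strategies[[i]]
    where <- sprintf("strategies[%d]", i)
    check_keys(s, where,
               required = c("name", "drug_cost_per_cycle", "survival"),
               optional = "adverse_events")
    dist_block(s$drug_cost_per_cycle, paste0(where, ".drug_cost_per_cycle"))
    check_keys(s$survival, paste0(where, ".survival"), required = c("os", "pfs"))
    mk_model <- function(b, key) {
      check_keys(b, key, required = c("family", "shape", "scale"))
      parametric_survival(b$family, b$shape, b$scale)
    }
    ae <- data.frame(name = character(), incidence = numeric(),
                     unit_cost = numeric())
    if (length(s$adverse_events)) {
      ae <- do.call(rbind, lapply(s$adverse_events, function(a) {
        check_keys(a, paste0(where, ".adverse_events"),
                   required = c("name", "incidence"))
        uc <- raw$ae_unit_costs[[a$name]]
        if (is.null(uc)) {
          stop(sprintf("%s.adverse_events: no ae_unit_costs entry for '%s'",
                       where, a$name), call. = FALSE)
        }
        data.frame(name = a$name, incidence = a$incidence,
                   unit_cost = uc$baseline)
      }))
    }
    strategy_inputs(
      name = s$name, drug_cost_per_cycle = s$drug_cost_per_cycle$baseline,
      os_model = mk_model(s$survival$os, paste0(where, ".survival.os")),
      pfs_model = mk_model(s$survival$pfs, paste0(where, ".survival.pfs")),
      adverse_events = ae
    )
  })
  pipeline <- cea_pipeline(config, strategies[[1L]], strategies[[2L]],
                           costs, utils)
  specs <- config_param_specs(raw, strategies)
  structure(list(pipeline = pipeline, specs = specs, raw = raw),
            class = "pipeline_config")
}

check_keys <- function(x, where, required, optional = character(0)) {
  if (!is.list(x)) stop(sprintf("%s: expected a mapping", where), call. = FALSE)
  missing_keys <- setdiff(required, names(x))
  if (length(missing_keys)) {
    stop(sprintf("%s: missing required key(s): %s", where,
                 paste(missing_keys, collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(names(x), c(required, optional))
  if (length(unknown)) {
    stop(sprintf("%s: unknown key(s): %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

req_num <- function(x, where) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("%s: expected a single finite number", where), call. = FALSE)
  }
  x
}

dist_block <- function(b, where) {
  check_keys(b, where, required = c("baseline", "low", "high", "distribution"))
  req_num(b$baseline, paste0(where, ".baseline"))
  if (!(b$low <= b$baseline && b$baseline <= b$high)) {
    stop(sprintf("%s: need low <= baseline <= high", where), call. = FALSE)
  }
  if (!b$distribution %in% c("gamma", "beta", "fixed")) {
    stop(sprintf("%s.distribution: must be gamma, beta or fixed", where),
         call. = FALSE)
  }
  invisible(b)
}

# param_spec list from the parsed config
config_param_specs <- function(raw, strategies) {
  specs <- list()
  add <- function(name, b, support = c(0, 1)) {
    specs[[name]] <<- param_spec(name, b$baseline, b$low, b$high,
                                 b$distribution, support = support)
  }
  for (i in seq_along(raw$strategies)) {
    add(paste0("drug_cost.", raw$strategies[[i]]$name),
        raw$strategies[[i]]$drug_cost_per_cycle)
  }
  for (k in names(raw$costs)) add(k, raw$costs[[k]])
  used_ae <- unique(unlist(lapply(strategies, function(s) s$adverse_events$name)))
  for (nm in intersect(names(raw$ae_unit_costs), used_ae)) {
    add(paste0("ae_cost.", nm), raw$ae_unit_costs[[nm]])
  }
  add("u_pfs", raw$utilities$u_pfs)
  add("u_pd", raw$utilities$u_pd)
  add("discount", raw$model$annual_discount, support = c(0, 0.08))
  specs
}

#' Path to (and contents of) the shipped configuration
#'
#' `default_config_path()` returns the installed location of
#' `params_sunlight_cn.yaml`, the worked configuration for the third-line
#' colorectal cancer comparison (trifluridine/tipiracil + bevacizumab vs
#' monotherapy, Chinese healthcare-system perspective);
#' `default_config_list()` returns it parsed.
#'
#' @return A file path / a nested list.
#' @export
default_config_path <- function() {
  system.file("extdata", "params_sunlight_cn.yaml", package = "markovcea",
              mustWork = TRUE)
}

#' @rdname default_config_path
#' @export
default_config_list <- function() {
  yaml::read_yaml(default_config_path())
}

#' Run the whole pipeline end to end
#'
#' Orchestrates the base-case evaluation, the one-way (tornado) sensitivity
#' analysis and, optionally, the probabilistic sensitivity analysis with its
#' acceptability curve. When `out_dir` is given, every result is serialized
#' (`trace_intervention.csv`, `trace_comparator.csv`, `base_case.csv`,
#' `tornado.csv`, `psa_samples.csv`, `ceac.csv`, a machine-readable
#' `summary.json` and a `manifest.json` with MD5 hashes of all outputs, the
#' package version and the seed). Costs are rounded to 2 decimals at
#' serialization only. Given the same configuration and seed the run is
#' fully deterministic, manifest hashes included.
#'
#' @param config A `pipeline_config` from [load_config()], or a path to a
#'   configuration file.
#' @param out_dir Optional output directory (created if absent).
#' @param seed Integer seed for the probabilistic analysis.
#' @param n_sims Number of PSA draws (default 10000).
#' @param psa Logical; run the probabilistic analysis (default `TRUE`).
#' @param wtp_grid WTP grid for the acceptability curve.
#' @return A list (invisibly when `out_dir` is given): `base` (`cea_result`),
#'   `base_table`, `tornado`, `psa`, `ceac`, `traces`, `files`.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = 1L, n_sims = 10000L,
                         psa = TRUE, wtp_grid = seq(0, 1e6, by = 5000)) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  pipeline <- config$pipeline
  base <- evaluate_cea(pipeline)
  tornado <- one_way(pipeline, config$specs)
  psa_res <- NULL
  ceac_df <- NULL
  if (psa) {
    psa_res <- run_psa(pipeline, n_sims = n_sims, seed = seed,
                       specs = config$specs)
    ceac_df <- ceac(psa_res, wtp_grid)
  }
  out <- list(base = base, base_table = cea_table(base), tornado = tornado,
              psa = psa_res, ceac = ceac_df, traces = pipeline$traces,
              files = NULL)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    fp <- function(x) file.path(out_dir, x)
    write_trace(pipeline$traces$intervention, fp("trace_intervention.csv"))
    write_trace(pipeline$traces$comparator, fp("trace_comparator.csv"))
    cea_table(base, fp("base_case.csv"))
    utils::write.csv(
      transform(as.data.frame(tornado),
                icer_low = round(icer_low, 2), icer_high = round(icer_high, 2),
                spread = round(spread, 2)),
      fp("tornado.csv"), row.names = FALSE, quote = FALSE)
    if (psa) {
      utils::write.csv(psa_res$samples, fp("psa_samples.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(ceac_df, fp("ceac.csv"), row.names = FALSE, quote = FALSE)
    }
    summary <- list(
      intervention = base$intervention$name,
      comparator = base$comparator$name,
      cost_intervention = round(base$intervention$cost, 2),
      cost_comparator = round(base$comparator$cost, 2),
      qalys_intervention = round(base$intervention$qalys, 4),
      qalys_comparator = round(base$comparator$qalys, 4),
      incremental_cost = round(base$incremental_cost, 2),
      incremental_qalys = round(base$incremental_qalys, 4),
      icer = if (is.na(base$icer)) NULL else round(base$icer, 2),
      dominance = base$dominance,
      nmb = round(base$nmb, 2),
      wtp = base$wtp,
      verdict = base$verdict
    )
    jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
    outputs <- list.files(out_dir, pattern = "\\.(csv|json)$", full.names = TRUE)
    outputs <- setdiff(outputs, fp("manifest.json"))
    manifest <- list(
      package = "markovcea",
      version = as.character(utils::packageVersion("markovcea")),
      seed = as.integer(seed),
      n_sims = if (psa) as.integer(n_sims) else NULL,
      hashes = as.list(tools::md5sum(sort(outputs)))
    )
    names(manifest$hashes) <- basename(names(manifest$hashes))
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                         null = "null")
    out$files <- c(outputs, fp("manifest.json"))
    return(invisible(out))
  }
  out
}
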