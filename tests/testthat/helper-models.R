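# shared fixtures: the shipped fitted-curve parameter sets and small configs

table1_models <- function() {
  list(
    combo = list(OS = parametric_survival("lognormal", 2.398, 0.808),
                 PFS = parametric_survival("lognormal", 1.660, 0.850)),
    mono = list(OS = parametric_survival("lognormal", 2.030, 0.793),
                PFS = parametric_survival("lognormal", 1.110, 0.644))
  )
}

# one representative parameter set per family, on a months scale comparable
# to the shipped curves
family_examples <- function() {
  list(
    exponential = parametric_survival("exponential", scale = 0.08),
    weibull     = parametric_survival("weibull", 1.3, 12),
    lognormal   = parametric_survival("lognormal", 2.398, 0.808),
    loglogistic = parametric_survival("loglogistic", 1.8, 10),
    gompertz    = parametric_survival("gompertz", 0.08, 0.05),
    gamma       = parametric_survival("gamma", 1.5, 0.12)
  )
}

shipped_pipeline <- function() {
  load_config(default_config_path())
}

# a cohort trace with everyone dead from cycle 1, for hand-computed accrual
dead_at_one_trace <- function() {
  structure(
    data.frame(cycle = 0:1, t_months = c(0, 28 / 30.4375),
               pfs = c(1, 0), pd = c(0, 0), dead = c(0, 1),
               new_deaths = c(0, 1)),
    class = c("cohort_trace", "data.frame")
  )
}

# synthetic surv_fit for selection tests
fake_fit <- function(family, aic, bic = aic) {
  structure(
    list(model = parametric_survival("exponential", scale = 1),
         family = family, loglik = -aic / 2, aic = aic, bic = bic,
         n = 10L, converged = TRUE),
    class = "surv_fit"
  )
}
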