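test_that("conditional event probability: memorylessness, anchoring and frozen log-normal value", {
  expo <- parametric_survival("exponential", scale = 0.2)
  u <- 0.8
  p <- conditional_event_prob(expo, c(u, 5, 20), u)
  expect_equal(p, rep(1 - exp(-0.2 * u), 3), tolerance = 1e-12)
  ln <- parametric_survival("lognormal", 2.398, 0.808)
  expect_equal(conditional_event_prob(ln, 3, 3), 1 - surv_prob(ln, 3), tolerance = 1e-12)
  # frozen from an independent normal-CDF computation of 1 - S(12)/S(11.0801)
  expect_equal(conditional_event_prob(ln, 12, 0.9199), 0.07915127558178692,
               tolerance = 1e-9)
  expect_error(conditional_event_prob(ln, 1, 2), "t >= u")
})

test_that("transition matrices are row-stochastic with an absorbing death state", {
  cfg <- model_config()
  ms <- table1_models()
  for (arm in names(ms)) {
    for (cc in c(1, 10, 65, 130)) {
      m <- transition_matrix(cc, cfg, ms[[arm]]$OS, ms[[arm]]$PFS)
      expect_equal(rowSums(m), c(pfs = 1, pd = 1, dead = 1), tolerance = 1e-12)
      expect_equal(unname(m["dead", ]), c(0, 0, 1))
      expect_true(all(m >= 0 & m <= 1))
    }
  }
  # PFS-exit below death probability floors the progression entry at zero
  slow_pfs <- parametric_survival("exponential", scale = 0.01)
  fast_os <- parametric_survival("exponential", scale = 0.5)
  m <- transition_matrix(1, cfg, fast_os, slow_pfs)
  expect_identical(m["pfs", "pd"], 0)
})

test_that("the cohort starts progression-free and conserves mass to 1e-10 every cycle", {
  cfg <- model_config()
  ms <- table1_models()
  for (arm in names(ms)) {
    tr <- build_trace(cfg, ms[[arm]]$OS, ms[[arm]]$PFS)
    expect_identical(nrow(tr), n_cycles(cfg) + 1L)
    expect_identical(n_cycles(cfg), 130L)
    expect_equal(unname(unlist(tr[1, c("pfs", "pd", "dead")])), c(1, 0, 0))
    expect_lt(max(abs(tr$pfs + tr$pd + tr$dead - 1)), 1e-10)
    expect_true(all(diff(tr$dead) >= -1e-12))
    expect_true(all(diff(tr$pfs) <= 1e-12))
    expect_true(all(tr$pfs >= 0 & tr$pd >= 0 & tr$dead >= 0))
  }
})

test_that("identical OS and PFS curves leave the progressed state empty (partitioned mode)", {
  cfg <- model_config(transition_mode = "partitioned")
  m <- parametric_survival("lognormal", 2.0, 0.8)
  tr <- build_trace(cfg, m, m)
  expect_true(all(tr$pd == 0))
})

test_that("markov and partitioned constructions agree within 0.02 per cycle at the shipped parameters", {
  ms <- table1_models()
  for (arm in names(ms)) {
    trm <- build_trace(model_config(transition_mode = "markov"),
                       ms[[arm]]$OS, ms[[arm]]$PFS)
    trp <- build_trace(model_config(transition_mode = "partitioned"),
                       ms[[arm]]$OS, ms[[arm]]$PFS)
    for (st in c("pfs", "pd", "dead")) {
      expect_lt(max(abs(trm[[st]] - trp[[st]])), 0.02)
    }
  }
})

test_that("exponential-curve trace matches the continuous-time three-state closed form", {
  cfg <- model_config()
  os <- parametric_survival("exponential", scale = 0.10)
  pfs <- parametric_survival("exponential", scale = 0.25)
  tr <- build_trace(cfg, os, pfs)
  expect_lt(max(abs(tr$pfs - exp(-0.25 * tr$t_months))), 0.01)
  expect_lt(max(abs(tr$dead - (1 - exp(-0.10 * tr$t_months)))), 0.01)
  expect_lt(max(abs(tr$pd - (exp(-0.10 * tr$t_months) - exp(-0.25 * tr$t_months)))), 0.01)
})

test_that("with a long horizon the whole cohort reaches the death state", {
  cfg <- model_config(horizon_years = 40)
  ms <- table1_models()
  for (arm in names(ms)) {
    tr <- build_trace(cfg, ms[[arm]]$OS, ms[[arm]]$PFS)
    expect_gt(tr$dead[nrow(tr)], 0.99)
  }
})

test_that("curve-crossing pathology triggers the documented clamp warning", {
  # PFS above OS until ~5.4 months; over a 1-year horizon that clamps more
  # than 5% of cycles
  cfg <- model_config(transition_mode = "partitioned", horizon_years = 1)
  os <- parametric_survival("lognormal", 2.030, 0.793)
  pfs_above <- parametric_survival("lognormal", 1.9, 0.5)
  expect_warning(build_trace(cfg, os, pfs_above), "floored at zero")
  # over the full 10-year horizon the same pair clamps < 5% of cycles and
  # passes silently, with the progressed state floored at zero early on
  tr <- build_trace(model_config(transition_mode = "partitioned"), os, pfs_above)
  expect_identical(tr$pd[2], 0)
  expect_true(all(tr$pd >= 0))
})

test_that("trace CSV export keeps the documented column layout", {
  cfg <- model_config(horizon_years = 1)
  ms <- table1_models()$combo
  tr <- build_trace(cfg, ms$OS, ms$PFS)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, path)
  back <- read.csv(path)
  expect_identical(names(back),
                   c("cycle", "t_months", "pfs", "pd", "dead", "new_deaths"))
  expect_equal(back$pfs, tr$pfs, tolerance = 1e-12)
})

test_that("model configuration rejects out-of-support discount rates unless extended", {
  expect_error(model_config(annual_discount = 0.2), "\\[0, 0.08\\]")
  expect_silent(model_config(annual_discount = 0.2, allow_extended = TRUE))
  expect_error(model_config(cycle_days = 0), "positive")
})
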