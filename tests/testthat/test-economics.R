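test_that("BSA and the sex-weighted patient profile reproduce the worked example", {
  h <- weighted_patient_profile(169.70, 158.00, 256, 236)
  w <- weighted_patient_profile(69.60, 59.00, 256, 236)
  expect_equal(round(h, 2), 164.09)
  expect_equal(round(w, 2), 64.52)
  expect_equal(round(body_surface_area(h, w), 2), 1.79)
  # plain linear arithmetic
  expect_equal(body_surface_area(169.70, 69.60),
               0.0061 * 169.70 + 0.0124 * 69.60 - 0.0099, tolerance = 1e-12)
  expect_equal(weighted_patient_profile(5, 5, 3, 11), 5)
  expect_error(body_surface_area(-1, 60), "positive")
  expect_error(weighted_patient_profile(1, 2, 0, 0), "positive total")
})

test_that("discount factors follow (1+r)^-t on the cycle grid", {
  cfg <- model_config()
  expect_identical(discount_factor(0, cfg), 1)
  expect_equal(discount_factor(13, cfg), 1.05^(-364 / 365.25), tolerance = 1e-12)
  cfg0 <- model_config(annual_discount = 0)
  expect_equal(discount_factor(0:130, cfg0), rep(1, 131))
  expect_true(all(diff(discount_factor(0:130, cfg)) < 0))
})

test_that("accrual matches a two-cycle hand computation when everyone dies at cycle 1", {
  cfg <- model_config(horizon_years = 28 / 365.25)  # exactly one cycle
  expect_identical(n_cycles(cfg), 1L)
  tr <- dead_at_one_trace()
  ms <- table1_models()$combo
  strat <- strategy_inputs(
    "combo", 23625.40, ms$OS, ms$PFS,
    adverse_events = data.frame(name = "neutropenia", incidence = 0.431,
                                unit_cost = 3214.90)
  )
  costs <- cost_inputs()
  res <- accrue(tr, strat, costs, utilities(), cfg)
  exp_cost <- 0.431 * 3214.90 +                      # adverse-event lump sum
    (23625.40 + 317.36 + 677.70) +                   # cycle-0 PFS state costs
    11299.00 * discount_factor(1, cfg)               # end-of-life at death entry
  expect_equal(res$cost, exp_cost, tolerance = 1e-9)
  expect_equal(res$qalys, 0.84 * 28 / 365.25, tolerance = 1e-12)
})

test_that("zero costs give zero spend; unit utilities give discounted life-years", {
  cfg <- model_config()
  ms <- table1_models()$combo
  tr <- build_trace(cfg, ms$OS, ms$PFS)
  strat0 <- strategy_inputs("free", 0, ms$OS, ms$PFS)
  zero <- cost_inputs(0, 0, 0, 0, 0)
  res0 <- accrue(tr, strat0, zero, utilities(1, 1), cfg)
  expect_identical(res0$cost, 0)
  ly <- sum(discount_factor(tr$cycle, cfg) * (tr$pfs + tr$pd)) * 28 / 365.25
  expect_equal(res0$qalys, ly, tolerance = 1e-12)
})

test_that("with unit utilities and no discounting QALYs equal the restricted mean OS within one cycle", {
  cfg <- model_config(annual_discount = 0)
  ms <- table1_models()
  for (arm in names(ms)) {
    tr <- build_trace(cfg, ms[[arm]]$OS, ms[[arm]]$PFS)
    strat <- strategy_inputs(arm, 0, ms[[arm]]$OS, ms[[arm]]$PFS)
    res <- accrue(tr, strat, cost_inputs(0, 0, 0, 0, 0), utilities(1, 1), cfg)
    rmst_months <- restricted_mean_survival(ms[[arm]]$OS, max(tr$t_months))
    expect_lt(abs(res$qalys * 12 - rmst_months), 28 / 30.4375)
  }
})

test_that("discounting can only shrink totals; costs and QALYs are monotone in their inputs", {
  pc <- shipped_pipeline()
  base <- evaluate_cea(pc$pipeline)
  undisc <- evaluate_cea(pc$pipeline, c(discount = 0))
  expect_lt(base$intervention$cost, undisc$intervention$cost)
  expect_lt(base$intervention$qalys, undisc$intervention$qalys)
  for (p in c("lab_per_visit", "supportive_per_cycle", "end_of_life_once",
              "subsequent_tx_per_cycle", "drug_cost.FTD-TPI")) {
    baseline <- if (startsWith(p, "drug")) {
      pc$pipeline$comparator$drug_cost_per_cycle
    } else {
      pc$pipeline$costs[[p]]
    }
    bumped <- evaluate_cea(pc$pipeline, stats::setNames(baseline + 1000, p))
    expect_gt(bumped$comparator$cost, base$comparator$cost)
  }
  up <- evaluate_cea(pc$pipeline, c(u_pd = 0.60))
  expect_gt(up$intervention$qalys, base$intervention$qalys)
})

test_that("utility objects enforce the dead <= progressed <= progression-free ordering", {
  expect_error(utilities(u_pfs = 0.84, u_pd = 0.9), "u_pd <= u_pfs")
  expect_error(utilities(u_pfs = 1.2, u_pd = 0.5), "u_pd <= u_pfs")
  expect_silent(utilities(0.84, 0.57))
})

test_that("comparison reproduces the published base-case increments from the printed totals", {
  cfg <- model_config()
  a <- structure(list(name = "combo", cost = 838492.74, qalys = 2.45),
                 class = "strategy_result")
  b <- structure(list(name = "mono", cost = 357396.97, qalys = 1.54),
                 class = "strategy_result")
  res <- compare_strategies(a, b, cfg)
  expect_equal(res$incremental_qalys, 0.91, tolerance = 1e-12)
  # the published increment (481,095.78) differs from the subtraction of the
  # published totals by 0.01 CNY (rounding in source)
  expect_lt(abs(res$incremental_cost - 481095.78), 0.02)
  expect_identical(res$dominance, "none")
  expect_false(res$cost_effective)
  expect_match(res$verdict, "not cost-effective")
})

test_that("dominance and equivalence flags replace the ICER when signs disagree", {
  cfg <- model_config()
  mk <- function(cost, q) structure(list(name = "x", cost = cost, qalys = q),
                                    class = "strategy_result")
  dom <- compare_strategies(mk(100, 2), mk(200, 1), cfg)
  expect_identical(dom$dominance, "dominant")
  expect_true(is.na(dom$icer))
  expect_true(dom$cost_effective)
  dtd <- compare_strategies(mk(300, 1), mk(200, 2), cfg)
  expect_identical(dtd$dominance, "dominated")
  expect_false(dtd$cost_effective)
  eqv <- compare_strategies(mk(200, 1), mk(200, 1), cfg)
  expect_identical(eqv$dominance, "equivalent")
})

test_that("the NMB sign agrees with the ICER-vs-WTP rule whenever QALYs are gained", {
  pc <- shipped_pipeline()
  set.seed(99)
  for (i in 1:20) {
    wtp <- runif(1, 1e5, 1e6)
    pl <- pc$pipeline
    pl$config$wtp <- wtp
    res <- evaluate_cea(pl, c(u_pfs = runif(1, 0.7, 0.95)))
    expect_gt(res$incremental_qalys, 0)
    expect_identical(res$nmb >= 0, res$icer <= wtp)
  }
})

test_that("half-cycle correction halves only the boundary cycles", {
  cfg_h <- model_config(half_cycle_correction = TRUE)
  cfg <- model_config()
  ms <- table1_models()$combo
  tr <- build_trace(cfg, ms$OS, ms$PFS)
  strat <- strategy_inputs("combo", 1000, ms$OS, ms$PFS)
  plain <- accrue(tr, strat, cost_inputs(0, 0, 0, 0, 0), utilities(), cfg)
  half <- accrue(tr, strat, cost_inputs(0, 0, 0, 0, 0), utilities(), cfg_h)
  # cycle 0 has full PFS occupancy: the corrected cost drops by ~half a cycle
  expect_lt(half$cost, plain$cost)
  expect_gt(half$cost, plain$cost - 1000)
})
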