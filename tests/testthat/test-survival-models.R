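test_that("every family has a proper survival function: S(0)=1, non-increasing, in [0,1], vanishing tail", {
  grid <- c(0, 0.1, 0.5, 1, 2, 5, 10, 20, 60, 120)
  for (m in family_examples()) {
    s <- surv_prob(m, grid)
    expect_equal(s[1], 1, info = m$family)
    expect_true(all(s >= 0 & s <= 1), info = m$family)
    expect_true(all(diff(s) <= 1e-12), info = m$family)
    expect_lt(surv_prob(m, 1e4), 0.01)
  }
  # negative-shape Gompertz is the documented exception: survival plateaus
  defective <- parametric_survival("gompertz", -0.05, 0.02)
  expect_gt(surv_prob(defective, 1e5), 0.5)
  s <- surv_prob(defective, grid)
  expect_true(all(diff(s) <= 1e-12))
})

test_that("log-normal survival matches the normal-CDF closed form", {
  m <- parametric_survival("lognormal", 2.398, 0.808)
  expect_identical(surv_prob(m, 0), 1)
  # median at exp(meanlog)
  expect_equal(surv_prob(m, exp(2.398)), 0.5, tolerance = 1e-12)
  # frozen from an independent numerical normal-CDF computation:
  # 1 - Phi((ln 12 - 2.398) / 0.808)
  expect_equal(surv_prob(m, 12), 0.45717326254876056, tolerance = 1e-10)
})

test_that("survival evaluation rejects invalid inputs", {
  m <- parametric_survival("weibull", 1.2, 10)
  expect_error(surv_prob(m, -1), "must be finite and >= 0")
  expect_error(parametric_survival("weibull", -1, 10), "shape must be > 0")
  expect_error(parametric_survival("lognormal", 2.4, 0), "sdlog")
  expect_error(parametric_survival("exponential", scale = -0.1), "rate")
})

test_that("cumulative hazard is -log S with the documented closed forms and Inf sentinel", {
  for (m in family_examples()) {
    expect_equal(cum_hazard(m, 0), 0, info = m$family)
    h <- cum_hazard(m, c(1, 5, 20))
    expect_true(all(diff(h) > 0), info = m$family)
  }
  expo <- parametric_survival("exponential", scale = 0.3)
  expect_equal(cum_hazard(expo, 7), 0.3 * 7, tolerance = 1e-12)
  wei <- parametric_survival("weibull", 1.7, 9)
  expect_equal(cum_hazard(wei, 4), (4 / 9)^1.7, tolerance = 1e-12)
  # exhausted survival yields the documented +Inf sentinel
  steep <- parametric_survival("weibull", 8, 1)
  expect_identical(cum_hazard(steep, 1e6), Inf)
})

test_that("analytic density matches -dS/dt by finite differences", {
  grid <- c(0.5, 1, 2, 5, 10, 20, 40)
  h <- 1e-5
  for (m in family_examples()) {
    num <- (surv_prob(m, grid - h) - surv_prob(m, grid + h)) / (2 * h)
    ana <- surv_density(m, grid)
    expect_equal(num, ana, tolerance = 1e-6, info = m$family)
  }
})

test_that("uncensored exponential MLE equals the closed-form events/total-time estimator", {
  ipd <- pseudo_ipd(c(1, 2, 4), c(1, 1, 1))
  f <- fit_mle(ipd, "exponential")
  expect_true(f$converged)
  expect_equal(f$model$scale, 3 / 7, tolerance = 1e-6)
  # AIC/BIC identities with k = 1
  expect_equal(f$aic, -2 * f$loglik + 2, tolerance = 1e-12)
  expect_equal(f$bic, -2 * f$loglik + log(3), tolerance = 1e-12)
})

test_that("censored log-normal MLE recovers truth within the pre-computed +-0.05 band at n = 2000", {
  truth <- parametric_survival("lognormal", 2.398, 0.808)
  for (s in 1:3) {
    ipd <- simulate_ipd(truth, 2000, censoring_rate = 0.28, t_max = 40,
                        seed = 40 + s)
    expect_gt(mean(1 - ipd$event), 0.10)  # censoring genuinely present
    f <- fit_mle(ipd, "lognormal")
    expect_lt(abs(f$model$shape - 2.398), 0.05)
    expect_lt(abs(f$model$scale - 0.808), 0.05)
  }
})

test_that("each family refits its own simulated data within pre-computed relative-error bands", {
  bands <- c(exponential = 0.08, weibull = 0.08, lognormal = 0.06,
             loglogistic = 0.08, gompertz = 0.25, gamma = 0.12)
  ex <- family_examples()
  for (fam in names(ex)) {
    m <- ex[[fam]]
    ipd <- simulate_ipd(m, 2000, censoring_rate = 0.2, t_max = 36, seed = 301)
    f <- fit_mle(ipd, fam)
    expect_true(f$converged, info = fam)
    rel <- abs(f$model$scale - m$scale) / m$scale
    if (fam != "exponential") {
      rel <- max(rel, abs(f$model$shape - m$shape) / max(abs(m$shape), 0.05))
    }
    expect_lt(rel, bands[[fam]])
    # information-criterion identities, k = 2 except exponential
    k <- if (fam == "exponential") 1 else 2
    expect_equal(f$aic, -2 * f$loglik + 2 * k, tolerance = 1e-10)
    expect_equal(f$bic, -2 * f$loglik + k * log(f$n), tolerance = 1e-10)
  }
})

test_that("fitting guards reject degenerate inputs and report failures explicitly", {
  expect_error(pseudo_ipd(c(1, 2), c(0, 0)), "at least one event")
  expect_error(pseudo_ipd(c(0, 2), c(1, 1)), "strictly positive")
  expect_error(fit_mle(pseudo_ipd(c(3, 3), c(1, 1)), "weibull"),
               "two distinct times")
  # single-time data is legal for the one-parameter exponential
  f <- fit_mle(pseudo_ipd(c(3, 3), c(1, 1)), "exponential")
  expect_true(f$converged)
})

test_that("select_best picks the minimal criterion with the documented family-order tie-break", {
  fits <- list(fake_fit("exponential", 100), fake_fit("weibull", 98),
               fake_fit("lognormal", 99))
  expect_identical(select_best(fits, "aic")$family, "weibull")
  expect_identical(select_best(fits[2], "aic")$family, "weibull")
  tie <- list(fake_fit("gompertz", 50), fake_fit("weibull", 50))
  expect_identical(select_best(tie, "aic")$family, "weibull")
  expect_error(select_best(list(), "aic"), "no fits")
  # bic can disagree with aic and is honoured
  fits2 <- list(fake_fit("weibull", 98, bic = 120), fake_fit("lognormal", 99, bic = 101))
  expect_identical(select_best(fits2, "bic")$family, "lognormal")
})

test_that("AIC selection identifies the true log-normal family in >= 95% of replicates", {
  truth <- parametric_survival("lognormal", 2.398, 0.808)
  wins <- vapply(1:100, function(s) {
    ipd <- simulate_ipd(truth, 500, seed = 1000 + s)
    select_best(fit_all(ipd), "aic")$family == "lognormal"
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("fit tables round-trip through CSV", {
  ipd <- simulate_ipd(parametric_survival("weibull", 1.3, 12), 300, seed = 5)
  fits <- fit_all(ipd, c("exponential", "weibull"))
  path <- withr::local_tempfile(fileext = ".csv")
  df <- fit_table(fits, path)
  back <- read.csv(path)
  expect_equal(back$aic, df$aic, tolerance = 1e-6)
  expect_identical(back$family, df$family)
})
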