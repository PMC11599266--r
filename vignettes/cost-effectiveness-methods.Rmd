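---
title: "Methods: survival extrapolation and the three-state cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: survival extrapolation and the three-state cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovcea)
```

This vignette is the package's own account of its modelling choices: the
state-transition model and its assumptions, the survival machinery feeding
it, the economic accrual rules, the sensitivity machinery, and the places
where a published analysis of this kind leaves the implementer genuine
freedom — together with how that freedom was exercised here and why.

## The decision problem

The shipped configuration compares two third-line regimens for metastatic
colorectal cancer — trifluridine/tipiracil plus bevacizumab ("combination")
vs trifluridine/tipiracil alone ("monotherapy") — from the Chinese
healthcare-system perspective. Only direct medical costs enter: drug
acquisition, grade ≥ 3 adverse-event management, follow-up while
progression-free, subsequent-line therapy and supportive care after
progression, and one-time end-of-life care. Outcomes are quality-adjusted
life years. Both are discounted at 5% per year and compared through the
incremental cost-effectiveness ratio against a willingness-to-pay threshold
of ¥268,200 per QALY (three times 2023 per-capita GDP).

## Survival families and their parameterization

Six families are supported, each reduced to a `(shape, scale)` pair (time in
months throughout; day-denominated cycle lengths convert at 1 month =
30.4375 days):

| family | shape | scale | S(t) |
|---|---|---|---|
| exponential | — | rate $r$ | $e^{-rt}$ |
| Weibull | $k$ | $\lambda$ | $e^{-(t/\lambda)^k}$ |
| log-normal | meanlog $\mu$ | sdlog $\sigma$ | $1-\Phi\!\big(\tfrac{\ln t-\mu}{\sigma}\big)$ |
| log-logistic | $k$ | $\lambda$ | $\big(1+(t/\lambda)^k\big)^{-1}$ |
| Gompertz | $\gamma$ | $\lambda$ | $\exp\!\big(-\tfrac{\lambda}{\gamma}(e^{\gamma t}-1)\big)$ |
| gamma | $k$ | rate $r$ | $1-F_{\Gamma(k,r)}(t)$ |

Two conventions deserve emphasis because the source material for analyses
of this kind often leaves them implicit. First, the log-normal "shape" is
the meanlog and the "scale" the sdlog, on the log-month scale: the shipped
combination-arm OS parameters (2.398, 0.808) put the median at
$e^{2.398} = 11.0$ months, which is the only reading consistent with a
trial population whose 12-month survival is below one half. Second, the
Gompertz family admits negative shapes, under which survival plateaus at
$\exp(\lambda/\gamma) > 0$; the package permits this (it is a legitimate
fitted outcome) and documents that the "survival tends to zero" invariant
is exempted for it.

Fitting maximizes the right-censored log-likelihood
$\sum_{\text{events}}\log f(t_i) + \sum_{\text{censored}}\log S(t_i)$
through `flexsurv::flexsurvreg()`, the standard tool for exactly this task;
the package adds the bookkeeping the pipeline needs (explicit
non-convergence results instead of errors, AIC $=-2\ell+2k$ and BIC
$=-2\ell+k\ln n$ with $n$ the record count, deterministic family-order
tie-breaking in `select_best()`). Tests pin the fitter to closed forms
where they exist — the uncensored exponential MLE is events over total
time — and to parameter-recovery bands pre-computed by simulation.

## Reconstructing pseudo individual-patient data

Published curves arrive as digitized coordinates, not data. `reconstruct_ipd()`
turns a validated coordinate set into `total_n` event/censoring records:

* With a numbers-at-risk table, each inter-point interval receives
  $d_i = \mathrm{round}\{n_i(1 - S_{i+1}/S_i)\}$ events and
  $c_i = n_i - n_{i+1} - d_i$ censorings — the standard published-KM
  balance. When digitization noise makes the survival drop and the at-risk
  balance disagree slightly, the survival drop wins and the at-risk count
  is allowed to deplete below the table; a conflict worth more than five
  survival points is rejected as an infeasible digitization, naming the
  interval.
* Without a table, censoring is assumed administrative at the curve's end —
  the right default for a trial plot truncated at its follow-up horizon.

Event times inside an interval are placed by linear interpolation of the
survival drop (evenly spaced across the interval); a midpoint placement is
available via `event_placement = "midpoint"`. Interpolation is the default
because it is what makes the reconstruction self-consistent: the KM
estimate of the reconstructed records tracks the input coordinates within
0.02 at the input time points, a contract the test suite enforces for all
four shipped curve shapes. Curve validation refuses physically impossible
inputs — rising survival, values outside $[0,1]$, or a first point away
from $(0, 1)$ — naming the first offending point.

An independent cross-check, `fit_curve_lsq()`, fits parameters by least
squares on the log-cumulative-hazard of the coordinates directly, bypassing
reconstruction; the two routes agree on the fitted survival function to a
few percent, which is reassurance that neither is quietly wrong, though the
IPD-MLE route is the primary one.

## The cohort model

Three states — progression-free (PFS), progressed (PD), dead — with the
whole cohort starting progression-free and transitions irreversible. Cycles
are 28 days; the 10-year horizon gives
$\lfloor 10 \cdot 365.25/28 \rfloor = 130$ cycles, evaluated at cycle ends.

Per cycle $c$ (width $u$ months, end time $t_c$), the death probability is
the conditional event probability of the fitted OS curve,
$$p_{\text{death}}(c) = 1 - S_{OS}(t_c)/S_{OS}(t_c - u),$$
and likewise $p_{\text{exit}}(c)$ from the PFS curve; progression is the
excess $p_{\text{exit}} - p_{\text{death}}$, floored at zero. One point of
notation is worth flagging prominently: the conditional survival *ratio*
$S(t)/S(t-u)$ is the probability of remaining alive over the cycle; source
materials in this literature occasionally print that ratio under the label
"death probability", which is an evident transcription slip — the death
probability is its complement, and that is what the package implements.

Because death is drawn from the OS curve for both living states, the Markov
construction reproduces $S_{OS}$ and $S_{PFS}$ exactly at cycle ends, and
therefore coincides with the partitioned-survival construction
($\text{pfs} = S_{PFS}$, $\text{dead} = 1 - S_{OS}$,
$\text{pd} = S_{OS} - S_{PFS}$) wherever the curves are ordered. Both modes
are exposed (`transition_mode`), tested to agree within 0.02 per cycle at
the shipped parameters, and the Markov mode is the default. When the
fitted PFS curve crosses above OS — possible with independently fitted
curves — the progressed occupancy is floored at zero and the event is
logged; if more than 5% of cycles need the floor a warning names the
pathology rather than silently renormalizing. Mass conservation holds to
1e-10 per cycle by construction and is asserted per run.

## Economic accrual

Per cycle, with discount factor $(1+r)^{-t_{\text{years}}}$ at the
cycle-end time:

* PFS occupancy accrues drug acquisition plus laboratory and imaging
  follow-up. The source convention "per visit" comes with no stated visit
  frequency; one visit per 28-day cycle is the common convention and is the
  package's documented, overridable choice. Drug cost stops at progression
  (treatment-until-progression).
* PD occupancy accrues subsequent-line therapy (fruquintinib) plus
  supportive care each cycle — the accrual rule for subsequent therapy
  being another point the source class leaves unstated.
* The mass newly entering death each cycle is charged the one-time
  end-of-life cost. Charging at death entry (rather than the last PD cycle)
  is the package's choice and is flagged as such.
* Adverse-event management is a one-time expected lump sum at model entry,
  $\sum_j \text{incidence}_j \times \text{unit cost}_j$ over the arm's
  event list, since trials report per-patient incidences, not per-cycle
  rates. The shipped lists are loaded exactly as given even though the
  stated ≥ 20%-incidence inclusion rule and the listed incidences disagree;
  resolving that contradiction is not the package's job.
* QALYs weight occupancy by $u_{PFS} = 0.84$, $u_{PD} = 0.57$ (dead = 0),
  times the cycle length in years.

Half-cycle correction is off by default (the source class is silent on it)
and available via the configuration; it half-weights the boundary cycles'
occupancy terms but never the entry lump sum or the death-entry flow. One
upper limit in the shipped cost table is a printed typo
("9.49.32" for the subsequent-treatment cost): it is restored to 9,049.32,
which is exactly 1.2× the baseline, matching the ±20% convention of every
neighbouring row; the value is configuration-overridable.

Comparison reports increments (intervention minus comparator), the ICER
when the QALY increment is positive, dominance flags when the signs
disagree, the net monetary benefit at the configured threshold, and a
plain-text verdict implementing the decision rule.

## Sensitivity machinery

One-way analysis re-evaluates the deterministic model at each parameter's
low and high value, all else at baseline, and sorts by ICER spread. The
probabilistic analysis samples all non-fixed parameters independently —
gamma for costs, beta for utilities (support $[0,1]$) and the discount rate
(support $[0, 0.08]$, the one-way range) — using method-of-moments with
mean at baseline and sd $(\text{high}-\text{low})/(2\times 1.96)$, the
ranges being read as 95% intervals. Infeasible beta moments fail at
specification time, never during sampling. The fitted survival parameters
are held fixed in the PSA: the source class publishes no uncertainty for
them, and inventing a covariance would be worse than documenting the
omission.

Draws violating the utility ordering $u_{PD} \le u_{PFS}$ are resampled and
counted. Under the shipped distributions this affects about 1% of draws —
an expected consequence of independent sampling of overlapping betas, not a
defect — so the abort threshold for resampling sits at 2% of draws
(`max_invalid_frac`), high enough that ordinary overlap never trips it and
low enough that a genuinely mis-specified distribution still does.

The CEAC reports, per willingness-to-pay value on a ¥0–1,000,000 grid
(¥5,000 steps, covering both the ¥268,200 threshold and the region where
the curve crosses 50%), the fraction of draws with positive incremental
NMB. With every draw gaining QALYs the curve is monotone; QALY-losing draws
are the only possible source of non-monotonicity and are counted.

Everything is seed-deterministic: same configuration and seed, byte-identical
sample files — the test suite compares file hashes, and `run_pipeline()`
writes a manifest of output hashes to make silent drift visible.

## The synthetic-data generator

`make_scenario()` produces the complete input surface from known truth, so
the pipeline can be validated where the real analysis cannot be (no
patient-level data exists downstream of a published figure). The
`sunlight_like` preset simulates 246 patients per arm from the four
log-normal truths of the shipped configuration, applies 5% random
withdrawal (uniform over follow-up) plus administrative censoring at 12
months — the follow-up span the published curves actually cover, so
extrapolation beyond observed data is genuinely exercised — then computes
the KM estimate and emulates digitization: 30 points on an even time grid,
truncated-Gaussian reading error (sd 0.005 survival units, about half a
percentage point of axis-reading error), isotonic clipping to restore
monotonicity, exact anchor at $(0,1)$. The withdrawal rate and reading
error are the package's own choices of realistic magnitudes: modern
registrational trials lose few patients to follow-up within a year, and a
careful digitizer reads a printed axis to well under a point.

What the generator does *not* emulate: informative censoring, reporting-time
granularity (monthly tick marks), pixel quantization, and the
within-interval censoring patterns a real at-risk table would carry. Passing
the end-to-end recovery tests therefore shows the chain is correct and
well-calibrated under clean conditions; it does not certify accuracy against
arbitrarily degraded source figures.

Recovery tolerances were pre-computed by a 200-replicate oracle run of this
generator at the shipped truths (the acceptance test then uses 50 fresh
replicates): worst-case absolute parameter error 0.33 (combination-arm OS,
whose 11-month median meets the 12-month censoring wall, leaving roughly
half the distribution unobserved) down to 0.15 for the best-identified
curve, with mean bias under 0.06 everywhere.

## Reproducibility of the motivating analysis, and its limits

With the published inputs — the fitted log-normal parameters, the cost
table, the utilities, the cycle structure — the package reproduces the
motivating analysis's *structure and decision*: an ICER far above the
threshold (¥515,351/QALY here), the combination-arm drug cost and
progression-free utility dominating the tornado, and a CEAC crossing 50%
around ¥509,000/QALY (the motivating analysis reports the same crossing
near ¥494,000). The published *absolute* totals, however, are not
recoverable from the published inputs alone, and the package deliberately
does not tune toward them: the published 2.45 QALYs for the combination arm
exceeds what its own published OS parameters allow, since a log-normal with
meanlog 2.398 and sdlog 0.808 has mean survival
$e^{\mu+\sigma^2/2} \approx 15.2$ months ≈ 1.27 life-years, i.e. at most
about 1.07 QALYs even undiscounted at the PFS utility. Unstated accrual
frequencies similarly prevent cost-total replication. The acceptance suite
therefore checks the worked dose arithmetic exactly, the engine against
independent oracles, and the published totals only through this documented
impossibility argument — an honest boundary, stated computationally.

## Problem sizes used in the shipped checks

The test suite simulates at $n = 246$ per curve for the digitization path
(50 replicates per truth), $n = 2000$ for direct fitter calibration,
$n = 500 \times 100$ replicates for family selection, and 10,000 PSA draws
for the acceptability analysis — the same order as the analyses the package
targets, chosen so the full suite completes in well under a minute of
simulation-heavy work.

## Known limitations

* Survival-curve uncertainty is excluded from the PSA (no published
  covariance); the ICER cloud understates total uncertainty accordingly.
* Parameters are sampled independently; real cost and utility parameters
  correlate.
* No treatment-switching adjustment, tunnel states, cure fractions or
  flexible (spline) hazards; covariate-adjusted survival is out of scope.
* The model is a cohort average: no microsimulation, no heterogeneity
  beyond the sex-weighted dosing profile.
* Currency is plain floating point internally, rounded to 2 d.p. only at
  serialization; totals in the hundreds of thousands of CNY lose nothing
  material at double precision.
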