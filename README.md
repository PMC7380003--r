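# persched

Personalized biopsy schedules for prostate-cancer active surveillance,
built on a joint model for longitudinal PSA and the interval-censored time
of Gleason reclassification.

## The problem

Men with low-risk prostate cancer on active surveillance (AS) are monitored
with serum PSA and periodic biopsies; a biopsy Gleason grade above 6
("Gleason reclassification", GR) triggers active treatment. Biopsies are
painful and risky, so fixed protocols face a burden/delay trade-off: annual
biopsies detect GR within a year but are burdensome, while the PRIAS
protocol (biopsies at years 1, 4, 7, 10, then every 5 years, switching to
annual spacing for patients whose PSA doubling time falls in (0, 10]
years) can delay detection by up to 3 years. `persched` implements
schedules that adapt the next biopsy time to each patient's own PSA history
and negative biopsies, and a simulation framework to score any schedule by
its burden and delay.

## The model

The PSA trajectory on the log2 scale follows a mixed-effects model

    y_i(t) = m_i(t) + eps_i(t),
    m_i(t) = x_i(t)' beta + z_i(t)' b_i,

with fixed effects for an intercept, centred age terms `(age-70)`,
`(age-70)^2` and a natural cubic spline in follow-up time (internal knots
0.1, 0.5 and 4 years, boundary knots 0 and 7), subject-level random effects
`b_i ~ N(0, D)` on the intercept and a smaller time spline, and
t-distributed residuals (3 df, scale `sigma`). The hazard of GR is a
relative-risk model in which the *level* and *velocity* of the error-free
trajectory enter the log hazard:

    h_i(t) = h0(t) exp{ gamma_1 (age-70) + gamma_2 (age-70)^2
                        + alpha_1 m_i(t) + alpha_2 m_i'(t) },

with a Weibull or piecewise-constant baseline `h0`. Given a patient's PSA
history `Y_j(s)` and latest negative biopsy at `t`, the package computes the
posterior predictive distribution of the GR time through the posterior of
`b_j` and derives biopsy times as Bayes rules: the expected GR time
(squared loss), the median (absolute loss), the time `u` at which the
dynamic survival `pi_j(u | t, s)` drops to a threshold `kappa` (multilinear
loss; `kappa` can be selected by maximizing an F1 score), and a hybrid rule
that falls back to the risk-based time when the predictive distribution is
too dispersed. Schedules are compared by the number of biopsies `N` until
detection and the offset `O` (detection time minus true GR time) on
simulated cohorts with three progression subgroups (Weibull baselines with
shape/scale (1.5, 4), (3, 5), (4.5, 6)).

## Worked example

```r
library(persched)

params <- priasParams()                   # PRIAS-like population parameters
tt <- seq(0, 2, by = 0.25)                # quarterly PSA for two years
hist <- patientHistory(psaTimes = tt, psa = 6 * 2^(0.05 * tt),
                       age = 65, lastBiopsy = 1)
pp <- posteriorRandomEffects(hist, params, nDraws = 500, seed = 7)

expectedGRTime(pp)                        # 4.69 years
quantileGRTime(pp, 0.5)                   # 4.24 years (median)
sqrt(varianceGRTime(pp))                  # 2.37 years (predictive SD)
proposeBiopsyTime(scheduler("dyn_risk", kappa = 0.95), pp)   # 1.83 years
```

The patient's latest biopsy (year 1) was negative and the PSA is rising
slowly: the predictive distribution of the GR time centres around 4.7
years, so the expected-time rule would wait years, while a risk-averse
dynamic-risk rule (`kappa = 0.95`, i.e. biopsy once the conditional risk
reaches 5%) proposes a biopsy at about 1.8 years. `runSchedule()` plays any
rule forward against a patient with known true GR time, and
`scheduleExperiment()` reproduces the six-schedule comparison (annual,
PRIAS, dynamic-risk, hybrid, median, expected) on replicated test cohorts,
reporting pooled means and SDs of `N` and of `O` in months.

A command-line interface is installed with the package (the script lives at
`system.file("exec", "persched", package = "persched")`; link it onto your
`PATH` or call it through `Rscript`):

```sh
persched simulate --out cohort --n 1000 --seed 1
persched fit      --cohort cohort --out fit.yml --seed 1
persched propose  --history patient.csv --method dyn_risk --kappa 0.95 --seed 1
persched kappa    --cohort cohort --t 1 --seed 1
persched evaluate --datasets 50 --ntest 250 --seed 1 --out table.csv
```

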