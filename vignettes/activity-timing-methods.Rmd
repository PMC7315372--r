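---
title: "Modeling the timing of personal-average MVPA attainment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the timing of personal-average MVPA attainment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mvpatiming` estimates *when* adolescents accumulate their person-specific
average daily moderate-to-vigorous physical activity (MVPA), and turns the
answer into decision points for just-in-time adaptive interventions. This
vignette is the package's account of the method: the model and its
assumptions, the parameters that matter, what the synthetic cohort does and
does not emulate, the numerical choices, and the design decisions that were
genuinely open.

## The event and the risk set

Each participant's threshold is their own mean daily MVPA, `m_i`, averaged
over included days. The event on a day is the first hour interval by which
cumulative MVPA since midnight *attains* `m_i`. Three conventions are fixed
package-wide:

* **Interval labeling.** Discrete time is indexed by the hour `t` ending
  the interval: row "Before 8 PM" is the interval (7 PM, 8 PM]. Every
  output file echoes this convention, because hour rows are otherwise easy
  to misread as clock spans.
* **Tie rule.** Cumulative MVPA exactly equal to `m_i` counts as the event
  (`>=`): "accumulating one's average" is attainment, not exceedance.
* **Risk window.** Intervals ending 9 AM through 11 PM, with "Before 8 AM"
  as the reference boundary. The window is configurable; the one actually
  used is echoed in outputs. Days whose event would fall before the window
  opens, days with no worn-awake minute inside the window, and participants
  with `m_i = 0` (who would trivially "attain" their average at the first
  worn hour of every day) are excluded and logged — the model has nothing
  to say about them.

## The hazard model

On the person-period table the discrete-time hazard is mixed-effects
logistic regression:

$$\operatorname{logit} h_i(t) = \beta_0 + \sum_{k=1}^{K}\beta_k s^k +
\gamma' x_i + \sum_k \delta_k' x_i\, s^k + u_i,\qquad u_i \sim N(0,\sigma_u^2)$$

with `s = (t - 8)/10`, an affine recoding that conditions the cubic design
(`s^3` stays order-1 across the window). Coefficients are back-transformed
to the raw hour scale for reporting; all contrasts (odds ratios, hazard
probabilities) are invariant to the recoding, and the test suite asserts
this.

* **Degree selection.** Degrees 1–3 are fitted sequentially; degree `k+1`
  is retained when the likelihood-ratio test against degree `k` has
  `p < 0.05`. The α is per step; no correction is applied, mirroring the
  ambient 5% convention of the field. Sequential selection can stop early
  when a cubic's quadratic projection is weak — a known property, not a
  bug; the power checks in the test suite use a cubic with strong signals
  at both steps.
* **Random effects.** A single person-level intercept. A day-level
  intercept is not identifiable with at most one event per day and is not
  offered.
* **Estimation.** `lme4::glmer` with adaptive Gauss–Hermite quadrature;
  `nodes = 1` is the Laplace approximation (the original estimator of this
  literature), `nodes = 9` the default for better-behaved marginal
  likelihoods at small cluster sizes. Estimates at 9 vs 15 nodes agree to
  1e-3 on simulated fixtures.
* **Moderators.** One model per moderator (sex, BMI category, sports,
  school day): main effect(s) plus interactions with every polynomial
  term. The moderated models inherit the base degree rather than
  re-selecting it (`reselect = TRUE` re-runs selection); school day enters
  as a row-level covariate in the same multilevel structure.
* **Likelihood computation.** Bernoulli rows are collapsed to binomial
  counts per person × design row before fitting — an exact reformulation
  that speeds the mixed fits several-fold. The binomial-coefficient
  constant is removed from the reported `-2LL` so likelihood-ratio tests
  compare models on the Bernoulli scale even when their groupings differ.
* **Degenerate designs.** Zero-variance and rank-deficient columns (e.g. a
  moderator constant in the table) are dropped with a warning and recorded
  on the fit; all-event or all-censor tables are rejected (separation);
  optimizer failure returns `converged = FALSE` with diagnostics rather
  than an exception.

## Reported quantities

Effect tables evaluate the fit at a covariate profile (reference levels
unless stated; always echoed): odds ratios `exp(eta(t) - eta(ref))` with
95% Wald CIs from the delta contrast `c'Vc` (z = 1.959964), hazard
probabilities `logit^{-1}(eta(t))`, and survival probabilities. The random
intercept is set to 0 — a median-person report; a population-averaged
variant was considered and rejected as the default because the reference
literature reports conditional curves.

**Survival lag convention.** `S(row k)` is the product of `(1 - h)` over
rows *strictly before* `k`, so the reference row has `S = 1`. This is the
only convention under which the published 16-row hazard/survival table
shipped in `inst/extdata/` is internally consistent (maximum deviation
0.008, within printed rounding) — the acceptance suite recomputes the
whole column, including 0.73 at "Before 8 PM" and the 12-point drop from
5 PM to 8 PM.

**Group comparison.** Two groups differ significantly at an hour when
their 95% CIs do not overlap: `max(lo_a, lo_b) > min(hi_a, hi_b)`. This is
deliberately the conservative CI-overlap convention of the source
literature, not a Wald test on the difference; with ~113 participants it
flags only large timing differences.

## Decision points

The overall window is the maximal contiguous run of rows whose hazard is
within `rel_tolerance` of the peak. The pipeline default is 5%: fitted
hazard curves are flat near their maximum, and a pure argmax would
arbitrarily return a single row where neighbours differ in the third
decimal (the published table itself prints a three-row plateau at 0.05).
Ties between equal-length runs break toward the later run — evening
priority, because the substantive conclusion of this literature privileges
the late-day window. The steepest `span`-row survival decline (default
span 3) is reported as a companion basis.

Moderator windows require both criteria: (1) at least one significantly
different hour, and (2) the difference in the registered direction. The
hypothesis registry defaults to: sports participants expected to have
higher odds, school days expected higher than non-school days, sex and BMI
exploratory (criterion 2 automatic once criterion 1 holds). Windows are
the longest contiguous run of significant hours, reported as *row labels*
plus the interval convention — never as raw clock spans, since prose
mappings of rows to clock windows are ambiguous.

## Preprocessing constants

All constants live in `algorithm_params()`; the cited algorithms' own
publications are the source of the defaults, and nothing is hard-coded
elsewhere:

| parameter | default | meaning |
|---|---|---|
| `nonwear_window_min` | 60 min | zero-count run defining nonwear |
| `nonwear_spike_max` | 2 min | tolerated interrupt minutes per run |
| `nonwear_spike_ceiling` | 100 counts | maximum count in an interrupt |
| `sleep_coefficients` | 7.601, −0.065, −1.08, −0.056, −0.703 | the five-term actigraphic score |
| `sleep_window` | 8 PM–10 AM | nightly scoring window |
| `cutpoints` | 306 / 818 / 1969 counts per 5 s | light / moderate / vigorous boundaries |
| `min_wear_min` | 480 min | valid-day wear threshold |
| `reactivity_trim_days` | 3 | leading wear days dropped |
| `min_valid_days` | 4 | days to retain a participant |

Open points resolved here and flagged as decisions, not inferences:

* Sleep scoring is restricted to a nightly window (default 8 PM–10 AM) so
  long sedentary daytime stretches are not labelled naps; 24-h scoring is
  available (`sleep_window = NULL`).
* "First 3 days" trimming drops the first three *calendar days containing
  any wear* — reactivity is a property of study days, not of valid days.
* Counts exactly at a cutpoint go to the higher class (`>=`).
* Timestamps are local clock time; no DST arithmetic is attempted.

## The synthetic cohort

`sim_config()` defaults are the study conditions this package targets: 113
participants × 20 days at 5-s epochs; person-level mean daily MVPA Gamma
with mean 30.91 and SD 30.94 min; 37.2% male, 39.8% sports participants,
BMI 71.7 / 11.5 / 16.8%, 45.4% school days.

Generative law (recorded in the truth record): person means `M_i` are
Gamma, with sports participants' means scaled ×1.65 (population mean
preserved — sports participants are more active); daily MVPA is Gamma
around `M_i` with CV 0.5; that day's MVPA minutes are placed on the clock
with probability proportional to a circadian profile peaking at 5–7 PM,
circularly shifted per moderator (males −3 h, sports +1 h, school days
+1 h) plus a day-level N(0, 2 h) jitter; MVPA minutes carry epoch counts
above the moderate cutpoint; other worn minutes carry overdispersed
(gamma-mixed Poisson) low counts; overnight (11 PM–7 AM) minutes carry
near-zero counts that the sleep score labels sleep; nonwear blocks are
exact-zero daytime runs at about one per day.

The daytime profile and the day-level jitter were chosen so the *event
time* distribution resembles the published cohort's: most first-attainment
events in the late afternoon and evening, a thin but non-empty morning
tail. Without the jitter, morning hazards are numerically zero, morning
odds-ratio contrasts against the 8 AM reference are unidentified in
practice, and no moderator contrast can reach CI nonoverlap — a flatly
unrealistic regime.

What the generator does **not** emulate: raw 30 Hz waveforms (generation
starts at epoch counts), activity bouts and within-day autocorrelation of
MVPA placement beyond the hourly profile, seasonal structure, wear-time
habits that vary by person, or any MVPA–covariate correlation beyond the
sports volume effect and the timing shifts. Consequently, passing tests
demonstrate that the *pipeline* recovers what it is designed to recover
under a known law — not that real adolescent data meet these assumptions.
One practical consequence of the conservative CI-overlap rule is worth
stating plainly: at N = 113 the built-in sex timing shift is recovered as
a both-criteria decision point in most but not all cohort replicates;
replicates where it is missed are the expected behaviour of the rule, not
a pipeline defect.

Determinism: one master seed; per-participant sub-streams are derived
deterministically from it, so simulating 20 participants and the first 20
of 113 yield identical streams, and any fixed seed reproduces the cohort
bit-for-bit.

## Problem sizes in the test suite

The validation suites run at sizes chosen to give stable Monte-Carlo
verdicts while keeping the full suite a few minutes long: oracle
equivalence on 500 randomized series per classifier; Wald-coverage over
200 replications of 500 persons × 10 days (a 6-hour evening risk window,
where a degree-1 truth is well-identified); LRT null calibration over 500
replications of 100 persons × 5 days; selection consistency over 100
replications of 200 persons × 8 days with an asymmetric-peak cubic; and
one full 113 × 20 end-to-end run with byte-level determinism checks.

## Known limitations

* The event definition collapses a day to a single first-attainment time;
  intermittent accumulation patterns and multiple within-day episodes are
  out of scope.
* CI-overlap is conservative relative to a direct test on the OR
  difference; hours flagged significant are trustworthy, hours not flagged
  may still differ.
* The Wald machinery assumes the usual asymptotics; with very few events
  per hour the morning contrasts have huge variances (visible as extreme
  OR confidence bounds), which is reported honestly rather than smoothed.
* `sigma_u` is frequently estimated at the boundary (0) on synthetic
  cohorts whose between-person heterogeneity enters through `m_i` rather
  than through an explicit frailty — the fit then reduces to ordinary
  logistic regression, which is the correct behaviour.
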