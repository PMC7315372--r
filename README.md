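# mvpatiming

When during the day do adolescents accumulate their *own typical amount* of
moderate-to-vigorous physical activity (MVPA)? Answering that question from
wrist-accelerometer data gives digital physical-activity interventions
(JITAIs — just-in-time adaptive interventions) empirically grounded
*decision points*: hours at which a prompt to exercise is most likely to
land in a window where activity actually happens.

`mvpatiming` is an R package plus analysis workflow for exactly this
question. It is aimed at behavioral scientists working with epoch-level
accelerometer exports who want a tested, reproducible path from raw counts
to intervention decision points, and it ships a synthetic cohort generator
so every stage can be exercised and validated without access to raw cohort
data.

## The model

For participant *i*, let `m_i` be the mean of their daily MVPA minutes over
included days. On each monitored day the **event** is the first clock-hour
interval `t` ("Before *t*", i.e. the interval `(t-1:00, t:00]`) by which
cumulative MVPA since midnight reaches `m_i` (attainment, `>=`). Days that
never reach `m_i` inside the risk window (intervals ending 9 AM through
11 PM) are censored.

Stacking one row per person-day-hour at risk gives a person-period table on
which the discrete-time hazard

    h_i(t) = Pr(event in interval t | no earlier event, u_i)
    logit h_i(t) = b0 + b1 s + b2 s^2 + b3 s^3
                   + g' x_i + (d' x_i) s^k + u_i,     u_i ~ N(0, sigma_u^2)

is ordinary mixed-effects logistic regression: polynomial time (`s` an
affine recoding of `t`; the degree chosen by sequential likelihood-ratio
tests), moderator main effects and moderator-by-time interactions (sex, BMI
category, sports participation, school day — one model per moderator), and
a person-level random intercept estimated by adaptive Gauss–Hermite
quadrature (one node = the Laplace approximation).

Reported quantities per hour, at the median person (`u = 0`):

* **odds ratio** vs the 8 AM reference interval, `exp(eta(t) - eta(8))`,
  with 95% Wald CIs from the delta contrast;
* **hazard probability** `logit^{-1}(eta(t))`;
* **survival probability** — the probability the personal average is still
  unmet — the running product of complements of all earlier hazards.

Decision rules: the overall intervention window is the peak-hazard plateau
(hazards within a tolerance of the maximum; the steepest survival decline
is reported alongside). A moderator-specific window is emitted only when
(1) the groups' ORs have non-overlapping 95% CIs at one or more hours and
(2) the difference runs in the registered direction (sex and BMI are
exploratory; sports and school day carry directional hypotheses).

Upstream, epoch counts become valid-day summaries via the standard
adolescent wrist-accelerometry rules: nonwear = 60-min zero-count runs
(tolerating 2 interrupt minutes under 100 counts), sleep by the five-term
actigraphic linear score restricted to a nightly window, intensity by wrist
vector-magnitude cutpoints at their native 5-s epoch (moderate at 818
counts/5 s), valid day = at least 8 h wear, first 3 wear days trimmed for
measurement reactivity, and at least 4 valid days to retain a participant.
All constants live in `algorithm_params()` and are echoed in every output.

## Worked example

The package ships the published per-hour hazard/survival table of an
observed adolescent cohort as a plain-text reference. Reproducing its
survival arithmetic and decision windows:

```r
library(mvpatiming)

ref <- published_hazard_survival()
S <- survival_from_hazard(ref$hazard_prob)
round(S[ref$label == "Before 8 PM"], 2)
#> [1] 0.73        # 73% chance the personal average is still unmet after 8 PM

peak_hazard_window(ref)$label
#> [1] "Before 5 PM" "Before 6 PM" "Before 7 PM"

sw <- steepest_survival_decline(ref, span = 3)
c(sw$label[1], sw$label[4], attr(sw, "drop"))
#> [1] "Before 5 PM" "Before 8 PM" "0.12"   # the -12% late-afternoon drop
```

A full synthetic study — 113 adolescents, 20 days of 5-s epochs — runs
end-to-end in under a minute:

```r
cohort <- simulate_cohort(sim_config(seed = 1))
bundle <- run_pipeline(pipeline_config(out_dir = "out", nodes = 1, seed = 1),
                       cohort = cohort)
bundle$decisions
#> <decision_report>
#>   overall window (peak hazard): Before 9 PM - Before 10 PM
#>   steepest survival decline (-19%): Before 7 PM - Before 10 PM
#>   sex: criterion1=TRUE criterion2=TRUE window Before 8 PM - Before 11 PM
#>     non-overlapping CIs at Before 8 PM, Before 9 PM, Before 10 PM,
#>     Before 11 PM favor female, consistent with 'exploratory'; ...
#>   bmi_category: criterion1=FALSE criterion2=FALSE
#>   ...
```

The synthetic cohort peaks in the evening by design, so the derived window
sits later in the day; the sex timing shift built into the generator is
recovered as a significant group difference meeting both decision criteria.

## Analysis workflow

The numbered drivers under `analysis/` run the whole study on the synthetic
cohort, caching the raw cohort under `scratch/` and writing narrative
tables under `results/`:

    Rscript analysis/01_simulate.R      # cohort: counts, covariates, calendar
    Rscript analysis/02_preprocess.R    # wear/sleep/intensity -> day summaries
    Rscript analysis/03_events.R        # person means -> person-period risk set
    Rscript analysis/04_hazard.R        # degree selection + moderated models
    Rscript analysis/05_effects.R       # OR / hazard / survival tables
    Rscript analysis/06_decisions.R     # intervention decision points

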