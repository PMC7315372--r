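#' Configuration of the synthetic accelerometer cohort
#'
#' Defaults emulate the observational design the package analyses: 113
#' adolescents wearing a wrist accelerometer for 20 days, person-level daily
#' MVPA heterogeneity with grand mean about 31 min/day and between-person SD
#' about 31 min, an evening (5-8 PM) activity peak, overnight sleep, about
#' one nonwear block per day, and moderator-dependent shifts of the timing
#' profile (males and non-school days earlier, sports participants later and
#' with higher MVPA volume).
#'
#' @param n_participants number of participants.
#' @param n_days monitoring days per participant.
#' @param epoch_s epoch length in seconds (must divide 60; default the
#'   5-s native epoch of the intensity cutpoints).
#' @param circadian_profile nonnegative 24-vector of relative MVPA-allocation
#'   weight per clock hour (index 1 = hour starting midnight).
#' @param mvpa_mean_minutes population mean of person-level daily MVPA.
#' @param mvpa_between_sd between-person SD of the person-level means.
#' @param mvpa_within_cv day-level coefficient of variation around the
#'   person mean.
#' @param moderator_prevalences list: `male`, `sports`, `school_day`
#'   proportions and `bmi` (named 3-vector summing to 1).
#' @param timing_day_sd SD (hours) of the day-level random shift of the
#'   allocation profile, emulating day-to-day schedule variation; this is
#'   what spreads event times into the morning on some days.
#' @param timing_shift list of per-moderator circular hour shifts of the
#'   allocation profile (negative = earlier): `male`, `sports`,
#'   `school_day`, `overweight`, `obese`.
#' @param sports_mvpa_ratio multiplicative MVPA-volume effect of sports
#'   participation (population mean is preserved).
#' @param nonwear_rate expected nonwear blocks per day (Poisson).
#' @param sleep_hours `c(onset, offset)` clock hours of the overnight
#'   low-activity block.
#' @param seed RNG seed for the cohort stream; per-participant sub-streams
#'   are derived deterministically, so subsetting participants is
#'   reproducible.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 113,
                       n_days = 20,
                       epoch_s = 5,
                       circadian_profile = c(0, 0, 0, 0, 0, 0, 0.1,
                                             0.5, 0.9, 1.1, 1.2, 1.3, 1.4,
                                             1.5, 1.7, 2.2, 3, 4, 4.4, 4,
                                             2.8, 1.6, 0.6, 0),
                       timing_day_sd = 2,
                       mvpa_mean_minutes = 30.91,
                       mvpa_between_sd = 30.94,
                       mvpa_within_cv = 0.5,
                       moderator_prevalences = list(
                         male = 0.372, sports = 0.398, school_day = 0.454,
                         bmi = c(normal = 0.717, overweight = 0.115,
                                 obese = 0.168)),
                       timing_shift = list(male = -3, sports = 1,
                                           school_day = 1, overweight = 0,
                                           obese = 0),
                       sports_mvpa_ratio = 1.65,
                       nonwear_rate = 1,
                       sleep_hours = c(23, 7),
                       seed = 1L) {
  assert_that(n_participants > 0 && n_days > 0, "counts must be positive")
  assert_that(epoch_s > 0 && 60 %% epoch_s == 0,
              sprintf("epoch length %s s does not divide 60 s; cannot aggregate to minutes", epoch_s))
  assert_that(length(circadian_profile) == 24 &&
                all(circadian_profile >= 0),
              "circadian_profile must be 24 nonnegative weights")
  assert_that(mvpa_mean_minutes >= 0 && mvpa_between_sd > 0 &&
                mvpa_within_cv > 0, "MVPA moments out of range")
  pr <- moderator_prevalences
  assert_that(all(unlist(pr[c("male", "sports", "school_day")]) >= 0 &
                    unlist(pr[c("male", "sports", "school_day")]) <= 1),
              "prevalences must be in [0, 1]")
  assert_that(abs(sum(pr$bmi) - 1) < 1e-8 && all(pr$bmi >= 0) &&
                all(c("normal", "overweight", "obese") %in% names(pr$bmi)),
              "BMI category proportions must be named and sum to 1")
  assert_that(nonwear_rate >= 0, "nonwear_rate must be nonnegative")
  assert_that(sports_mvpa_ratio > 0, "sports_mvpa_ratio must be positive")
  structure(list(n_participants = as.integer(n_participants),
                 n_days = as.integer(n_days), epoch_s = as.integer(epoch_s),
                 circadian_profile = circadian_profile,
                 mvpa_mean_minutes = mvpa_mean_minutes,
                 mvpa_between_sd = mvpa_between_sd,
                 mvpa_within_cv = mvpa_within_cv,
                 timing_day_sd = timing_day_sd,
                 moderator_prevalences = pr,
                 timing_shift = timing_shift,
                 sports_mvpa_ratio = sports_mvpa_ratio,
                 nonwear_rate = nonwear_rate,
                 sleep_hours = sleep_hours,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a synthetic accelerometer cohort
#'
#' Generates epoch-level count streams (one [epoch_series] per
#' participant-day), a participant covariate table and a school-day
#' calendar, with a known generative law recorded in the truth record:
#' person-level mean daily MVPA `M_i` is Gamma with the configured
#' population mean and SD (sports participants scaled by
#' `sports_mvpa_ratio`, population mean preserved); daily MVPA minutes are
#' Gamma around `M_i` with CV `mvpa_within_cv`, allocated to clock minutes
#' with probability proportional to the (moderator-shifted) circadian
#' profile; MVPA minutes carry epoch counts above the moderate cutpoint,
#' other worn minutes overdispersed (gamma-mixed Poisson) low counts,
#' overnight minutes low counts that score as sleep, and nonwear blocks are
#' runs of exact zeros. Fixing the seed reproduces the cohort bit-for-bit.
#'
#' @param config a [sim_config].
#' @param params an [algorithm_params] (supplies the cutpoints the counts
#'   are calibrated against).
#' @return list with `covariates`, `calendar`, `series` (list of
#'   [epoch_series]) and `truth` (generative law and per-person targets).
#' @export
simulate_cohort <- function(config = sim_config(),
                            params = algorithm_params()) {
  stopifnot(inherits(config, "sim_config"))
  epochs_per_min <- 60L %/% config$epoch_s
  n_epoch <- 86400L %/% config$epoch_s
  cp <- params$cutpoints
  active <- any(config$circadian_profile > 0)
  p_max <- if (active) max(config$circadian_profile) else 1
  pr <- config$moderator_prevalences

  set.seed(config$seed)
  dates <- as.Date("2015-06-01") + seq_len(config$n_days) - 1L
  calendar <- data.frame(date = dates,
                         is_school_day = stats::rbinom(config$n_days, 1,
                                                       pr$school_day) == 1)

  ## sports-group means preserving the population mean
  p_sports <- pr$sports
  r <- config$sports_mvpa_ratio
  mean_non <- config$mvpa_mean_minutes / (1 + p_sports * (r - 1))
  shape <- if (config$mvpa_mean_minutes > 0)
    (config$mvpa_mean_minutes / config$mvpa_between_sd)^2 else 1

  sl_from <- config$sleep_hours[1]; sl_to <- config$sleep_hours[2]
  hr_of_min <- rep(0:23, each = 60L)
  sleep_min <- if (sl_from <= sl_to) hr_of_min >= sl_from & hr_of_min < sl_to
  else hr_of_min >= sl_from | hr_of_min < sl_to

  covs <- vector("list", config$n_participants)
  series <- vector("list", config$n_participants * config$n_days)
  person_truth <- vector("list", config$n_participants)

  for (i in seq_len(config$n_participants)) {
    set.seed(derive_seed(config$seed, i))
    pid <- sprintf("P%03d", i)
    sex <- if (stats::runif(1) < pr$male) "male" else "female"
    sports <- as.integer(stats::runif(1) < p_sports)
    bmi <- sample(names(pr$bmi), 1, prob = pr$bmi)
    M_i <- if (config$mvpa_mean_minutes > 0)
      max(2, stats::rgamma(1, shape = shape,
                           scale = mean_non * ifelse(sports == 1, r, 1) / shape))
    else 0
    shift_base <- config$timing_shift$male * (sex == "male") +
      config$timing_shift$sports * sports +
      config$timing_shift$overweight * (bmi == "overweight") +
      config$timing_shift$obese * (bmi == "obese")
    covs[[i]] <- data.frame(participant_id = pid, sex = sex,
                            bmi_category = bmi, sports = sports,
                            stringsAsFactors = FALSE)
    person_truth[[i]] <- data.frame(participant_id = pid, M_i = M_i,
                                    shift_base = shift_base,
                                    stringsAsFactors = FALSE)

    for (j in seq_len(config$n_days)) {
      shift <- round(shift_base +
                       config$timing_shift$school_day *
                       calendar$is_school_day[j] +
                       stats::rnorm(1, 0, config$timing_day_sd))
      prof <- config$circadian_profile[((0:23 - shift) %% 24) + 1L]

      ## nonwear blocks: exact-zero runs in the daytime
      nonwear_min <- logical(1440)
      n_blk <- stats::rpois(1, config$nonwear_rate)
      if (n_blk > 0) for (b in seq_len(n_blk)) {
        dur <- round(stats::runif(1, 60, 150))
        start <- floor(stats::runif(1, 420, 1320 - dur))
        nonwear_min[start:(start + dur - 1L)] <- TRUE
      }

      ## baseline per-minute intensity (counts/epoch), gamma-mixed Poisson
      lam_epoch <- ifelse(sleep_min, 0.25 * active,
                          (10 + 60 * prof[hr_of_min + 1L] / p_max) * active)
      g <- stats::rgamma(1440, shape = 3, rate = 3)
      lam_epoch <- lam_epoch * g
      counts <- stats::rpois(n_epoch, rep(lam_epoch, each = epochs_per_min))

      ## allocate the day's MVPA minutes over awake, worn minutes
      if (M_i > 0) {
        cv <- config$mvpa_within_cv
        D <- stats::rgamma(1, shape = 1 / cv^2, scale = M_i * cv^2)
        w <- ifelse(sleep_min | nonwear_min, 0, prof[hr_of_min + 1L])
        m_alloc <- min(round(D), sum(w > 0))
        if (m_alloc > 0) {
          chosen <- sample(seq_len(1440), m_alloc, prob = w)
          ep_idx <- as.vector(outer(seq_len(epochs_per_min),
                                    (chosen - 1L) * epochs_per_min, `+`))
          counts[ep_idx] <- round(stats::runif(length(ep_idx),
                                               cp["moderate"],
                                               1.3 * cp["vigorous"]))
        }
      }
      counts[rep(nonwear_min, each = epochs_per_min)] <- 0L

      series[[(i - 1L) * config$n_days + j]] <-
        epoch_series(pid, dates[j], config$epoch_s, counts)
    }
  }

  truth <- list(
    law = paste("M_i ~ Gamma(mean by sports group, population mean",
                "preserved); daily MVPA ~ Gamma(mean = M_i, cv =",
                config$mvpa_within_cv, "); minutes allocated ~ shifted",
                "circadian profile; baseline counts gamma(3,3)-mixed",
                "Poisson; nonwear = exact-zero runs"),
    config = config,
    cutpoints_used = cp,
    persons = do.call(rbind, person_truth))

  list(covariates = do.call(rbind, covs), calendar = calendar,
       series = series, truth = truth)
}

#' A known discrete-time hazard model for simulation
#'
#' The generative law of [simulate_person_period]: on the internal time
#' scale `s = (t - time_ref) / time_scale`, the log-odds of the event at
#' interval `t` (given no earlier event) are
#' `beta` applied to `(1, s, ..., s^degree, covariates,
#' covariate-by-s interactions)` plus a person random intercept
#' `u_i ~ N(0, sigma_u^2)`.
#'
#' @param degree polynomial degree 1-3.
#' @param beta named coefficients: `(Intercept)`, `time1..time<degree>`,
#'   optionally covariate dummies (`sexmale`, `sports1`, ...) and
#'   interactions (`sexmale_x_time1`, ...).
#' @param sigma_u SD of the person random intercept (log-odds scale).
#' @param risk_window `c(first, last)` interval indices in 1..24.
#' @param time_ref,time_scale the affine time coding.
#' @return object of class `true_hazard_model`.
#' @export
true_hazard_model <- function(degree, beta, sigma_u = 0,
                              risk_window = c(9, 23),
                              time_ref = 8, time_scale = 10) {
  assert_that(degree %in% 1:3, "degree must be 1-3")
  tnames <- paste0("time", seq_len(degree))
  assert_that(all(c("(Intercept)", tnames) %in% names(beta)),
              "beta must name (Intercept) and every time power up to the degree")
  assert_that(!any(grepl(paste0("time", degree + 1), names(beta))),
              "beta has time terms above the stated degree")
  assert_that(sigma_u >= 0, "sigma_u must be nonnegative")
  assert_that(risk_window[1] >= 1 && risk_window[2] <= 24 &&
                risk_window[1] <= risk_window[2],
              "risk window must be nonempty within interval indices 1..24")
  structure(list(degree = as.integer(degree), beta = beta,
                 sigma_u = sigma_u, risk_window = risk_window,
                 time_ref = time_ref, time_scale = time_scale),
            class = "true_hazard_model")
}

## dummies used by the generator for sampled covariates
dummies_from_covariates <- function(df) {
  out <- NULL
  if (!is.null(df$sex))
    out <- cbind(out, sexmale = as.numeric(df$sex == "male"))
  if (!is.null(df$bmi_category))
    out <- cbind(out,
                 bmioverweight = as.numeric(df$bmi_category == "overweight"),
                 bmiobese = as.numeric(df$bmi_category == "obese"))
  if (!is.null(df$sports))
    out <- cbind(out, sports1 = as.numeric(df$sports == 1))
  if (!is.null(df$school_day))
    out <- cbind(out, schoolday1 = as.numeric(df$school_day == 1))
  out
}

#' Simulate a person-period table from a known hazard model
#'
#' For each person, one random intercept `u_i` is drawn; for each day the
#' generator walks the hours of the risk window and emits the event at hour
#' `t` with probability `logit^{-1}(eta(t) + u_i)`, stopping at the event or
#' censoring at the window end. The returned truth record carries the model
#' so estimation can be checked against it.
#'
#' @param model a [true_hazard_model].
#' @param n_participants,n_days cohort dimensions.
#' @param covariate_sampler optional `function(n)` returning a data.frame of
#'   person-level covariates (`sex`, `bmi_category`, `sports`,
#'   `school_day`) for the `n` participants; omit for a covariate-free
#'   model.
#' @param seed RNG seed.
#' @return list `pp` (person-period data.frame with attributes as in
#'   [build_person_period]) and `truth`.
#' @export
simulate_person_period <- function(model, n_participants, n_days,
                                   covariate_sampler = NULL, seed = 1L) {
  stopifnot(inherits(model, "true_hazard_model"))
  assert_that(model$risk_window[1] <= model$risk_window[2],
              "empty risk window")
  set.seed(seed)
  t_seq <- model$risk_window[1]:model$risk_window[2]
  s <- (t_seq - model$time_ref) / model$time_scale
  eta_time <- model$beta[["(Intercept)"]] +
    Reduce(`+`, lapply(seq_len(model$degree), function(k)
      model$beta[[paste0("time", k)]] * s^k))

  covs <- if (!is.null(covariate_sampler)) covariate_sampler(n_participants)
  D <- if (!is.null(covs)) dummies_from_covariates(covs)

  ## per-person hazard over the window (random intercept + covariates)
  H <- length(t_seq)
  u <- stats::rnorm(n_participants, 0, model$sigma_u)
  hmat <- vapply(seq_len(n_participants), function(i) {
    eta <- eta_time + u[i]
    if (!is.null(D)) {
      bval <- function(nm) if (nm %in% names(model$beta))
        model$beta[[nm]] else 0
      for (d in colnames(D)) {
        eta <- eta + bval(d) * D[i, d]
        for (k in seq_len(model$degree)) {
          bint <- bval(paste0(d, "_x_time", k))
          if (bint != 0) eta <- eta + bint * D[i, d] * s^k
        }
      }
    }
    inv_logit(eta)
  }, numeric(H))

  ## one Bernoulli walk per person-day; the first success is the event
  n_cells <- n_participants * n_days
  p_long <- as.vector(hmat[, rep(seq_len(n_participants), each = n_days)])
  y <- matrix(stats::rbinom(H * n_cells, 1L, p_long), nrow = H)
  hit <- rep(NA_integer_, n_cells)
  w <- which(y == 1L, arr.ind = TRUE)
  if (nrow(w)) {
    first <- tapply(w[, 1], w[, 2], min)
    hit[as.integer(names(first))] <- as.integer(first)
  }
  n_rows <- ifelse(is.na(hit), H, hit)
  person_of_cell <- rep(seq_len(n_participants), each = n_days)
  day_of_cell <- rep(seq_len(n_days), times = n_participants)
  pp <- data.frame(
    participant_id = sprintf("P%04d", rep(person_of_cell, n_rows)),
    day = rep(day_of_cell, n_rows),
    t = t_seq[sequence(n_rows)],
    event = 0L, stringsAsFactors = FALSE)
  last_row <- cumsum(n_rows)
  pp$event[last_row[!is.na(hit)]] <- 1L
  if (!is.null(covs))
    for (cn in names(covs))
      pp[[cn]] <- covs[[cn]][rep(person_of_cell, n_rows)]
  attr(pp, "risk_window") <- model$risk_window
  attr(pp, "convention") <- interval_convention()
  list(pp = pp, truth = list(model = model, seed = seed,
                             covariates = covs))
}
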