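test_that("person means average daily MVPA and flag degenerate participants", {
  days <- rbind(make_day("A", "2020-01-01", c(rep(0, 23), 0) + 20 / 24),
                make_day("A", "2020-01-02", rep(30 / 24, 24)),
                make_day("A", "2020-01-03", rep(40 / 24, 24)),
                make_day("B", "2020-01-01", rep(0, 24)),
                make_day("B", "2020-01-02", rep(0, 24)))
  m <- person_mean_mvpa(days)
  expect_equal(m$mean_mvpa[m$participant_id == "A"], 30)
  expect_equal(m$n_days[m$participant_id == "A"], 3)
  expect_true(m$degenerate[m$participant_id == "B"])
  expect_false(m$degenerate[m$participant_id == "A"])
  expect_error(person_mean_mvpa(days[0, ]), "no included days")
})

test_that("event hour is the first interval whose cumulative MVPA attains the mean", {
  ## cumulative 5,10,20,35 against mean 30: event in the 4th interval
  h <- c(5, 5, 10, 15, rep(0, 20))
  expect_equal(code_event_hour(h, 30, c(1, 24)),
               list(status = "event", hour = 4L))
  ## day total below the mean: censored
  expect_equal(code_event_hour(c(rep(1, 24)) * 25 / 24, 30)$status, "censored")
  ## exact attainment counts (>= tie rule)
  h2 <- rep(0, 24); h2[10] <- 30
  expect_equal(code_event_hour(h2, 30)$hour, 10L)
  ## attainment before the window opens is flagged, not modeled
  h3 <- rep(0, 24); h3[6] <- 50
  expect_equal(code_event_hour(h3, 30)$status, "pre_window")
  expect_error(code_event_hour(c(-1, rep(1, 23)), 10), "negative")
})

test_that("event coding equals a naive linear-scan oracle on random days", {
  set.seed(606)
  for (r in 1:2000) {
    h <- round(runif(24) * sample(c(0, 1, 3, 8), 24, replace = TRUE), 1)
    m <- runif(1, 0.5, 60)
    got <- code_event_hour(h, m)
    want <- oracle_event_hour(h, m)
    expect_identical(got$status, want$status)
    if (got$status == "event") expect_equal(got$hour, want$hour)
  }
})

test_that("person-period rows stop at the event and carry covariates", {
  days <- rbind(make_day("A", "2020-01-01",
                         c(rep(0, 9), 20, 20, rep(0, 13))),   # event at t=11
                make_day("A", "2020-01-02", rep(0.5, 24)))    # total 12 < 30
  days$is_school_day <- c(TRUE, FALSE)
  means <- data.frame(participant_id = "A", mean_mvpa = 30, n_days = 2,
                      degenerate = FALSE)
  pp <- build_person_period(days, means, make_covs("A", sex = "male"),
                            risk_window = c(9, 23))
  d1 <- pp[pp$date == as.Date("2020-01-01"), ]
  expect_equal(d1$t, 9:11)
  expect_equal(d1$event, c(0, 0, 1))
  expect_true(all(d1$school_day == 1))
  d2 <- pp[pp$date == as.Date("2020-01-02"), ]
  expect_equal(d2$t, 9:23)                      # censored: full window
  expect_equal(sum(d2$event), 0)
  expect_true(all(pp$sex == "male"))
  expect_error(build_person_period(days, means, make_covs("ZZZ")),
               "covariates missing.*A")
})

test_that("degenerate participants and pre-window or wear-free days are excluded with a log", {
  days <- rbind(make_day("A", "2020-01-01", c(rep(0, 5), 50, rep(0, 18))),
                make_day("A", "2020-01-02", c(rep(0, 17), 40, rep(0, 6))),
                make_day("B", "2020-01-01", rep(0, 24)))
  means <- data.frame(participant_id = c("A", "B"), mean_mvpa = c(30, 0),
                      n_days = c(2, 1), degenerate = c(FALSE, TRUE))
  pp <- build_person_period(days, means, make_covs(c("A", "B")))
  expect_true(all(pp$participant_id == "A"))
  lg <- attr(pp, "log")
  expect_true("degenerate_zero_mean" %in% lg$reason)
  expect_true("event_before_window" %in% lg$reason)
  ## the pre-window day contributes no rows; the evening-event day does
  expect_equal(unique(format(pp$date)), "2020-01-02")
})

test_that("row counts, risk-set monotonicity and status round-trip hold on random cohorts", {
  set.seed(707)
  for (r in 1:10) {
    n_p <- sample(3:8, 1)
    days <- do.call(rbind, lapply(seq_len(n_p), function(i) {
      do.call(rbind, lapply(1:6, function(j) {
        h <- round(runif(24) * sample(c(0, 2, 6), 24, replace = TRUE), 1)
        make_day(sprintf("P%02d", i), as.Date("2020-01-01") + j - 1, h)
      }))
    }))
    means <- person_mean_mvpa(days)
    means$mean_mvpa <- pmax(means$mean_mvpa, 0.5)
    means$degenerate <- FALSE
    covs <- make_covs(unique(days$participant_id))
    pp <- build_person_period(days, means, covs, risk_window = c(9, 23))

    ## per-day oracle over the day summaries
    expected_rows <- 0L
    for (k in seq_len(nrow(days))) {
      ev <- oracle_event_hour(as.numeric(days[k, paste0("h", 0:23)]),
                              means$mean_mvpa[means$participant_id ==
                                                days$participant_id[k]])
      expected_rows <- expected_rows +
        switch(ev$status, event = ev$hour - 8L, censored = 15L,
               pre_window = 0L)
    }
    expect_equal(nrow(pp), expected_rows)

    ## monotone risk set
    at_risk <- table(factor(pp$t, levels = 9:23))
    expect_true(all(diff(as.numeric(at_risk)) <= 0))

    ## at most one terminal event per day
    by_day <- split(pp, paste(pp$participant_id, pp$date))
    for (d in by_day) {
      expect_true(all(diff(d$t) == 1))
      expect_lte(sum(d$event), 1)
      if (sum(d$event) == 1) expect_equal(which(d$event == 1), nrow(d))
      ## round-trip: censor status recoverable from the rows
      status <- if (sum(d$event) == 1) "event" else "censored"
      ev <- oracle_event_hour(as.numeric(
        days[days$participant_id == d$participant_id[1] &
               days$date == d$date[1], paste0("h", 0:23)]),
        means$mean_mvpa[means$participant_id == d$participant_id[1]])
      expect_identical(status, ev$status)
    }
  }
})
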