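test_that("nonwear rule flags zero runs, tolerates interrupts, respects the ceiling", {
  p <- algorithm_params()
  x <- c(rep(500, 10), rep(0, 90), rep(500, 10))
  m <- detect_nonwear(x, p)
  expect_equal(which(m), 11:100)

  ## 60-min zero run with one sub-ceiling interrupt is still nonwear
  x2 <- c(rep(0, 30), 50, rep(0, 30), rep(400, 10))
  expect_true(all(detect_nonwear(x2, p)[1:61]))

  ## an interrupt at or above the ceiling splits the run
  x3 <- c(rep(0, 30), 100, rep(0, 30), rep(400, 10))
  expect_false(any(detect_nonwear(x3, p)))

  ## 59 zeros are not enough
  expect_false(any(detect_nonwear(c(rep(0, 59), rep(300, 20)), p)))

  expect_error(detect_nonwear(c(-1, 0, 0), p), "negative")
})

test_that("nonwear mask equals the exhaustive window-scan oracle on random series", {
  p <- algorithm_params()
  set.seed(101)
  for (r in 1:120) {
    n <- sample(80:200, 1)
    ## zero-inflated counts so long zero runs actually occur
    x <- ifelse(runif(n) < 0.55, 0,
                sample(c(1, 40, 99, 100, 150, 900), n, replace = TRUE))
    expect_identical(detect_nonwear(x, p), oracle_nonwear(x, p))
  }
})

test_that("sleep scoring labels quiet nights sleep, active stretches wake", {
  p24 <- algorithm_params(sleep_window = NULL)
  expect_true(all(score_sleep(rep(0, 480), p24)))
  expect_false(any(score_sleep(rep(400, 480), p24)))
  expect_error(score_sleep(rep(0, 10), p24), "shorter")
})

test_that("sleep score equals a naive minute-by-minute recomputation", {
  p24 <- algorithm_params(sleep_window = NULL)
  set.seed(202)
  for (r in 1:60) {
    n <- sample(30:150, 1)
    x <- sample(c(0, 0, 0, 5, 20, 60, 90, 150, 600), n, replace = TRUE)
    expect_identical(score_sleep(x, p24), oracle_sleep(x, p24))
  }
})

test_that("nightly scoring window masks daytime minutes as wake", {
  p <- algorithm_params(sleep_window = c(20, 10))
  x <- rep(0, 1440)                       # a fully quiet day
  s <- score_sleep(x, p, minute_of_day = 0:1439)
  hr <- rep(0:23, each = 60)
  expect_true(all(s[hr >= 20 | hr < 10]))
  expect_false(any(s[hr >= 10 & hr < 20]))
})

test_that("intensity classification respects the >= boundary convention", {
  p <- algorithm_params()
  lab <- classify_intensity(c(0, 305, 306, 817, 818, 1968, 1969), p,
                            epoch_s = 5)
  expect_equal(as.character(lab),
               c("sedentary", "sedentary", "light", "light", "moderate",
                 "moderate", "vigorous"))
  expect_error(
    classify_intensity(1:4, algorithm_params(cutpoints = c(light = 500,
                                                           moderate = 300,
                                                           vigorous = 900)),
                       epoch_s = 5),
    "increasing")
})

test_that("finer epochs are re-aggregated by summation; coarser rejected", {
  p <- algorithm_params()     # native 5 s
  x1s <- rep(200, 10)         # 1-s epochs -> two 5-s epochs of 1000
  lab <- classify_intensity(x1s, p, epoch_s = 1)
  expect_length(lab, 2)
  expect_equal(as.character(lab), c("moderate", "moderate"))
  expect_error(classify_intensity(rep(100, 4), p, epoch_s = 60), "coarser")
})

test_that("random intensity vectors match the elementwise oracle", {
  p <- algorithm_params()
  set.seed(303)
  x <- sample(0:2500, 600, replace = TRUE)
  expect_equal(as.character(classify_intensity(x, p, epoch_s = 5)),
               oracle_intensity(x, p))
})

test_that("day summary counts only worn, awake MVPA and conserves hourly totals", {
  p <- algorithm_params()
  cal <- data.frame(date = as.Date("2020-01-06"), is_school_day = TRUE)
  ## constructed day: 60 MVPA minutes 18:00-19:00, rest light activity
  counts <- rep(50L, 17280)
  mvpa_idx <- (18 * 3600 / 5 + 1):(19 * 3600 / 5)
  counts[mvpa_idx] <- 1000L
  s <- epoch_series("A", "2020-01-06", 5, counts)
  nw <- rep(FALSE, 1440); sl <- rep(FALSE, 1440)
  lab <- classify_intensity(s$counts, p, epoch_s = 5)
  d <- summarize_day(s, nw, sl, lab, cal, p)
  expect_equal(d$mvpa_minutes, 60)
  expect_equal(d$h18, 60)
  expect_equal(sum(as.numeric(d[paste0("h", c(0:17, 19:23))])), 0)
  expect_equal(d$wear_minutes, 1440)
  expect_true(d$is_school_day)

  ## an all-nonwear day has no wear and is invalid
  d0 <- summarize_day(s, rep(TRUE, 1440), sl, lab, cal, p)
  expect_equal(d0$wear_minutes, 0)
  expect_equal(d0$mvpa_minutes, 0)
  expect_false(d0$is_valid)

  ## a sleeping minute removes its MVPA epochs too (mask exclusivity)
  sl2 <- rep(FALSE, 1440); sl2[(18 * 60 + 1):(18 * 60 + 30)] <- TRUE
  d2 <- summarize_day(s, nw, sl2, lab, cal, p)
  expect_equal(d2$mvpa_minutes, 30)
  expect_equal(d2$wear_minutes, 1410)

  expect_error(summarize_day(s, nw, sl, lab,
                             data.frame(date = as.Date("1999-01-01"),
                                        is_school_day = FALSE), p),
               "calendar")
})

test_that("hourly MVPA sums to the daily total on random days", {
  p <- algorithm_params()
  cal <- data.frame(date = as.Date("2020-01-06"), is_school_day = FALSE)
  set.seed(404)
  for (r in 1:25) {
    counts <- sample(c(0L, 50L, 400L, 1000L, 2200L), 17280, replace = TRUE,
                     prob = c(0.4, 0.3, 0.15, 0.1, 0.05))
    s <- epoch_series("A", "2020-01-06", 5, counts)
    mc <- minute_counts(s)
    nw <- detect_nonwear(mc, p)
    sl <- score_sleep(mc, p)
    lab <- classify_intensity(counts, p, epoch_s = 5)
    d <- summarize_day(s, nw, sl, lab, cal, p)
    expect_equal(sum(as.numeric(d[paste0("h", 0:23)])), d$mvpa_minutes)
    expect_true(all(as.numeric(d[paste0("h", 0:23)]) <= 60 + 1e-12))
    expect_true(d$mvpa_minutes <= d$wear_minutes)
  }
})

test_that("inclusion rules: 8-h boundary, leading-day trim, minimum valid days", {
  p <- algorithm_params()
  days <- do.call(rbind, lapply(1:20, function(i)
    make_day("A", as.Date("2020-01-01") + i - 1, rep(1, 24),
             hourly_wear = rep(25, 24))))   # 600 wear min, all valid
  days$wear_minutes[5] <- 479               # below the 8-h boundary
  days[5, paste0("w", 0:23)] <- as.list(c(rep(20, 23), 19 + 0.9))
  res <- apply_inclusion_rules(days, p)
  expect_equal(nrow(res$summaries), 16)     # 20 - 3 trimmed - 1 short
  expect_setequal(res$log$rule[res$log$date %in% days$date[1:3]],
                  "reactivity_trim")
  expect_true(any(res$log$rule == "insufficient_wear" &
                    res$log$date == days$date[5]))

  ## exactly 480 minutes is kept
  days2 <- days; days2$wear_minutes[5] <- 480
  expect_equal(nrow(apply_inclusion_rules(days2, p)$summaries), 17)

  ## a participant left with 3 valid days is excluded entirely
  short <- do.call(rbind, lapply(1:6, function(i)
    make_day("B", as.Date("2020-01-01") + i - 1, rep(1, 24),
             hourly_wear = rep(25, 24))))
  res2 <- apply_inclusion_rules(short, p)
  expect_equal(nrow(res2$summaries), 0)
  expect_true(any(res2$log$rule == "too_few_valid_days"))
})

test_that("inclusion rules are idempotent and tolerate empty input", {
  p <- algorithm_params()
  days <- do.call(rbind, lapply(1:10, function(i)
    make_day("A", as.Date("2020-01-01") + i - 1, rep(1, 24),
             hourly_wear = rep(25, 24))))
  once <- apply_inclusion_rules(days, p)$summaries
  twice <- apply_inclusion_rules(once, p)$summaries
  expect_identical(once, twice)
  empty <- apply_inclusion_rules(days[0, ], p)
  expect_equal(nrow(empty$log), 0)
})

test_that("trimming drops exactly the first wear days found by a brute-force filter", {
  p <- algorithm_params()
  set.seed(505)
  days <- do.call(rbind, lapply(1:20, function(i)
    make_day("C", as.Date("2020-03-01") + i - 1, rep(1, 24),
             hourly_wear = rep(sample(18:30, 1), 24))))
  res <- apply_inclusion_rules(days, p)
  wear_days <- days$date[days$wear_minutes > 0]
  expected_drop <- head(wear_days, 3)
  expect_true(all(!expected_drop %in% res$summaries$date))
  kept_expected <- setdiff(days$date[days$wear_minutes >= 480],
                           expected_drop)
  expect_setequal(as.numeric(res$summaries$date), as.numeric(kept_expected))
})
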