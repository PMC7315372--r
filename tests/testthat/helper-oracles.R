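# Independent brute-force oracles for the classification and modeling steps.
# These deliberately use naive scans / explicit loops, not the package's
# algorithms, so agreement is evidence and not tautology.

## nonwear: exhaustive window scan -- a minute is nonwear iff some window
## [i, j] covers it with c[i] = c[j] = 0, all counts < ceiling, at most
## spike_max nonzero minutes, and length >= win.
oracle_nonwear <- function(counts, params) {
  n <- length(counts)
  win <- params$nonwear_window_min
  ceiling_ <- params$nonwear_spike_ceiling
  spike_max <- params$nonwear_spike_max
  mask <- logical(n)
  for (i in seq_len(n)) {
    if (counts[i] != 0) next
    nonzero <- 0L
    last_ok <- NA_integer_
    j <- i
    while (j <= n) {
      if (counts[j] != 0) {
        if (counts[j] >= ceiling_) break
        nonzero <- nonzero + 1L
        if (nonzero > spike_max) break
      } else {
        last_ok <- j
      }
      j <- j + 1L
    }
    if (!is.na(last_ok) && last_ok - i + 1L >= win)
      mask[i:last_ok] <- TRUE
  }
  mask
}

## sleep score: direct per-minute recomputation with explicit zero padding
oracle_sleep <- function(counts, params) {
  n <- length(counts)
  b <- params$sleep_coefficients
  band <- params$sleep_nat_range
  at <- function(k) if (k < 1 || k > n) 0 else counts[k]
  out <- logical(n)
  for (i in seq_len(n)) {
    w11 <- vapply((i - 5):(i + 5), at, numeric(1))
    w6 <- vapply((i - 5):i, at, numeric(1))
    si <- b[["intercept"]] + b[["avg"]] * mean(w11) +
      b[["nat"]] * sum(w11 >= band[1] & w11 < band[2]) +
      b[["sd"]] * sd(w6) + b[["lg"]] * log(counts[i] + 1)
    out[i] <- si >= params$sleep_threshold
  }
  out
}

## intensity: explicit if-chain per element (counts already at native epoch)
oracle_intensity <- function(counts, params) {
  cp <- params$cutpoints
  vapply(counts, function(x) {
    if (x >= cp[["vigorous"]]) "vigorous"
    else if (x >= cp[["moderate"]]) "moderate"
    else if (x >= cp[["light"]]) "light"
    else "sedentary"
  }, character(1))
}

## event hour: naive linear scan of the cumulative sum
oracle_event_hour <- function(hourly, mean_mvpa, win = c(9, 23)) {
  acc <- 0
  for (t in 1:24) {
    acc <- acc + hourly[t]
    if (acc >= mean_mvpa) {
      if (t < win[1]) return(list(status = "pre_window", hour = t))
      if (t > win[2]) return(list(status = "censored", hour = NA))
      return(list(status = "event", hour = t))
    }
  }
  list(status = "censored", hour = NA)
}

## plain logistic regression by Newton-Raphson/IRLS on the raw design
newton_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    p <- plogis(drop(X %*% beta))
    W <- p * (1 - p)
    step <- solve(crossprod(X, X * W), crossprod(X, y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

## tiny valid day-summary row builder for constructed scenarios
make_day <- function(pid, date, hourly_mvpa, hourly_wear = rep(60, 24),
                     school = FALSE) {
  out <- data.frame(participant_id = pid, date = as.Date(date),
                    wear_minutes = sum(hourly_wear),
                    mvpa_minutes = sum(hourly_mvpa),
                    is_valid = sum(hourly_wear) >= 480,
                    is_school_day = school,
                    trimmed_for_reactivity = FALSE,
                    stringsAsFactors = FALSE)
  out[paste0("h", 0:23)] <- as.list(hourly_mvpa)
  out[paste0("w", 0:23)] <- as.list(hourly_wear)
  out
}

## one-participant covariate row
make_covs <- function(pids, sex = "female", bmi = "normal", sports = 0) {
  data.frame(participant_id = pids, sex = sex, bmi_category = bmi,
             sports = sports, stringsAsFactors = FALSE)
}
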