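#' Person-specific average daily MVPA
#'
#' The arithmetic mean of daily MVPA minutes over a participant's included
#' (valid, post-trim) days. This person mean `m_i` is the event threshold for
#' the survival analysis: the event on a given day is the first hour by which
#' cumulative MVPA reaches `m_i`.
#'
#' @param summaries day-summary rows for the cohort (after
#'   [apply_inclusion_rules]).
#' @return data.frame `participant_id`, `mean_mvpa`, `n_days`, `degenerate`
#'   (`TRUE` when the mean is 0, i.e. no MVPA on any included day).
#' @export
person_mean_mvpa <- function(summaries) {
  assert_that(!is.null(summaries) && nrow(summaries) > 0,
              "no included days: cannot compute person means")
  agg <- stats::aggregate(mvpa_minutes ~ participant_id, data = summaries,
                          FUN = mean)
  n <- stats::aggregate(mvpa_minutes ~ participant_id, data = summaries,
                        FUN = length)
  out <- data.frame(participant_id = agg$participant_id,
                    mean_mvpa = agg$mvpa_minutes,
                    n_days = n$mvpa_minutes,
                    stringsAsFactors = FALSE)
  out$degenerate <- out$mean_mvpa <= 0
  out
}

#' Code the event hour for one day
#'
#' The event hour is the smallest interval index `t` (interval `(t-1, t]`)
#' whose cumulative MVPA from midnight reaches the person mean; attainment is
#' `>=` (reaching the average exactly counts). Days that never reach the mean
#' by the end of the risk window are censored; days that reach it before the
#' risk window opens are flagged `pre_window` and excluded from the risk set
#' (they carry no within-window risk information).
#'
#' @param hourly_mvpa numeric 24-vector of MVPA minutes per clock hour
#'   (index 1 = hour starting 00:00).
#' @param mean_mvpa the person mean `m_i` (minutes, > 0).
#' @param risk_window integer `c(first, last)` interval indices at risk
#'   (default intervals ending 9 AM through 11 PM).
#' @return list with `status` (`"event"`, `"censored"` or `"pre_window"`)
#'   and `hour` (the event interval index, or `NA` when censored).
#' @export
code_event_hour <- function(hourly_mvpa, mean_mvpa, risk_window = c(9, 23)) {
  assert_that(length(hourly_mvpa) == 24 && !anyNA(hourly_mvpa),
              "hourly_mvpa must be a complete 24-vector")
  assert_that(all(hourly_mvpa >= 0), "negative hourly MVPA is not valid")
  assert_that(mean_mvpa > 0, "person mean must be positive (degenerate participants are excluded upstream)")
  assert_that(risk_window[1] <= risk_window[2] &&
                risk_window[1] >= 1 && risk_window[2] <= 24,
              "risk window must be within interval indices 1..24")
  cum <- cumsum(hourly_mvpa)          # cum[t] = MVPA through interval t
  hit <- which(cum >= mean_mvpa)
  if (length(hit) == 0 || hit[1] > risk_window[2])
    return(list(status = "censored", hour = NA_integer_))
  t0 <- hit[1]
  if (t0 < risk_window[1])
    return(list(status = "pre_window", hour = as.integer(t0)))
  list(status = "event", hour = as.integer(t0))
}

#' Build the discrete-time person-period risk set
#'
#' One row per person-day-hour at risk: each included day contributes rows
#' from the risk-window start up to and including its event hour (the last
#' row carrying `event = 1`), or through the window end with all `event = 0`
#' when censored. Person-level covariates are repeated on every row; the
#' school-day indicator is taken per day. Days with no worn-awake minute
#' inside the risk window contribute no rows, as do days whose event occurred
#' before the window opened; both are named in the attached log.
#'
#' @param summaries included day-summary rows.
#' @param means output of [person_mean_mvpa].
#' @param covariates data.frame `participant_id`, `sex`
#'   (`"female"`/`"male"`), `bmi_category` (`"normal"`/`"overweight"`/
#'   `"obese"`), `sports` (0/1).
#' @param risk_window integer `c(first, last)` interval indices.
#' @param drop_degenerate drop participants whose mean MVPA is 0 (default
#'   `TRUE`; they would trivially "attain" their average at the first worn
#'   hour of every day).
#' @return data.frame with columns `participant_id`, `date`, `t`, `event`,
#'   `sex`, `bmi_category`, `sports`, `school_day`; attributes `risk_window`,
#'   `convention` and `log` (excluded days).
#' @export
build_person_period <- function(summaries, means, covariates,
                                risk_window = c(9, 23),
                                drop_degenerate = TRUE) {
  assert_that(nrow(summaries) > 0, "no included days")
  missing_cov <- setdiff(unique(summaries$participant_id),
                         covariates$participant_id)
  assert_that(length(missing_cov) == 0,
              paste("covariates missing for participant(s):",
                    paste(missing_cov, collapse = ", ")))
  missing_mean <- setdiff(unique(summaries$participant_id),
                          means$participant_id)
  assert_that(length(missing_mean) == 0,
              paste("person mean missing for participant(s):",
                    paste(missing_mean, collapse = ", ")))

  log <- list()
  if (drop_degenerate) {
    degen <- means$participant_id[means$degenerate]
    if (length(degen)) {
      log[[length(log) + 1L]] <- data.frame(
        participant_id = degen, date = as.Date(NA),
        reason = "degenerate_zero_mean", stringsAsFactors = FALSE)
      summaries <- summaries[!summaries$participant_id %in% degen, ,
                             drop = FALSE]
    }
  }
  assert_that(nrow(summaries) > 0, "no non-degenerate days remain")

  t_seq <- risk_window[1]:risk_window[2]
  wear_cols <- paste0("w", t_seq - 1L)       # wear of clock hour t-1 => interval t
  mvpa_cols <- paste0("h", 0:23)
  mean_of <- stats::setNames(means$mean_mvpa, means$participant_id)
  cov_row <- covariates[match(summaries$participant_id,
                              covariates$participant_id), ]

  pieces <- vector("list", nrow(summaries))
  for (i in seq_len(nrow(summaries))) {
    wear_in_win <- sum(as.numeric(summaries[i, wear_cols]))
    if (wear_in_win <= 0) {
      log[[length(log) + 1L]] <- data.frame(
        participant_id = summaries$participant_id[i],
        date = summaries$date[i], reason = "no_wear_in_window",
        stringsAsFactors = FALSE)
      next
    }
    ev <- code_event_hour(as.numeric(summaries[i, mvpa_cols]),
                          mean_of[[summaries$participant_id[i]]],
                          risk_window)
    if (ev$status == "pre_window") {
      log[[length(log) + 1L]] <- data.frame(
        participant_id = summaries$participant_id[i],
        date = summaries$date[i], reason = "event_before_window",
        stringsAsFactors = FALSE)
      next
    }
    t_end <- if (ev$status == "event") ev$hour else risk_window[2]
    tt <- risk_window[1]:t_end
    pieces[[i]] <- data.frame(
      participant_id = summaries$participant_id[i],
      date = summaries$date[i],
      t = tt,
      event = as.integer(ev$status == "event" & tt == t_end),
      sex = cov_row$sex[i],
      bmi_category = cov_row$bmi_category[i],
      sports = cov_row$sports[i],
      school_day = as.integer(summaries$is_school_day[i]),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  assert_that(!is.null(out) && nrow(out) > 0,
              "risk set is empty after exclusions")
  rownames(out) <- NULL
  attr(out, "risk_window") <- risk_window
  attr(out, "convention") <- interval_convention()
  attr(out, "log") <- if (length(log)) do.call(rbind, log) else
    data.frame(participant_id = character(), date = as.Date(character()),
               reason = character(), stringsAsFactors = FALSE)
  out
}
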