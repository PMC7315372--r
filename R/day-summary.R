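#' Summarize one participant-day into wear and hourly MVPA
#'
#' Combines the nonwear mask, sleep mask and per-epoch intensity labels into
#' a per-day summary: a minute counts as worn only if it is neither nonwear
#' nor sleep, and an epoch contributes to MVPA only if its minute is worn and
#' it is labelled moderate or vigorous. Epochs are attributed to the clock
#' hour containing their start (epochs never straddle an hour because the
#' epoch length divides 60 s).
#'
#' @param series an [epoch_series].
#' @param nonwear_mask logical per-minute mask from [detect_nonwear].
#' @param sleep_mask logical per-minute mask from [score_sleep].
#' @param labels per-native-epoch intensity factor from [classify_intensity].
#' @param calendar data.frame with columns `date`, `is_school_day`; must
#'   contain the series' date.
#' @param params an [algorithm_params] object.
#' @return a one-row data.frame ("day summary" row) with columns
#'   `participant_id`, `date`, `wear_minutes`, `mvpa_minutes`, `is_valid`,
#'   `is_school_day`, `trimmed_for_reactivity`, hourly MVPA minutes
#'   `h0..h23`, and hourly worn-awake minutes `w0..w23`.
#' @export
summarize_day <- function(series, nonwear_mask, sleep_mask, labels, calendar,
                          params = algorithm_params()) {
  stopifnot(inherits(series, "epoch_series"))
  n_min <- 1440L
  assert_that(length(nonwear_mask) == n_min && length(sleep_mask) == n_min,
              "masks must be per-minute over the full day")
  native <- params$cutpoint_epoch_s
  n_native <- 86400L %/% as.integer(native)
  assert_that(length(labels) == n_native,
              "labels must align with the series at the cutpoints' native epoch")
  cal_row <- match(series$date, as.Date(calendar$date))
  assert_that(!is.na(cal_row),
              sprintf("calendar does not cover %s", format(series$date)))

  worn_min <- !nonwear_mask & !sleep_mask
  per_min <- 60L %/% as.integer(native)
  worn_epoch <- rep(worn_min, each = per_min)
  mvpa_epoch <- worn_epoch & (labels %in% c("moderate", "vigorous"))

  hour_of_epoch <- rep(0:23, each = n_native %/% 24L)
  hourly_mvpa <- vapply(0:23, function(h)
    sum(mvpa_epoch[hour_of_epoch == h]) * native / 60, numeric(1))
  hour_of_min <- rep(0:23, each = 60L)
  hourly_wear <- vapply(0:23, function(h)
    sum(worn_min[hour_of_min == h]), numeric(1))

  out <- data.frame(participant_id = series$participant_id,
                    date = series$date,
                    wear_minutes = sum(worn_min),
                    mvpa_minutes = sum(hourly_mvpa),
                    is_valid = sum(worn_min) >= params$min_wear_min,
                    is_school_day = as.logical(calendar$is_school_day[cal_row]),
                    trimmed_for_reactivity = FALSE,
                    stringsAsFactors = FALSE)
  out[paste0("h", 0:23)] <- as.list(hourly_mvpa)
  out[paste0("w", 0:23)] <- as.list(hourly_wear)
  out
}

#' Run the full per-day classification chain over a cohort
#'
#' For each epoch series: aggregate to minutes, detect nonwear, score sleep,
#' classify intensity at the cutpoints' native epoch, and summarize the day.
#'
#' @param series_list list of [epoch_series] objects.
#' @param calendar data.frame `date`, `is_school_day`.
#' @param params an [algorithm_params] object.
#' @return data.frame of day-summary rows (one per series).
#' @export
summarize_cohort <- function(series_list, calendar,
                             params = algorithm_params()) {
  assert_that(length(series_list) > 0, "no epoch series supplied")
  rows <- lapply(series_list, function(s) {
    mc <- minute_counts(s)
    nw <- detect_nonwear(mc, params)
    sl <- score_sleep(mc, params)
    lab <- classify_intensity(s$counts, params, epoch_s = s$epoch_s)
    summarize_day(s, nw, sl, lab, calendar, params)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply valid-day and participant inclusion rules
#'
#' Applies, in order and per participant: (1) drop the first
#' `reactivity_trim_days` calendar days containing any wear (measurement
#' reactivity); (2) drop days with fewer than `min_wear_min` worn minutes;
#' (3) drop participants left with fewer than `min_valid_days` valid days.
#' Every dropped day or participant is named in the exclusion log together
#' with the rule that removed it.
#'
#' The returned summary table carries the attribute `inclusion_applied`;
#' re-applying the rules to an already-filtered table is the identity.
#'
#' @param summaries day-summary data.frame from [summarize_cohort].
#' @param params an [algorithm_params] object.
#' @return list with `summaries` (filtered data.frame) and `log`
#'   (data.frame `participant_id`, `date`, `rule`).
#' @export
apply_inclusion_rules <- function(summaries, params = algorithm_params()) {
  empty_log <- data.frame(participant_id = character(), date = as.Date(character()),
                          rule = character(), stringsAsFactors = FALSE)
  if (is.null(summaries) || nrow(summaries) == 0)
    return(list(summaries = summaries, log = empty_log))
  if (isTRUE(attr(summaries, "inclusion_applied")))
    return(list(summaries = summaries, log = empty_log))

  summaries <- summaries[order(summaries$participant_id, summaries$date), ]
  logs <- list()
  keep <- rep(TRUE, nrow(summaries))

  for (pid in unique(summaries$participant_id)) {
    idx <- which(summaries$participant_id == pid)
    wear_days <- idx[summaries$wear_minutes[idx] > 0]
    trim <- head(wear_days, params$reactivity_trim_days)
    if (length(trim)) {
      keep[trim] <- FALSE
      logs[[length(logs) + 1L]] <- data.frame(
        participant_id = pid, date = summaries$date[trim],
        rule = "reactivity_trim", stringsAsFactors = FALSE)
    }
    rest <- setdiff(idx, trim)
    short <- rest[summaries$wear_minutes[rest] < params$min_wear_min]
    if (length(short)) {
      keep[short] <- FALSE
      logs[[length(logs) + 1L]] <- data.frame(
        participant_id = pid, date = summaries$date[short],
        rule = "insufficient_wear", stringsAsFactors = FALSE)
    }
    remaining <- setdiff(rest, short)
    if (length(remaining) < params$min_valid_days) {
      keep[remaining] <- FALSE
      if (length(remaining))
        logs[[length(logs) + 1L]] <- data.frame(
          participant_id = pid, date = summaries$date[remaining],
          rule = "too_few_valid_days", stringsAsFactors = FALSE)
      else
        logs[[length(logs) + 1L]] <- data.frame(
          participant_id = pid, date = as.Date(NA),
          rule = "too_few_valid_days", stringsAsFactors = FALSE)
    }
  }
  out <- summaries[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "inclusion_applied") <- TRUE
  log <- if (length(logs)) do.call(rbind, logs) else empty_log
  list(summaries = out, log = log)
}
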