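#' Accelerometer processing constants
#'
#' All constants used by the wear, sleep and intensity classification rules
#' live here; none is hard-coded elsewhere, and every pipeline output echoes
#' the values actually used.
#'
#' Defaults are the transcribed constants of the standard adolescent
#' wrist-accelerometry workflow:
#' \itemize{
#'   \item Nonwear: a minute is nonwear when it lies in a run of at least
#'     `nonwear_window_min` zero-count minutes, allowing up to
#'     `nonwear_spike_max` interrupt minutes each with counts below
#'     `nonwear_spike_ceiling` (the classic 60-min / 2-min / 100-count rule).
#'   \item Sleep: the five-term actigraphic linear scoring of rolling mean
#'     activity, rolling variability, the count of moderately active epochs,
#'     and the log of current activity; scores at or above `sleep_threshold`
#'     are sleep. `sleep_window` restricts scoring to a nightly window
#'     (start hour, end hour, spanning midnight) so sedentary daytime minutes
#'     are not misread as naps; set to `NULL` to score all 24 h.
#'   \item Intensity: wrist vector-magnitude cutpoints for youth at their
#'     native 5-s epoch; counts at or above a boundary go to the higher class.
#' }
#'
#' @param nonwear_window_min minutes of consecutive zeros defining nonwear.
#' @param nonwear_spike_max allowed nonzero interrupt minutes inside a run.
#' @param nonwear_spike_ceiling maximum count during an interrupt minute.
#' @param sleep_coefficients named numeric: `intercept`, `avg` (11-min rolling
#'   mean), `nat` (count of window minutes with counts in `[nat_low, nat_high)`),
#'   `sd` (trailing 6-min standard deviation), `lg` (natural log of
#'   current count + 1).
#' @param sleep_threshold score at or above which a minute is sleep.
#' @param sleep_nat_range two counts `[low, high)` defining a "moderately
#'   active" minute for the NAT term.
#' @param sleep_window `c(start_hour, end_hour)` nightly scoring window
#'   (default 8 PM to 10 AM), or `NULL` for 24-h scoring.
#' @param cutpoints named numeric thresholds `c(light=, moderate=, vigorous=)`:
#'   the smallest count classified into each class; counts below `light` are
#'   sedentary.
#' @param cutpoint_epoch_s native epoch length (seconds) of the cutpoints.
#' @param min_wear_min minutes of wear required for a valid day (8 h).
#' @param reactivity_trim_days leading days-with-wear dropped per participant
#'   against measurement reactivity.
#' @param min_valid_days valid days required to retain a participant.
#' @return an object of class `algorithm_params` (a validated list).
#' @examples
#' p <- algorithm_params()
#' p$cutpoints
#' @export
algorithm_params <- function(nonwear_window_min = 60,
                             nonwear_spike_max = 2,
                             nonwear_spike_ceiling = 100,
                             sleep_coefficients = c(intercept = 7.601,
                                                    avg = -0.065,
                                                    nat = -1.08,
                                                    sd = -0.056,
                                                    lg = -0.703),
                             sleep_threshold = 0,
                             sleep_nat_range = c(50, 100),
                             sleep_window = c(20, 10),
                             cutpoints = c(light = 306, moderate = 818,
                                           vigorous = 1969),
                             cutpoint_epoch_s = 5,
                             min_wear_min = 480,
                             reactivity_trim_days = 3,
                             min_valid_days = 4) {
  assert_that(nonwear_window_min > 0 && nonwear_spike_max >= 0 &&
                nonwear_spike_ceiling >= 0,
              "nonwear parameters must be nonnegative with a positive window")
  assert_that(all(c("intercept", "avg", "nat", "sd", "lg") %in%
                    names(sleep_coefficients)),
              "sleep_coefficients must name intercept, avg, nat, sd, lg")
  assert_that(all(c("light", "moderate", "vigorous") %in% names(cutpoints)),
              "cutpoints must name light, moderate, vigorous")
  cutpoints <- cutpoints[c("light", "moderate", "vigorous")]
  assert_that(all(cutpoints >= 0) && !is.unsorted(cutpoints, strictly = TRUE),
              "cutpoints must be nonnegative and strictly increasing (sedentary < light < moderate < vigorous)")
  assert_that(cutpoint_epoch_s > 0 && 60 %% cutpoint_epoch_s == 0,
              "cutpoint_epoch_s must divide 60")
  if (!is.null(sleep_window))
    assert_that(length(sleep_window) == 2 &&
                  all(sleep_window >= 0 & sleep_window <= 24),
                "sleep_window must be two hours in 0..24 or NULL")
  assert_that(min_wear_min > 0 && min_wear_min <= 1440,
              "min_wear_min must be in (0, 1440]")
  assert_that(reactivity_trim_days >= 0 && min_valid_days >= 1,
              "trim/min-valid day counts out of range")
  structure(list(nonwear_window_min = nonwear_window_min,
                 nonwear_spike_max = nonwear_spike_max,
                 nonwear_spike_ceiling = nonwear_spike_ceiling,
                 sleep_coefficients = sleep_coefficients,
                 sleep_threshold = sleep_threshold,
                 sleep_nat_range = sleep_nat_range,
                 sleep_window = sleep_window,
                 cutpoints = cutpoints,
                 cutpoint_epoch_s = cutpoint_epoch_s,
                 min_wear_min = min_wear_min,
                 reactivity_trim_days = reactivity_trim_days,
                 min_valid_days = min_valid_days),
            class = "algorithm_params")
}

#' @export
print.algorithm_params <- function(x, ...) {
  cat("<algorithm_params>\n")
  cat(sprintf("  nonwear: %d-min zero window, <=%d interrupt min < %d counts\n",
              x$nonwear_window_min, x$nonwear_spike_max,
              x$nonwear_spike_ceiling))
  cat(sprintf("  sleep score: %.3f %+0.3f*AVG %+0.3f*NAT %+0.3f*SD %+0.3f*LG >= %g\n",
              x$sleep_coefficients["intercept"], x$sleep_coefficients["avg"],
              x$sleep_coefficients["nat"], x$sleep_coefficients["sd"],
              x$sleep_coefficients["lg"], x$sleep_threshold))
  if (!is.null(x$sleep_window))
    cat(sprintf("  sleep scored %02d:00-%02d:00 only\n",
                x$sleep_window[1], x$sleep_window[2]))
  cat(sprintf("  cutpoints (/%d s): light>=%g moderate>=%g vigorous>=%g\n",
              x$cutpoint_epoch_s, x$cutpoints["light"],
              x$cutpoints["moderate"], x$cutpoints["vigorous"]))
  cat(sprintf("  valid day >= %d wear min; trim first %d wear days; keep >= %d valid days\n",
              x$min_wear_min, x$reactivity_trim_days, x$min_valid_days))
  invisible(x)
}

#' Epoch-level count series for one participant-day
#'
#' The raw observational unit: counts for one participant over one calendar
#' day at a fixed epoch length, starting at midnight.
#'
#' @param participant_id opaque identifier.
#' @param date calendar date (`Date` or coercible).
#' @param epoch_s epoch length in seconds; must divide 60.
#' @param counts nonnegative integer counts, one per epoch, covering the full
#'   day (`86400 / epoch_s` values).
#' @param channel label for the count channel (default `"vm"`, vector
#'   magnitude).
#' @return an object of class `epoch_series`.
#' @export
epoch_series <- function(participant_id, date, epoch_s, counts,
                         channel = "vm") {
  assert_that(length(counts) > 0, "counts must be nonempty")
  assert_that(epoch_s > 0 && 60 %% epoch_s == 0,
              sprintf("epoch length %s s does not divide 60 s; cannot aggregate to minutes", epoch_s))
  assert_that(!anyNA(counts) && all(counts >= 0),
              "counts must be nonnegative and non-missing")
  n_expected <- 86400 / epoch_s
  assert_that(length(counts) == n_expected,
              sprintf("expected %d epochs for a full day at %d s, got %d",
                      n_expected, as.integer(epoch_s), length(counts)))
  structure(list(participant_id = as.character(participant_id),
                 date = as.Date(date), epoch_s = as.integer(epoch_s),
                 counts = as.integer(round(counts)), channel = channel),
            class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> %s %s: %d x %ds epochs (%s), total %d counts\n",
              x$participant_id, format(x$date), length(x$counts), x$epoch_s,
              x$channel, sum(x$counts)))
  invisible(x)
}

## sum epochs to per-minute counts
minute_counts <- function(series) {
  per_min <- 60L %/% series$epoch_s
  if (per_min == 1L) return(as.numeric(series$counts))
  as.numeric(colSums(matrix(series$counts, nrow = per_min)))
}
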