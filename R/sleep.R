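#' Score sleep minutes from per-minute activity counts
#'
#' Implements the classic actigraphic five-term linear sleep score for minute
#' `i`:
#' \deqn{SI_i = b_0 + b_{avg} AVG_i + b_{nat} NAT_i + b_{sd} SD_i + b_{lg} LG_i}
#' where `AVG` is the mean count over the 11-minute window centred on `i`,
#' `NAT` the number of minutes in that window with counts in the
#' "moderately active" band, `SD` the standard deviation of the trailing
#' 6-minute window (minute `i` and the 5 before), and `LG = log(count_i + 1)`.
#' Minutes with `SI >= sleep_threshold` are sleep.
#'
#' Edges are padded with zero counts (a declared policy: a day boundary is
#' overwhelmingly surrounded by overnight inactivity). When
#' `params$sleep_window` is set, only minutes whose clock hour falls inside
#' the nightly window are eligible for a sleep label; all others are wake by
#' design, so sedentary daytime stretches are not misread as naps.
#'
#' @param minute_counts per-minute counts for one day (length >= 11).
#' @param params an [algorithm_params] object.
#' @param minute_of_day optional integer vector (0..1439) giving each minute's
#'   clock position; defaults to `0:(n-1)` for a midnight-aligned day. Used
#'   only to apply `sleep_window`.
#' @return logical vector, `TRUE` where the minute is scored sleep.
#' @export
score_sleep <- function(minute_counts, params = algorithm_params(),
                        minute_of_day = NULL) {
  assert_that(is.numeric(minute_counts) && !anyNA(minute_counts) &&
                all(minute_counts >= 0),
              "minute counts must be nonnegative and non-missing")
  n <- length(minute_counts)
  assert_that(n >= 11,
              "series shorter than the 11-minute scoring window is not scorable")
  si <- sleep_score(minute_counts, params)
  sleep <- si >= params$sleep_threshold
  if (!is.null(params$sleep_window)) {
    mod_ <- minute_of_day %||% (seq_len(n) - 1L)
    assert_that(length(mod_) == n, "minute_of_day length mismatch")
    hr <- (mod_ %/% 60) %% 24
    from <- params$sleep_window[1]; to <- params$sleep_window[2]
    in_window <- if (from <= to) hr >= from & hr < to else hr >= from | hr < to
    sleep <- sleep & in_window
  }
  sleep
}

## vectorized five-term score; zero-padded edges
sleep_score <- function(x, params) {
  n <- length(x)
  b <- params$sleep_coefficients
  pad <- c(rep(0, 5), x, rep(0, 5))
  avg <- stats::filter(pad, rep(1 / 11, 11), sides = 2)[6:(n + 5)]
  band <- params$sleep_nat_range
  nat_ind <- as.numeric(pad >= band[1] & pad < band[2])
  nat <- stats::filter(nat_ind, rep(1, 11), sides = 2)[6:(n + 5)]
  ## trailing 6-minute sd via rolling first/second moments
  s1 <- stats::filter(pad, rep(1, 6), sides = 1)[6:(n + 5)]
  s2 <- stats::filter(pad^2, rep(1, 6), sides = 1)[6:(n + 5)]
  var6 <- pmax((s2 - s1^2 / 6) / 5, 0)
  sd6 <- sqrt(var6)
  lg <- log(x + 1)
  as.numeric(b["intercept"] + b["avg"] * avg + b["nat"] * nat +
               b["sd"] * sd6 + b["lg"] * lg)
}

#' Classify epochs into intensity classes by count cutpoints
#'
#' Ordered thresholds assign each epoch to sedentary, light, moderate or
#' vigorous; a count exactly at a boundary goes to the higher class (the
#' `>=` convention). MVPA is the union of moderate and vigorous. Counts
#' recorded at a finer epoch than the cutpoints' native epoch are aggregated
#' by summation first; coarser data cannot be disaggregated and are rejected.
#'
#' @param epoch_counts nonnegative counts per epoch.
#' @param params an [algorithm_params] object (supplies `cutpoints` and their
#'   native epoch length).
#' @param epoch_s epoch length of `epoch_counts` in seconds.
#' @return factor of labels (`sedentary < light < moderate < vigorous`), one
#'   per *native-epoch* window (length `length(epoch_counts) * epoch_s /
#'   cutpoint_epoch_s`).
#' @examples
#' p <- algorithm_params()
#' classify_intensity(c(0, 306, 818, 1969, 817), p, epoch_s = 5)
#' @export
classify_intensity <- function(epoch_counts, params = algorithm_params(),
                               epoch_s) {
  assert_that(is.numeric(epoch_counts) && !anyNA(epoch_counts) &&
                all(epoch_counts >= 0),
              "epoch counts must be nonnegative and non-missing")
  cp <- params$cutpoints
  assert_that(!is.unsorted(cp, strictly = TRUE),
              "cutpoints must be strictly increasing")
  native <- params$cutpoint_epoch_s
  if (epoch_s < native) {
    assert_that(native %% epoch_s == 0,
                sprintf("epoch length %gs does not divide the cutpoints' native %gs",
                        epoch_s, native))
    k <- native %/% epoch_s
    assert_that(length(epoch_counts) %% k == 0,
                "count vector length is not a whole number of native epochs")
    epoch_counts <- colSums(matrix(epoch_counts, nrow = k))
  } else if (epoch_s > native) {
    stop(sprintf("data at %gs epochs are coarser than the cutpoints' native %gs epoch; cannot disaggregate",
                 epoch_s, native), call. = FALSE)
  }
  lev <- c("sedentary", "light", "moderate", "vigorous")
  idx <- findInterval(epoch_counts, c(cp["light"], cp["moderate"],
                                      cp["vigorous"])) + 1L
  factor(lev[idx], levels = lev, ordered = TRUE)
}
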