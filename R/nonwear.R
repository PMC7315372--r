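#' Detect nonwear minutes from consecutive zero counts
#'
#' A minute is nonwear iff it lies inside some window of minutes that (a)
#' starts and ends on a zero-count minute, (b) contains at most
#' `nonwear_spike_max` nonzero "interrupt" minutes, each with a count below
#' `nonwear_spike_ceiling`, (c) contains no minute at or above the ceiling,
#' and (d) spans at least `nonwear_window_min` minutes. The mask is the union
#' of all such windows, so interrupt minutes inside a flagged run are flagged
#' too.
#'
#' @param minute_counts numeric vector of per-minute counts (aggregate epochs
#'   to 60 s first; see [minute_counts]).
#' @param params an [algorithm_params] object.
#' @return logical vector, `TRUE` where the minute is nonwear; same length as
#'   the input.
#' @examples
#' p <- algorithm_params()
#' x <- c(rep(500, 10), rep(0, 90), rep(500, 10))
#' sum(detect_nonwear(x, p))  # the 90 zero minutes
#' @export
detect_nonwear <- function(minute_counts, params = algorithm_params()) {
  assert_that(is.numeric(minute_counts) && !anyNA(minute_counts),
              "minute counts must be numeric and non-missing")
  assert_that(all(minute_counts >= 0), "negative counts are not valid")
  n <- length(minute_counts)
  win <- params$nonwear_window_min
  spike_max <- params$nonwear_spike_max
  ceiling_ <- params$nonwear_spike_ceiling
  mask <- logical(n)
  if (n == 0) return(mask)

  is_zero <- minute_counts == 0
  is_block <- minute_counts >= ceiling_ & !is_zero  # terminates any window
  ## prefix count of nonzero minutes, for the interrupt budget
  nz_prefix <- cumsum(!is_zero)

  ## scan segments delimited by blocking minutes; within each, a two-pointer
  ## sweep: for each zero start i, the furthest zero end j with at most
  ## spike_max interrupts in [i, j]; j is nondecreasing in i.
  seg_id <- cumsum(is_block)
  starts <- which(is_zero)
  if (length(starts) == 0) return(mask)
  j <- 0L
  for (i in starts) {
    if (j < i) j <- i
    ## extend j while the window [i, j+1] stays within this segment and budget
    repeat {
      nxt <- j + 1L
      if (nxt > n || is_block[nxt] || seg_id[nxt] != seg_id[i]) break
      if (nz_prefix[nxt] - nz_prefix[i] > spike_max) break
      j <- nxt
    }
    ## shrink to the last zero minute (windows end on zeros)
    jz <- j
    while (jz > i && !is_zero[jz]) jz <- jz - 1L
    if (jz - i + 1L >= win) mask[i:jz] <- TRUE
  }
  mask
}
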