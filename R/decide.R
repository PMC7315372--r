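#' Peak-hazard decision window
#'
#' The maximal contiguous run of effect-table rows whose hazard probability
#' is at least `(1 - rel_tolerance)` times the peak hazard. Ties in run
#' length are broken toward the later run (evening priority: the substantive
#' use privileges the late-day window). With `rel_tolerance = 0` this is
#' exactly the argmax run.
#'
#' Windows operate on row labels ("Before t"), never on raw clock spans;
#' the interval convention is attached so the clock mapping is explicit.
#'
#' @param table an effect table with a `hazard_prob` column.
#' @param rel_tolerance fraction in `[0, 1)` below the peak still counted as
#'   peak (default 0).
#' @return data.frame of the window rows (`hour`, `label`, `hazard_prob`)
#'   with attributes `basis = "peak_hazard"` and `convention`.
#' @export
peak_hazard_window <- function(table, rel_tolerance = 0) {
  assert_that(!is.null(table) && nrow(table) > 0, "empty effect table")
  assert_that(!is.null(table$hazard_prob), "hazard column missing")
  assert_that(rel_tolerance >= 0 && rel_tolerance < 1,
              "rel_tolerance must be in [0, 1)")
  h <- table$hazard_prob
  near_peak <- h >= (1 - rel_tolerance) * max(h)
  runs <- rle(near_peak)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  len <- runs$lengths[cand]
  best <- cand[max(which(len == max(len)))]   # later run on ties
  idx <- starts[best]:ends[best]
  out <- table[idx, c("hour", "label", "hazard_prob")]
  rownames(out) <- NULL
  structure(out, basis = "peak_hazard", convention = interval_convention())
}

#' Steepest survival-decline decision window
#'
#' The `span`-row window maximizing the survival drop
#' `S(start) - S(start + span)`; ties are broken toward the later window.
#'
#' @param table an effect table with a `survival_prob` column.
#' @param span number of rows spanned (default 3, e.g. "Before 5 PM" to
#'   "Before 8 PM").
#' @return data.frame of the window rows with attributes
#'   `basis = "survival_decline"`, `drop` (the survival decrease) and
#'   `convention`.
#' @export
steepest_survival_decline <- function(table, span = 3) {
  assert_that(!is.null(table) && nrow(table) > 0, "empty effect table")
  assert_that(!is.null(table$survival_prob), "survival column missing")
  assert_that(span >= 1 && span < nrow(table),
              "span must be in [1, nrow - 1]")
  s <- table$survival_prob
  n <- length(s)
  starts <- seq_len(n - span)
  drops <- s[starts] - s[starts + span]
  best <- max(which(drops == max(drops)))     # later window on ties
  idx <- starts[best]:(starts[best] + span)
  out <- table[idx, c("hour", "label", "survival_prob")]
  rownames(out) <- NULL
  structure(out, basis = "survival_decline", drop = max(drops),
            convention = interval_convention())
}

#' Default directional hypothesis registry
#'
#' Registered expectations for the moderator analyses: sports participants
#' are expected to have higher odds of attaining their average MVPA than
#' non-participants, and school days higher odds than non-school days; sex
#' and BMI comparisons are exploratory (criterion 2 is automatically
#' satisfied for them once a significant difference exists).
#'
#' Each entry is either `"exploratory"` or the *group-a-relative* expected
#' sign: `"a_higher"` / `"b_higher"`, where group a / b are the two tables
#' handed to [ci_overlap_compare] for that moderator.
#'
#' @return named list.
#' @export
default_hypotheses <- function() {
  list(sex = "exploratory",
       bmi_category = "exploratory",
       sports = "a_higher",      # a = sports participants
       school_day = "a_higher")  # a = school days
}

#' Derive intervention decision points
#'
#' Applies the two-criterion rule for moderator-specific decision points:
#' a subgroup window is emitted for a moderator only when (1) its groups'
#' odds ratios differ significantly (non-overlapping 95% CIs) at one or
#' more hours and (2) the direction of those differences matches the
#' registered hypothesis (automatically satisfied for exploratory
#' moderators). The overall window comes from the peak-hazard rule applied
#' to the overall effect table.
#'
#' @param overall_table effect table of the unmoderated model.
#' @param comparisons named list: per moderator, a list with `comparison`
#'   (a [ci_overlap_compare] result, group a vs group b) and optionally
#'   `label_a`, `label_b`.
#' @param hypotheses named list as in [default_hypotheses]; every compared
#'   moderator must be present.
#' @param rel_tolerance passed to [peak_hazard_window].
#' @param span passed to [steepest_survival_decline].
#' @return object of class `decision_report`: `overall_window`, `basis`,
#'   `survival_window`, `moderator_findings` (per moderator: criteria flags,
#'   window, rationale), `hypotheses`.
#' @export
moderator_decision_points <- function(overall_table, comparisons,
                                      hypotheses = default_hypotheses(),
                                      rel_tolerance = 0, span = 3) {
  overall <- peak_hazard_window(overall_table, rel_tolerance)
  surv_win <- steepest_survival_decline(overall_table, span)
  findings <- list()
  for (mod in names(comparisons)) {
    assert_that(!is.null(hypotheses[[mod]]),
                sprintf("no registered hypothesis for moderator '%s'", mod))
    cmp <- comparisons[[mod]]$comparison
    hyp <- hypotheses[[mod]]
    sig <- which(cmp$significant)
    c1 <- length(sig) > 0
    if (!c1) {
      findings[[mod]] <- list(
        criterion1_met = FALSE, criterion2_met = FALSE, window = NULL,
        rationale = "no hour with non-overlapping 95% CIs; no decision points")
      next
    }
    diff_sign <- sign(cmp$or_diff[sig])
    c2 <- if (identical(hyp, "exploratory")) TRUE
          else if (identical(hyp, "a_higher")) all(diff_sign > 0)
          else all(diff_sign < 0)
    if (!c2) {
      findings[[mod]] <- list(
        criterion1_met = TRUE, criterion2_met = FALSE, window = NULL,
        rationale = sprintf(
          "significant at %s but opposite to the registered hypothesis (%s); no decision points",
          paste(cmp$label[sig], collapse = ", "), hyp))
      next
    }
    ## favored group: the one with the higher OR over the significant hours
    favored <- if (mean(cmp$or_diff[sig]) > 0)
      comparisons[[mod]]$label_a %||% "group_a"
    else comparisons[[mod]]$label_b %||% "group_b"
    ## window = longest contiguous run of significant hours (later on ties)
    sig_flag <- cmp$significant
    runs <- rle(sig_flag)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    cand <- which(runs$values)
    len <- runs$lengths[cand]
    best <- cand[max(which(len == max(len)))]
    idx <- starts[best]:ends[best]
    win <- cmp[idx, c("hour", "label")]
    rownames(win) <- NULL
    findings[[mod]] <- list(
      criterion1_met = TRUE, criterion2_met = TRUE, window = win,
      favored_group = favored,
      rationale = sprintf(
        "non-overlapping CIs at %s favor %s, consistent with '%s'; subgroup decision points over %s-%s",
        paste(cmp$label[sig], collapse = ", "), favored, hyp,
        win$label[1], win$label[nrow(win)]))
  }
  structure(list(overall_window = overall, basis = "peak_hazard",
                 survival_window = surv_win,
                 moderator_findings = findings, hypotheses = hypotheses,
                 convention = interval_convention()),
            class = "decision_report")
}

#' @export
print.decision_report <- function(x, ...) {
  cat("<decision_report>\n")
  cat(sprintf("  overall window (peak hazard): %s - %s\n",
              x$overall_window$label[1],
              x$overall_window$label[nrow(x$overall_window)]))
  cat(sprintf("  steepest survival decline (-%.0f%%): %s - %s\n",
              100 * attr(x$survival_window, "drop"),
              x$survival_window$label[1],
              x$survival_window$label[nrow(x$survival_window)]))
  for (mod in names(x$moderator_findings)) {
    f <- x$moderator_findings[[mod]]
    cat(sprintf("  %s: criterion1=%s criterion2=%s%s\n    %s\n", mod,
                f$criterion1_met, f$criterion2_met,
                if (!is.null(f$window))
                  sprintf(" window %s - %s", f$window$label[1],
                          f$window$label[nrow(f$window)]) else "",
                f$rationale))
  }
  cat(" ", x$convention, "\n")
  invisible(x)
}
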