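## covariate profile helpers -------------------------------------------------

#' Reference covariate profile
#'
#' The covariate values plugged into effect tables when none are supplied:
#' every covariate at its reference level (female, normal weight, no sports,
#' non-school day). The profile used is always echoed on the table.
#'
#' @param sex,bmi_category,sports,school_day covariate values.
#' @return named list.
#' @export
covariate_profile <- function(sex = "female", bmi_category = "normal",
                              sports = 0, school_day = 0) {
  assert_that(sex %in% c("female", "male"), "unknown sex value")
  assert_that(bmi_category %in% c("normal", "overweight", "obese"),
              "unknown bmi_category value")
  assert_that(sports %in% c(0, 1), "sports must be 0/1")
  assert_that(school_day %in% c(0, 1), "school_day must be 0/1")
  list(sex = sex, bmi_category = bmi_category, sports = sports,
       school_day = school_day)
}

## value of an internal dummy column under a profile
profile_dummy <- function(name, profile) {
  switch(name,
         sexmale = as.numeric(profile$sex == "male"),
         bmioverweight = as.numeric(profile$bmi_category == "overweight"),
         bmiobese = as.numeric(profile$bmi_category == "obese"),
         sports1 = as.numeric(profile$sports == 1),
         schoolday1 = as.numeric(profile$school_day == 1),
         stop("unknown covariate column: ", name, call. = FALSE))
}

## internal-scale design row for (hour, profile), matching fit's columns
design_row <- function(fit, hour, profile) {
  spec <- fit$spec
  s <- (hour - spec$time_ref) / spec$time_scale
  vals <- vapply(names(fit$beta_internal), function(nm) {
    if (nm == "(Intercept)") return(1)
    if (grepl("^time[0-9]$", nm)) return(s^as.integer(sub("time", "", nm)))
    if (grepl("_x_time[0-9]$", nm)) {
      k <- as.integer(sub(".*_x_time", "", nm))
      d <- sub("_x_time[0-9]$", "", nm)
      return(profile_dummy(d, profile) * s^k)
    }
    profile_dummy(nm, profile)
  }, numeric(1))
  vals
}

#' Linear predictor at an hour for a covariate profile
#'
#' \eqn{\eta(t) = x(t, \mathrm{profile})'\hat\beta} with the random intercept
#' set to 0 (the median-person interpretation).
#'
#' @param fit a converged [hazard_fit].
#' @param hour interval index (integer clock hour ending the interval).
#' @param profile a [covariate_profile].
#' @return log-odds value.
#' @export
linear_predictor <- function(fit, hour, profile = covariate_profile()) {
  assert_that(fit$converged, "fit did not converge")
  sum(design_row(fit, hour, profile) * fit$beta_internal)
}

#' Effect table: per-hour odds ratios, hazard and survival probabilities
#'
#' For each interval `t` in the risk window plus the reference interval:
#' \itemize{
#'   \item `odds_ratio = exp(eta(t) - eta(ref))`, with a 95% Wald CI from the
#'     delta contrast `c'Vc` (`c` the design-row difference), so the
#'     reference row is exactly 1 with a collapsed CI;
#'   \item `hazard_prob = logit^{-1}(eta(t))` at the median person (u = 0);
#'   \item `survival_prob`: the cumulative product of complements of all
#'     *earlier* rows' hazards (the reference row's survival is 1).
#' }
#'
#' @param fit a converged [hazard_fit].
#' @param reference_hour reference interval index (default 8, "Before 8 AM");
#'   must not lie inside the risk window.
#' @param profile a [covariate_profile].
#' @param risk_window integer `c(first, last)` interval indices (default the
#'   window stored on the person-period table, hours 9-23).
#' @param ci_level confidence level (default 0.95).
#' @return data.frame of class `effect_table` with columns `hour`, `label`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `hazard_prob`, `survival_prob`;
#'   attributes `reference_hour`, `profile`, `convention`.
#' @export
effect_table <- function(fit, reference_hour = 8,
                         profile = covariate_profile(),
                         risk_window = c(9, 23), ci_level = 0.95) {
  assert_that(fit$converged, "fit did not converge")
  assert_that(reference_hour %in% c(risk_window[1] - 1,
                                    risk_window[1]:risk_window[2]),
              "reference hour must be the window's entry boundary or inside it")
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  hours <- sort(unique(c(reference_hour, risk_window[1]:risk_window[2])))
  x_ref <- design_row(fit, reference_hour, profile)
  rows <- lapply(hours, function(h) {
    x <- design_row(fit, h, profile)
    eta <- sum(x * fit$beta_internal)
    d <- x - x_ref
    delta <- sum(d * fit$beta_internal)
    se <- sqrt(drop(t(d) %*% fit$vcov_internal %*% d))
    data.frame(hour = h, label = hour_label(h),
               odds_ratio = exp(delta),
               ci_low = exp(delta - z * se),
               ci_high = exp(delta + z * se),
               hazard_prob = inv_logit(eta),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$survival_prob <- survival_from_hazard(out$hazard_prob)
  structure(out, reference_hour = reference_hour, profile = profile,
            convention = interval_convention(), ci_level = ci_level,
            class = c("effect_table", "data.frame"))
}

#' @rdname effect_table
#' @export
odds_ratio_table <- function(fit, reference_hour = 8,
                             profile = covariate_profile(),
                             risk_window = c(9, 23), ci_level = 0.95) {
  et <- effect_table(fit, reference_hour, profile, risk_window, ci_level)
  et[c("hour", "label", "odds_ratio", "ci_low", "ci_high")]
}

#' @rdname effect_table
#' @export
hazard_probability_table <- function(fit, reference_hour = 8,
                                     profile = covariate_profile(),
                                     risk_window = c(9, 23)) {
  et <- effect_table(fit, reference_hour, profile, risk_window)
  et[c("hour", "label", "hazard_prob", "survival_prob")]
}

#' Survival probabilities from ordered discrete hazards
#'
#' In discrete time the survival probability at a row is the product of the
#' complements of all earlier rows' hazards:
#' \deqn{S(\mathrm{row}\ k) = \prod_{j < k} (1 - h_j).}
#' When the hazard vector starts with the reference row (as in the effect
#' tables), the first survival value is exactly 1. Alternatively a separate
#' `reference_hazard` may be supplied for a vector that excludes the
#' reference row, in which case the first survival value is
#' `1 - reference_hazard`.
#'
#' @param hazards ordered per-row hazard probabilities in `[0, 1]`.
#' @param reference_hazard optional hazard of the row preceding `hazards[1]`.
#' @return numeric vector of survival probabilities, same length as input.
#' @examples
#' survival_from_hazard(c(0, 0.5, 0.5, 0.5))      # 1.00 1.00 0.50 0.25
#' survival_from_hazard(c(0.5, 0.5, 0.5), reference_hazard = 0)
#' @export
survival_from_hazard <- function(hazards, reference_hazard = NULL) {
  assert_that(is.numeric(hazards) && !anyNA(hazards) &&
                all(hazards >= 0 & hazards <= 1),
              "hazards must be probabilities in [0, 1]")
  if (is.null(reference_hazard)) {
    if (length(hazards) == 0) return(numeric())
    c(1, cumprod(1 - hazards))[seq_along(hazards)]
  } else {
    assert_that(reference_hazard >= 0 && reference_hazard <= 1,
                "reference hazard must be a probability")
    cumprod(1 - c(reference_hazard, hazards))[seq_along(hazards)]
  }
}

#' Compare two groups' odds ratios by confidence-interval overlap
#'
#' Flags an hour as a significant group difference when the two 95% CIs do
#' not overlap: `max(low_a, low_b) > min(high_a, high_b)`. This is the
#' CI-overlap convention for a two-sided test at the 5% level; it is
#' symmetric in its arguments.
#'
#' @param table_a,table_b effect tables (or OR tables) for the two groups,
#'   with identical hour rows.
#' @return data.frame of class `group_comparison`: per hour the two CI
#'   pairs, the OR difference `or_a - or_b`, and `significant`.
#' @export
ci_overlap_compare <- function(table_a, table_b) {
  assert_that(nrow(table_a) == nrow(table_b) &&
                all(table_a$hour == table_b$hour),
              "tables do not have matching hour rows")
  out <- data.frame(hour = table_a$hour, label = table_a$label,
                    or_a = table_a$odds_ratio, ci_low_a = table_a$ci_low,
                    ci_high_a = table_a$ci_high,
                    or_b = table_b$odds_ratio, ci_low_b = table_b$ci_low,
                    ci_high_b = table_b$ci_high,
                    stringsAsFactors = FALSE)
  out$or_diff <- out$or_a - out$or_b
  out$significant <- pmax(out$ci_low_a, out$ci_low_b) >
    pmin(out$ci_high_a, out$ci_high_b)
  class(out) <- c("group_comparison", "data.frame")
  out
}
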