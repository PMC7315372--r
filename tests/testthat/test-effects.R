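# a hand-built converged fit with chosen coefficients, for closed-form checks
fake_fit <- function(beta, vcov = diag(0, length(beta)), degree = 1,
                     moderator = NULL, include_interactions = FALSE) {
  spec <- model_spec(degree = degree, moderator = moderator,
                     include_interactions = include_interactions,
                     random_intercept = FALSE)
  structure(list(beta_internal = beta,
                 vcov_internal = `dimnames<-`(vcov,
                                              list(names(beta), names(beta))),
                 coefficients = beta, vcov = vcov, sigma_u = 0,
                 minus2LL = 0, converged = TRUE, dropped = character(),
                 spec = spec),
            class = "hazard_fit")
}

test_that("linear predictor is the plain dot product of design row and coefficients", {
  b <- c(`(Intercept)` = 0.4, time1 = -1.1, sexmale = 0.6,
         sexmale_x_time1 = 0.9)
  f <- fake_fit(b, degree = 1, moderator = "sex",
                include_interactions = TRUE)
  prof <- covariate_profile(sex = "male")
  for (h in c(8, 12, 23)) {
    s <- (h - 8) / 10
    expect_equal(linear_predictor(f, h, prof),
                 0.4 - 1.1 * s + 0.6 + 0.9 * s)
    expect_equal(linear_predictor(f, h),          # female reference
                 0.4 - 1.1 * s)
  }
  ## all-zero coefficients: eta identically zero, hazard 1/2
  f0 <- fake_fit(c(`(Intercept)` = 0, time1 = 0))
  expect_equal(linear_predictor(f0, 17), 0)
  et0 <- effect_table(f0)
  expect_true(all(et0$hazard_prob == 0.5))
  ## intercept-only curve is flat in the hour
  fc <- fake_fit(c(`(Intercept)` = -1, time1 = 0))
  expect_equal(length(unique(round(effect_table(fc)$hazard_prob, 12))), 1)
})

test_that("odds ratios anchor at the reference hour and extreme logits are safe", {
  f <- fake_fit(c(`(Intercept)` = -2, time1 = 6.931472 / 1.5))  # ln2 per hour/10...
  et <- effect_table(f)
  ref <- et[et$hour == 8, ]
  expect_equal(ref$odds_ratio, 1)
  expect_equal(ref$ci_low, 1)
  expect_equal(ref$ci_high, 1)
  ## zero-vcov fit: CI collapses onto the point estimate everywhere
  expect_equal(et$ci_low, et$odds_ratio)
  expect_equal(et$ci_high, et$odds_ratio)
  ## a delta of ln 2 with zero SE gives OR exactly 2
  f2 <- fake_fit(c(`(Intercept)` = 0, time1 = 10 * log(2)))
  et2 <- effect_table(f2)
  expect_equal(et2$odds_ratio[et2$hour == 9], 2, tolerance = 1e-12)
  ## deeply negative logit underflows to hazard 0 without warnings
  fneg <- fake_fit(c(`(Intercept)` = -30, time1 = 0))
  expect_equal(effect_table(fneg)$hazard_prob[1], 0, tolerance = 1e-12)
  expect_error(effect_table(f, reference_hour = 3), "reference hour")
})

test_that("Wald OR intervals agree with a parametric bootstrap from (beta, vcov)", {
  tm <- true_hazard_model(2, c("(Intercept)" = -2.2, time1 = 1.4,
                               time2 = -0.9),
                          sigma_u = 0, risk_window = c(9, 23))
  sim <- simulate_person_period(tm, 200, 8, seed = 21)
  f <- fit_hazard(sim$pp, model_spec(degree = 2, random_intercept = FALSE))
  et <- effect_table(f)
  set.seed(22)
  ch <- chol(f$vcov_internal)
  draws <- matrix(rnorm(10000 * length(f$beta_internal)), 10000) %*% ch
  draws <- sweep(draws, 2, f$beta_internal, "+")
  for (h in c(12, 17, 21)) {
    s <- (h - 8) / 10
    d <- c(0, s, s^2)        # contrast vs reference hour 8 (s = 0)
    lo <- exp(quantile(draws %*% d, 0.025))
    hi <- exp(quantile(draws %*% d, 0.975))
    row <- et[et$hour == h, ]
    expect_equal(row$ci_low, unname(lo), tolerance = 0.02)
    expect_equal(row$ci_high, unname(hi), tolerance = 0.02)
  }
})

test_that("survival is the running product of hazard complements", {
  expect_equal(survival_from_hazard(c(0, 0.5, 0.5, 0.5)),
               c(1, 1, 0.5, 0.25))
  expect_equal(survival_from_hazard(c(0.5, 0.5, 0.5), reference_hazard = 0),
               c(1, 0.5, 0.25))
  expect_equal(survival_from_hazard(rep(0, 6)), rep(1, 6))
  expect_error(survival_from_hazard(c(0.2, 1.4)), "probabilities")
  ## recurrence identity on a random vector
  set.seed(23)
  h <- runif(12)
  S <- survival_from_hazard(h)
  for (k in 2:12) expect_equal(S[k], S[k - 1] * (1 - h[k - 1]))
  expect_true(all(diff(S) <= 0))
})

test_that("effect tables carry non-increasing survival anchored at 1", {
  tm <- true_hazard_model(2, c("(Intercept)" = -2, time1 = 1.2,
                               time2 = -0.8),
                          sigma_u = 0, risk_window = c(9, 23))
  sim <- simulate_person_period(tm, 100, 6, seed = 24)
  et <- effect_table(fit_hazard(sim$pp,
                                model_spec(degree = 2,
                                           random_intercept = FALSE)))
  expect_equal(et$survival_prob[1], 1)
  expect_true(all(diff(et$survival_prob) <= 0))
  expect_true(all(et$ci_low <= et$odds_ratio + 1e-12 &
                    et$odds_ratio <= et$ci_high + 1e-12))
})

test_that("CI-overlap comparison flags only disjoint intervals and is symmetric", {
  tab <- function(or, lo, hi) data.frame(hour = seq_along(or),
                                         label = hour_label(seq_along(or)),
                                         odds_ratio = or, ci_low = lo,
                                         ci_high = hi)
  ## the published male-vs-female morning contrast: disjoint
  a <- tab(c(1.52, 1.5), c(1.29, 1.2), c(1.79, 2.0))
  b <- tab(c(1.12, 2.4), c(1.00, 1.9), c(1.25, 3.0))
  cmp <- ci_overlap_compare(a, b)
  expect_true(cmp$significant[1])      # (1.29,1.79) vs (1.00,1.25)
  expect_false(cmp$significant[2])     # (1.2,2.0) vs (1.9,3.0) overlap
  ## identical intervals are never significant
  expect_false(any(ci_overlap_compare(a, a)$significant))
  ## symmetry
  expect_equal(ci_overlap_compare(a, b)$significant,
               ci_overlap_compare(b, a)$significant)
  expect_error(ci_overlap_compare(a, b[1, ]), "matching")
})
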