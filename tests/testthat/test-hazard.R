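test_that("without a random intercept the fit matches a Newton-Raphson oracle", {
  tm <- true_hazard_model(2, c("(Intercept)" = -2, time1 = 1.2, time2 = -0.8),
                          sigma_u = 0, risk_window = c(9, 23))
  sim <- simulate_person_period(tm, 150, 6, seed = 11)
  f <- fit_hazard(sim$pp, model_spec(degree = 2, random_intercept = FALSE))
  s <- (sim$pp$t - 8) / 10
  X <- cbind(1, s, s^2)
  beta_oracle <- newton_logistic(X, sim$pp$event)
  expect_lt(max(abs(f$beta_internal - beta_oracle)), 1e-4)
  expect_true(f$converged)
  expect_equal(f$sigma_u, 0)
})

test_that("sigma_u fixed at zero in the data is recovered as (near) zero with matching coefficients", {
  tm <- true_hazard_model(1, c("(Intercept)" = -2, time1 = 1), sigma_u = 0,
                          risk_window = c(9, 20))
  sim <- simulate_person_period(tm, 200, 8, seed = 12)
  fmix <- fit_hazard(sim$pp, model_spec(degree = 1, random_intercept = TRUE,
                                        nodes = 9))
  fglm <- fit_hazard(sim$pp, model_spec(degree = 1, random_intercept = FALSE))
  expect_lt(fmix$sigma_u, 0.05)
  expect_lt(max(abs(fmix$beta_internal - fglm$beta_internal)), 1e-2)
})

test_that("a constant moderator is dropped and the reduced fit proceeds", {
  tm <- true_hazard_model(1, c("(Intercept)" = -1.5, time1 = 0.8),
                          sigma_u = 0, risk_window = c(9, 18))
  sim <- simulate_person_period(tm, 80, 5,
                                covariate_sampler = function(n)
                                  make_covs(seq_len(n), sex = "female"),
                                seed = 13)
  expect_warning(
    f <- fit_hazard(sim$pp, model_spec(degree = 1, moderator = "sex",
                                       random_intercept = FALSE)),
    "dropped")
  expect_true(f$converged)
  expect_setequal(f$dropped, c("sexmale", "sexmale_x_time1"))
  expect_setequal(names(f$beta_internal), c("(Intercept)", "time1"))
})

test_that("degenerate tables and empty risk windows are rejected", {
  tm <- true_hazard_model(1, c("(Intercept)" = -30, time1 = 0),
                          sigma_u = 0, risk_window = c(9, 14))
  sim <- simulate_person_period(tm, 30, 3, seed = 14)
  expect_error(fit_hazard(sim$pp, model_spec(degree = 1)), "degenerate")
  expect_error(true_hazard_model(1, c("(Intercept)" = 0, time1 = 0),
                                 risk_window = c(15, 12)), "risk window")
})

test_that("likelihood-ratio machinery: identity, chi-square tail, nesting guard", {
  tm <- true_hazard_model(2, c("(Intercept)" = -2, time1 = 1, time2 = -0.6),
                          sigma_u = 0, risk_window = c(9, 23))
  sim <- simulate_person_period(tm, 120, 6, seed = 15)
  f1 <- fit_hazard(sim$pp, model_spec(degree = 1, random_intercept = FALSE))
  f2 <- fit_hazard(sim$pp, model_spec(degree = 2, random_intercept = FALSE))
  f3 <- fit_hazard(sim$pp, model_spec(degree = 3, random_intercept = FALSE))

  self <- lrt(f2, f2a <- f2)
  expect_equal(self$chi2, 0)
  expect_equal(self$p, 1)
  ## adding parameters never worsens -2LL (optimizer tolerance)
  expect_lte(f2$minus2LL, f1$minus2LL + 1e-6)
  expect_lte(f3$minus2LL, f2$minus2LL + 1e-6)

  t12 <- lrt(f1, f2)
  expect_equal(t12$df, 1)
  expect_equal(t12$chi2, f1$minus2LL - f2$minus2LL, tolerance = 1e-10)
  ## the chi-square quantile identity at the conventional threshold
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)

  fmix <- fit_hazard(sim$pp, model_spec(degree = 1, random_intercept = TRUE,
                                        nodes = 1))
  expect_error(lrt(fmix, f2), "not nested")
})

test_that("self-test of lrt example: -2LL drop of 3.84 on 1 df has p just at 0.05", {
  f_small <- structure(list(coefficients = c(`(Intercept)` = 0),
                            beta_internal = c(`(Intercept)` = 0),
                            minus2LL = 1000, converged = TRUE,
                            n_rows = 10, n_events = 5,
                            spec = model_spec(degree = 1,
                                              random_intercept = FALSE)),
                       class = "hazard_fit")
  f_big <- structure(list(coefficients = c(`(Intercept)` = 0, t = 0),
                          beta_internal = c(`(Intercept)` = 0, time1 = 0),
                          minus2LL = 996.16, converged = TRUE,
                          n_rows = 10, n_events = 5,
                          spec = model_spec(degree = 1,
                                            random_intercept = FALSE)),
                     class = "hazard_fit")
  res <- lrt(f_small, f_big)
  expect_equal(res$chi2, 3.84, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p, 0.05, tolerance = 1e-3)
})

test_that("polynomial selection returns degree 1 with an empty trail when capped", {
  tm <- true_hazard_model(1, c("(Intercept)" = -2, time1 = 1), sigma_u = 0,
                          risk_window = c(9, 20))
  sim <- simulate_person_period(tm, 60, 5, seed = 16)
  sel <- select_time_polynomial(sim$pp, max_degree = 1,
                                random_intercept = FALSE)
  expect_equal(sel$degree, 1)
  expect_equal(nrow(sel$trail), 0)
})

test_that("moderator design expands a 3-level factor into two indicator blocks", {
  tm <- true_hazard_model(1, c("(Intercept)" = -1.5, time1 = 0.5,
                               bmioverweight = 0.3, bmiobese = -0.2),
                          sigma_u = 0, risk_window = c(9, 20))
  sampler <- function(n) make_covs(seq_len(n),
                                   bmi = sample(c("normal", "overweight",
                                                  "obese"), n, TRUE))
  sim <- simulate_person_period(tm, 150, 5, covariate_sampler = sampler,
                                seed = 17)
  f <- fit_moderator_model(sim$pp, "bmi_category", base_degree = 1,
                           random_intercept = FALSE)
  expect_setequal(names(f$beta_internal),
                  c("(Intercept)", "time1", "bmioverweight", "bmiobese",
                    "bmioverweight_x_time1", "bmiobese_x_time1"))
})

test_that("quadrature is converged: 9 vs 15 nodes agree to 1e-3", {
  tm <- true_hazard_model(1, c("(Intercept)" = -2, time1 = 1.2),
                          sigma_u = 0.7, risk_window = c(15, 21))
  sim <- simulate_person_period(tm, 250, 8, seed = 18)
  f9 <- fit_hazard(sim$pp, model_spec(degree = 1, nodes = 9))
  f15 <- fit_hazard(sim$pp, model_spec(degree = 1, nodes = 15))
  expect_lt(max(abs(f9$beta_internal - f15$beta_internal)), 1e-3)
  expect_lt(abs(f9$sigma_u - f15$sigma_u), 1e-3)
})

test_that("reported quantities are invariant to the internal time coding", {
  tm <- true_hazard_model(2, c("(Intercept)" = -2, time1 = 1, time2 = -0.7),
                          sigma_u = 0, risk_window = c(9, 23))
  sim <- simulate_person_period(tm, 150, 6, seed = 19)
  fa <- fit_hazard(sim$pp, model_spec(degree = 2, random_intercept = FALSE,
                                      time_ref = 8, time_scale = 10))
  fb <- fit_hazard(sim$pp, model_spec(degree = 2, random_intercept = FALSE,
                                      time_ref = 0, time_scale = 1))
  ta <- effect_table(fa)
  tb <- effect_table(fb)
  expect_equal(ta$odds_ratio, tb$odds_ratio, tolerance = 1e-6)
  expect_equal(ta$ci_low, tb$ci_low, tolerance = 1e-6)
  expect_equal(ta$hazard_prob, tb$hazard_prob, tolerance = 1e-6)
  ## and the back-transformed coefficients describe the same polynomial in t
  tt <- 9:23
  eta_a <- fa$coefficients["(Intercept)"] + fa$coefficients["t"] * tt +
    fa$coefficients["t2"] * tt^2
  eta_b <- fb$coefficients["(Intercept)"] + fb$coefficients["t"] * tt +
    fb$coefficients["t2"] * tt^2
  expect_equal(eta_a, eta_b, tolerance = 1e-6)
  expect_equal(unname(eta_a),
               vapply(tt, function(h) linear_predictor(fa, h), numeric(1)),
               tolerance = 1e-8)
})
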