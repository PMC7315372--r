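#' Specification of a discrete-time hazard model
#'
#' Describes the logistic hazard model fitted on the person-period table:
#' polynomial time of degree 1-3, an optional moderator entered as main
#' effect(s) with optional moderator-by-time interactions, and a
#' person-level random intercept. Time is internally centred at the
#' reference hour and divided by `time_scale` before powering, to condition
#' the cubic design; all reported quantities are back-transformed, and the
#' contrasts used downstream are invariant to this affine recoding.
#'
#' @param degree polynomial degree of time, 1-3.
#' @param moderator optional, one of `"sex"`, `"bmi_category"`, `"sports"`,
#'   `"school_day"`.
#' @param include_interactions include moderator-by-time-polynomial
#'   interactions (default: yes whenever a moderator is given).
#' @param time_ref reference hour subtracted from `t` (default 8, the
#'   "Before 8 AM" reference interval).
#' @param time_scale divisor applied after centring (default 10).
#' @param random_intercept include a person-level Gaussian random intercept.
#' @param nodes adaptive Gauss-Hermite quadrature nodes for the marginal
#'   likelihood (default 9; 1 is the Laplace approximation).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(degree = 3, moderator = NULL,
                       include_interactions = !is.null(moderator),
                       time_ref = 8, time_scale = 10,
                       random_intercept = TRUE, nodes = 9) {
  assert_that(degree %in% 1:3, "polynomial degree must be 1, 2 or 3")
  if (!is.null(moderator))
    assert_that(moderator %in% c("sex", "bmi_category", "sports",
                                 "school_day"),
                "unknown moderator")
  if (include_interactions)
    assert_that(!is.null(moderator), "interactions require a moderator")
  assert_that(time_scale > 0, "time_scale must be positive")
  assert_that(nodes >= 1, "at least one quadrature node")
  structure(list(degree = as.integer(degree), moderator = moderator,
                 include_interactions = include_interactions,
                 time_ref = time_ref, time_scale = time_scale,
                 random_intercept = random_intercept,
                 nodes = as.integer(nodes)),
            class = "model_spec")
}

## dummy columns for a moderator, reference levels: female / normal / 0 / 0
moderator_dummies <- function(pp, moderator) {
  switch(moderator,
    sex = {
      assert_that(all(pp$sex %in% c("female", "male")), "sex must be female/male")
      m <- cbind(sexmale = as.numeric(pp$sex == "male")); m
    },
    bmi_category = {
      assert_that(all(pp$bmi_category %in% c("normal", "overweight", "obese")),
                  "bmi_category must be normal/overweight/obese")
      cbind(bmioverweight = as.numeric(pp$bmi_category == "overweight"),
            bmiobese = as.numeric(pp$bmi_category == "obese"))
    },
    sports = cbind(sports1 = as.numeric(pp$sports == 1)),
    school_day = cbind(schoolday1 = as.numeric(pp$school_day == 1)))
}

## internal fixed-effects design (without intercept column), internal time scale
hazard_design <- function(pp, spec) {
  s <- (pp$t - spec$time_ref) / spec$time_scale
  X <- sapply(seq_len(spec$degree), function(k) s^k)
  colnames(X) <- paste0("time", seq_len(spec$degree))
  if (!is.null(spec$moderator)) {
    D <- moderator_dummies(pp, spec$moderator)
    X <- cbind(X, D)
    if (spec$include_interactions) {
      for (d in colnames(D)) for (k in seq_len(spec$degree)) {
        X <- cbind(X, D[, d] * (s^k))
        colnames(X)[ncol(X)] <- paste0(d, "_x_time", k)
      }
    }
  }
  X
}

## map internal-scale coefficients (s = (t - c)/d powers) to the original
## hour scale: s^k = sum_j choose(k,j) (-c)^(k-j) d^(-k) t^j
time_transform_matrix <- function(degree, ref, scale) {
  K <- degree
  A <- matrix(0, K + 1, K + 1)
  for (k in 0:K) for (j in 0:k)
    A[j + 1, k + 1] <- choose(k, j) * (-ref)^(k - j) / scale^k
  A
}

back_transform <- function(beta_int, vcov_int, spec, dummy_names) {
  A <- time_transform_matrix(spec$degree, spec$time_ref, spec$time_scale)
  blocks <- list(A)
  names_orig <- c("(Intercept)", paste0("t", seq_len(spec$degree)))
  names_orig[2] <- "t"
  for (d in dummy_names) {
    if (spec$include_interactions) {
      blocks[[length(blocks) + 1L]] <- A
      nm <- c(d, paste0(d, "_x_t", seq_len(spec$degree)))
    } else {
      blocks[[length(blocks) + 1L]] <- matrix(1, 1, 1)
      nm <- d
    }
    names_orig <- c(names_orig, nm)
  }
  C <- as.matrix(Matrix::bdiag(blocks))
  ## restrict to the coefficients actually present (columns may be dropped)
  present <- names(beta_int)
  full_int <- c("(Intercept)", paste0("time", seq_len(spec$degree)))
  for (d in dummy_names) {
    full_int <- c(full_int, d)
    if (spec$include_interactions)
      full_int <- c(full_int, paste0(d, "_x_time", seq_len(spec$degree)))
  }
  keep <- match(present, full_int)
  C <- C[, keep, drop = FALSE]
  beta_orig <- drop(C %*% beta_int)
  names(beta_orig) <- names_orig
  V_orig <- C %*% vcov_int %*% t(C)
  dimnames(V_orig) <- list(names_orig, names_orig)
  list(beta = beta_orig, vcov = V_orig)
}

#' Fit the multilevel discrete-time hazard model
#'
#' Maximizes the marginal likelihood of the logistic person-period model
#' \deqn{\Pr(y_{idt}=1 \mid u_i) = \mathrm{logit}^{-1}(x_{idt}'\beta + u_i),
#'   \quad u_i \sim N(0, \sigma_u^2),}
#' the integral over the random intercept approximated by adaptive
#' Gauss-Hermite quadrature (`spec$nodes` nodes; one node is the Laplace
#' approximation). With `random_intercept = FALSE` this is ordinary logistic
#' regression. Zero-variance (e.g. a moderator constant in the table) and
#' rank-deficient columns are dropped with a warning and recorded; optimizer
#' failure yields `converged = FALSE` with diagnostics, never an exception.
#'
#' @param pp person-period table from [build_person_period] (columns
#'   `participant_id`, `t`, `event`, covariates).
#' @param spec a [model_spec].
#' @return an object of class `hazard_fit`: `coefficients` and `vcov` on the
#'   original hour scale, `beta_internal` / `vcov_internal` on the fitted
#'   (centred/scaled) scale, `sigma_u`, `minus2LL`, counts, `converged`,
#'   `dropped` columns and the echoed `spec`.
#' @export
fit_hazard <- function(pp, spec = model_spec()) {
  assert_that(nrow(pp) > 0, "person-period table is empty")
  n_events <- sum(pp$event)
  assert_that(n_events > 0 && n_events < nrow(pp),
              "degenerate table (all rows events, or none): hazard not identifiable")
  X <- hazard_design(pp, spec)
  dummy_names <- if (!is.null(spec$moderator))
    colnames(moderator_dummies(pp, spec$moderator)) else character()

  ## drop zero-variance columns, then any column beyond the design rank
  dropped <- character()
  keep <- apply(X, 2, function(col) stats::var(col) > 0)
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    bad <- setdiff(seq_len(ncol(X) + 1L), qrX$pivot[seq_len(qrX$rank)]) - 1L
    dropped <- c(dropped, colnames(X)[bad])
    X <- X[, -bad, drop = FALSE]
  }
  if (length(dropped))
    warning("dropped non-identifiable column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)

  ## collapse Bernoulli rows to binomial counts per person x design row:
  ## the likelihood is identical up to the binomial-coefficient constant,
  ## which is removed again below so minus2LL stays on the Bernoulli scale
  agg <- data.table::as.data.table(cbind(data.frame(
    participant_id = pp$participant_id, event = pp$event), X))
  agg <- agg[, list(.y = sum(event), .n = .N),
             by = c("participant_id", colnames(X))]
  dat <- as.data.frame(agg)
  lchoose_const <- sum(lchoose(dat$.n, dat$.y))
  rhs <- paste(c("1", sprintf("`%s`", colnames(X))), collapse = " + ")

  diagnostics <- character()
  if (spec$random_intercept) {
    fml <- stats::as.formula(paste("cbind(.y, .n - .y) ~", rhs,
                                   "+ (1 | participant_id)"))
    fit <- withCallingHandlers(
      tryCatch(lme4::glmer(fml, data = dat, family = stats::binomial(),
                           nAGQ = spec$nodes,
                           control = lme4::glmerControl(optimizer = "bobyqa")),
               error = function(e) e),
      warning = function(w) {
        diagnostics <<- c(diagnostics, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (inherits(fit, "error"))
      return(failed_fit(spec, nrow(pp), length(unique(pp$participant_id)),
                        n_events, conditionMessage(fit)))
    beta_int <- lme4::fixef(fit)
    V_int <- withCallingHandlers(
      as.matrix(stats::vcov(fit)),
      warning = function(w) {
        diagnostics <<- c(diagnostics, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    sigma_u <- sqrt(as.numeric(lme4::VarCorr(fit)$participant_id))
    m2ll <- as.numeric(-2 * stats::logLik(fit)) + 2 * lchoose_const
    conv_code <- fit@optinfo$conv$opt
    converged <- is.numeric(conv_code) && conv_code == 0
  } else {
    fml <- stats::as.formula(paste("cbind(.y, .n - .y) ~", rhs))
    fit <- tryCatch(stats::glm(fml, data = dat, family = stats::binomial()),
                    error = function(e) e)
    if (inherits(fit, "error"))
      return(failed_fit(spec, nrow(pp), length(unique(pp$participant_id)),
                        n_events, conditionMessage(fit)))
    beta_int <- stats::coef(fit)
    V_int <- as.matrix(stats::vcov(fit))
    sigma_u <- 0
    m2ll <- as.numeric(-2 * stats::logLik(fit)) + 2 * lchoose_const
    converged <- isTRUE(fit$converged)
  }
  names(beta_int) <- gsub("`", "", names(beta_int))
  dimnames(V_int) <- list(names(beta_int), names(beta_int))
  bt <- back_transform(beta_int, V_int, spec, dummy_names)
  structure(list(coefficients = bt$beta, vcov = bt$vcov,
                 beta_internal = beta_int, vcov_internal = V_int,
                 sigma_u = sigma_u, minus2LL = m2ll,
                 n_rows = nrow(pp),
                 n_persons = length(unique(pp$participant_id)),
                 n_events = n_events,
                 converged = converged, dropped = dropped,
                 diagnostics = diagnostics, spec = spec),
            class = "hazard_fit")
}

failed_fit <- function(spec, n_rows, n_persons, n_events, msg) {
  structure(list(coefficients = NULL, vcov = NULL, beta_internal = NULL,
                 vcov_internal = NULL, sigma_u = NA_real_,
                 minus2LL = NA_real_, n_rows = n_rows, n_persons = n_persons,
                 n_events = n_events, converged = FALSE,
                 dropped = character(), diagnostics = msg, spec = spec),
            class = "hazard_fit")
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat(sprintf("<hazard_fit> degree %d%s, %s; %d rows / %d persons / %d events\n",
              x$spec$degree,
              if (!is.null(x$spec$moderator))
                paste0(" x ", x$spec$moderator) else "",
              if (x$spec$random_intercept)
                sprintf("random intercept (sigma_u = %.3f, %d-node AGQ)",
                        x$sigma_u, x$spec$nodes)
              else "fixed effects only",
              x$n_rows, x$n_persons, x$n_events))
  if (!x$converged) {
    cat("  ** did not converge **\n")
    return(invisible(x))
  }
  cat(sprintf("  -2LL = %.2f\n", x$minus2LL))
  est <- x$beta_internal
  se <- sqrt(diag(x$vcov_internal))
  print(round(cbind(estimate = est, se = se), 4))
  invisible(x)
}

## number of estimated parameters (fixed effects + variance component)
n_parameters <- function(fit) {
  length(fit$beta_internal) + as.integer(fit$spec$random_intercept)
}

#' Likelihood-ratio test of nested hazard fits
#'
#' Chi-square difference of the two fits' `-2 log L`, floored at zero, with
#' degrees of freedom equal to the parameter-count difference.
#'
#' @param nested,full [hazard_fit] objects on the same person-period table,
#'   the nested model's parameters a subset of the full model's.
#' @return list `chi2`, `df`, `p`.
#' @export
lrt <- function(nested, full) {
  stopifnot(inherits(nested, "hazard_fit"), inherits(full, "hazard_fit"))
  assert_that(nested$converged && full$converged,
              "both fits must have converged")
  assert_that(nested$n_rows == full$n_rows &&
                nested$n_events == full$n_events,
              "fits are not on the same person-period table")
  ## nesting check on the original-scale coefficient names
  assert_that(all(names(nested$coefficients) %in% names(full$coefficients)) &&
                nested$spec$random_intercept == full$spec$random_intercept,
              "models are not nested")
  df <- n_parameters(full) - n_parameters(nested)
  assert_that(df >= 0, "nested model has more parameters than the full model")
  chi2 <- max(0, nested$minus2LL - full$minus2LL)
  ## df = 0: the models coincide; a zero statistic carries p = 1
  p <- if (df == 0) as.numeric(chi2 <= 1e-8)
  else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Choose the polynomial degree of time by sequential likelihood-ratio tests
#'
#' Fits degrees `1..max_degree` (no moderator) and retains degree `k + 1`
#' over `k` whenever the likelihood-ratio test has `p < alpha`.
#'
#' @param pp person-period table.
#' @param max_degree highest degree tried (<= 3).
#' @param alpha per-step significance level (default 0.05).
#' @param ... passed to [model_spec] (e.g. `random_intercept`, `nodes`).
#' @return list `degree` (chosen), `fits` (per-degree [hazard_fit]s),
#'   `trail` (data.frame of the sequential tests).
#' @export
select_time_polynomial <- function(pp, max_degree = 3, alpha = 0.05, ...) {
  assert_that(max_degree %in% 1:3, "max_degree must be <= 3")
  fits <- lapply(seq_len(max_degree), function(k)
    fit_hazard(pp, model_spec(degree = k, ...)))
  chosen <- 1L
  trail <- list()
  for (k in seq_len(max_degree - 1)) {
    if (!fits[[k + 1]]$converged) break
    test <- lrt(fits[[chosen]], fits[[k + 1]])
    trail[[k]] <- data.frame(from = chosen, to = k + 1, chi2 = test$chi2,
                             df = test$df, p = test$p)
    if (test$p < alpha) chosen <- k + 1L else break
  }
  list(degree = chosen, fits = fits,
       trail = if (length(trail)) do.call(rbind, trail) else
         data.frame(from = integer(), to = integer(), chi2 = numeric(),
                    df = integer(), p = numeric()))
}

#' Fit a moderated hazard model
#'
#' The base polynomial-time model plus the moderator's main effect(s) and
#' moderator-by-time interactions for each polynomial term; each moderator
#' is modelled separately. The polynomial degree is inherited from the base
#' model selection (set `reselect = TRUE` to re-run selection with the
#' moderator included).
#'
#' @param pp person-period table.
#' @param moderator one of `"sex"`, `"bmi_category"`, `"sports"`,
#'   `"school_day"`.
#' @param base_degree degree chosen by [select_time_polynomial].
#' @param reselect re-run degree selection within the moderated model.
#' @param ... passed to [model_spec].
#' @return a [hazard_fit].
#' @export
fit_moderator_model <- function(pp, moderator, base_degree, reselect = FALSE,
                                ...) {
  if (reselect) {
    sel <- select_time_polynomial(pp, moderator = moderator,
                                  include_interactions = TRUE, ...)
    return(sel$fits[[sel$degree]])
  }
  fit_hazard(pp, model_spec(degree = base_degree, moderator = moderator,
                            include_interactions = TRUE, ...))
}
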