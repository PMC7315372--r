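#' Write epoch series to the epoch CSV dialect
#'
#' Columns: `participant_id`, `timestamp` (ISO-8601 local clock time),
#' `epoch_s`, `vm` (vector-magnitude counts). One row per epoch.
#'
#' @param series_list list of [epoch_series].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_epoch_csv <- function(series_list, path) {
  tabs <- lapply(series_list, function(s) {
    secs <- (seq_along(s$counts) - 1L) * s$epoch_s
    data.table::data.table(
      participant_id = s$participant_id,
      timestamp = paste0(format(s$date), "T",
                         sprintf("%02d:%02d:%02d", secs %/% 3600L,
                                 (secs %/% 60L) %% 60L, secs %% 60L)),
      epoch_s = s$epoch_s,
      vm = s$counts)
  })
  data.table::fwrite(data.table::rbindlist(tabs), path)
  invisible(path)
}

#' Read epoch-count CSV exports
#'
#' Parses `participant_id`, `timestamp` (ISO-8601 local), `epoch_s`, and
#' either a `vm` count column or three axis columns `axis1`, `axis2`,
#' `axis3` (vector magnitude is then the Euclidean norm rounded to the
#' nearest integer; a single `axis1` column is used as-is). Malformed rows
#' (unparseable timestamp, missing or negative counts) are collected into
#' the attached `report`, not silently dropped. Timestamps must be strictly
#' increasing within a participant. Partial days are zero-padded to full
#' days (zeros read as nonwear downstream) and noted in the report.
#'
#' @param path CSV file.
#' @return list of [epoch_series] (one per participant-day) with attribute
#'   `report` (data.frame of rejected rows and padding notes).
#' @export
read_epoch_csv <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path))
  dt <- data.table::fread(path, colClasses = list(character = "timestamp"))
  need <- c("participant_id", "timestamp", "epoch_s")
  miss <- setdiff(need, names(dt))
  assert_that(length(miss) == 0,
              paste("missing mandatory column(s):", paste(miss, collapse = ", ")))
  if (!"vm" %in% names(dt)) {
    if (all(c("axis1", "axis2", "axis3") %in% names(dt))) {
      dt$vm <- round(sqrt(dt$axis1^2 + dt$axis2^2 + dt$axis3^2))
    } else if ("axis1" %in% names(dt)) {
      dt$vm <- dt$axis1
    } else {
      stop("missing mandatory column(s): vm (or axis1[, axis2, axis3])",
           call. = FALSE)
    }
  }
  ts <- as.POSIXct(dt$timestamp, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  alt <- is.na(ts)
  ts[alt] <- as.POSIXct(dt$timestamp[alt], tz = "UTC",
                        format = "%Y-%m-%d %H:%M:%S")
  bad <- is.na(ts) | is.na(dt$vm) | dt$vm < 0 | is.na(dt$epoch_s)
  report <- data.frame(row = which(bad),
                       note = rep("malformed row (timestamp or counts)",
                                  sum(bad)),
                       stringsAsFactors = FALSE)
  ok <- dt[!bad]
  ts <- ts[!bad]
  assert_that(nrow(ok) > 0, "no parseable rows")
  ## strict monotonicity within participant
  ord <- order(ok$participant_id, ts)
  ok <- ok[ord]; ts <- ts[ord]
  same <- ok$participant_id[-1] == ok$participant_id[-nrow(ok)]
  nondec <- diff(as.numeric(ts)) <= 0
  assert_that(!any(same & nondec),
              "non-monotone timestamps within a participant")

  day <- as.Date(ts, tz = "UTC")
  sec <- as.numeric(ts) - as.numeric(as.POSIXct(paste(day, "00:00:00"),
                                                tz = "UTC"))
  key <- paste(ok$participant_id, day)
  out <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    ep <- ok$epoch_s[idx][1]
    assert_that(all(ok$epoch_s[idx] == ep),
                paste("mixed epoch lengths within", k))
    n_full <- 86400 %/% ep
    counts <- integer(n_full)
    pos <- sec[idx] %/% ep + 1L
    counts[pos] <- as.integer(ok$vm[idx])
    if (length(idx) < n_full)
      report <- rbind(report, data.frame(
        row = NA_integer_,
        note = sprintf("%s: %d of %d epochs present; zero-padded",
                       k, length(idx), n_full)))
    out[[length(out) + 1L]] <- epoch_series(ok$participant_id[idx][1],
                                            day[idx][1], ep, counts)
  }
  attr(out, "report") <- report
  out
}

#' @rdname run_pipeline
#' @export
pipeline_config <- function(epoch_csv = NULL, covariates_csv = NULL,
                            calendar_csv = NULL, out_dir = tempfile("mvpa_"),
                            params = algorithm_params(),
                            risk_window = c(9, 23), reference_hour = 8,
                            max_degree = 3, alpha = 0.05, nodes = 9,
                            random_intercept = TRUE,
                            moderators = c("sex", "bmi_category", "sports",
                                           "school_day"),
                            hypotheses = default_hypotheses(),
                            rel_tolerance = 0.05, span = 3, seed = 1L) {
  structure(list(epoch_csv = epoch_csv, covariates_csv = covariates_csv,
                 calendar_csv = calendar_csv, out_dir = out_dir,
                 params = params, risk_window = risk_window,
                 reference_hour = reference_hour, max_degree = max_degree,
                 alpha = alpha, nodes = nodes,
                 random_intercept = random_intercept,
                 moderators = moderators, hypotheses = hypotheses,
                 rel_tolerance = rel_tolerance, span = span,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

## write a data.frame as CSV with a commented provenance header
write_csv_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", header_lines), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes preprocess -> events -> hazard (polynomial selection, then one
#' moderated model per configured moderator, estimated separately) ->
#' effects -> decision points, writing every stage's output under
#' `config$out_dir`, plus a structured log recording the constants,
#' exclusions, convergence and conventions used. Inputs come either from
#' the CSV paths in the config or from an in-memory `cohort` (a list with
#' `series`, `covariates`, `calendar`, as returned by [simulate_cohort]).
#'
#' @param config a [pipeline_config].
#' @param cohort optional in-memory cohort overriding the CSV paths.
#' @return the artifact bundle (list of all stage outputs), invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline_log.txt")
  log_lines <- c(sprintf("run seed: %d", config$seed),
                 interval_convention(),
                 utils::capture.output(print(config$params)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ## ---- inputs
  if (is.null(cohort)) {
    cohort <- stage("read", {
      assert_that(!is.null(config$epoch_csv) && !is.null(config$covariates_csv)
                  && !is.null(config$calendar_csv),
                  "config must give epoch, covariate and calendar CSV paths (or pass an in-memory cohort)")
      list(series = read_epoch_csv(config$epoch_csv),
           covariates = utils::read.csv(config$covariates_csv,
                                        stringsAsFactors = FALSE),
           calendar = transform(
             utils::read.csv(config$calendar_csv, stringsAsFactors = FALSE),
             date = as.Date(date)))
    })
  }

  ## ---- preprocess
  pre <- stage("preprocess", {
    summaries <- summarize_cohort(cohort$series, cohort$calendar,
                                  config$params)
    apply_inclusion_rules(summaries, config$params)
  })
  write_csv_with_header(pre$summaries,
                        file.path(config$out_dir, "day_summaries.csv"),
                        c("per participant-day wear and hourly MVPA minutes",
                          interval_convention()))
  write_csv_with_header(pre$log,
                        file.path(config$out_dir, "exclusion_log.csv"),
                        "every excluded day/participant and the rule that removed it")
  log_lines <- c(log_lines,
                 sprintf("days kept: %d; exclusions: %d", nrow(pre$summaries),
                         nrow(pre$log)))

  ## ---- events
  ev <- stage("events", {
    means <- person_mean_mvpa(pre$summaries)
    pp <- build_person_period(pre$summaries, means, cohort$covariates,
                              risk_window = config$risk_window)
    list(means = means, pp = pp)
  })
  write_csv_with_header(ev$pp, file.path(config$out_dir, "person_period.csv"),
                        c(sprintf("discrete-time risk set, intervals %d..%d",
                                  config$risk_window[1], config$risk_window[2]),
                          interval_convention()))
  log_lines <- c(log_lines,
                 sprintf("risk window: intervals %d..%d (reference %d)",
                         config$risk_window[1], config$risk_window[2],
                         config$reference_hour),
                 sprintf("person-period rows: %d, events: %d",
                         nrow(ev$pp), sum(ev$pp$event)),
                 sprintf("event-coding exclusions: %d day(s)",
                         nrow(attr(ev$pp, "log"))))

  ## ---- hazard models
  haz <- stage("hazard", {
    sel <- select_time_polynomial(ev$pp, max_degree = config$max_degree,
                                  alpha = config$alpha,
                                  random_intercept = config$random_intercept,
                                  nodes = config$nodes)
    mods <- lapply(stats::setNames(config$moderators, config$moderators),
                   function(m)
                     fit_moderator_model(ev$pp, m, sel$degree,
                                         random_intercept =
                                           config$random_intercept,
                                         nodes = config$nodes))
    list(selection = sel, base = sel$fits[[sel$degree]], moderated = mods)
  })
  fit_record <- function(f) {
    if (!f$converged) return(list(converged = FALSE,
                                  diagnostics = f$diagnostics))
    list(converged = TRUE,
         coefficients = as.list(round(f$beta_internal, 6)),
         se = as.list(round(sqrt(diag(f$vcov_internal)), 6)),
         sigma_u = f$sigma_u, minus2LL = f$minus2LL,
         n_rows = f$n_rows, n_persons = f$n_persons, n_events = f$n_events,
         degree = f$spec$degree, moderator = f$spec$moderator,
         nodes = f$spec$nodes,
         time_coding = sprintf("s = (t - %g)/%g", f$spec$time_ref,
                               f$spec$time_scale),
         dropped = f$dropped)
  }
  jsonlite::write_json(
    c(list(base = fit_record(haz$base),
           selection_trail = haz$selection$trail),
      lapply(haz$moderated, fit_record)),
    file.path(config$out_dir, "model_fits.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  log_lines <- c(log_lines,
                 sprintf("polynomial degree selected: %d",
                         haz$selection$degree),
                 sprintf("convergence: base=%s, %s", haz$base$converged,
                         paste(sprintf("%s=%s", names(haz$moderated),
                                       vapply(haz$moderated,
                                              function(f) f$converged,
                                              logical(1))),
                               collapse = ", ")))

  ## ---- effect tables
  eff <- stage("effects", {
    overall <- effect_table(haz$base, config$reference_hour,
                            covariate_profile(), config$risk_window)
    levels_of <- list(sex = c("male", "female"),
                      bmi_category = c("normal", "overweight", "obese"),
                      sports = c(1, 0), school_day = c(1, 0))
    by_mod <- list()
    for (m in intersect(config$moderators, names(haz$moderated))) {
      f <- haz$moderated[[m]]
      if (!f$converged) next
      profs <- lapply(levels_of[[m]], function(v) {
        p <- covariate_profile()
        p[[m]] <- v
        p
      })
      tabs <- lapply(profs, function(p)
        effect_table(f, config$reference_hour, p, config$risk_window))
      names(tabs) <- as.character(levels_of[[m]])
      ## primary contrast: first listed level vs last (extremes for BMI)
      cmp <- ci_overlap_compare(tabs[[1]], tabs[[length(tabs)]])
      by_mod[[m]] <- list(tables = tabs, comparison = cmp,
                          label_a = as.character(levels_of[[m]][1]),
                          label_b = as.character(
                            levels_of[[m]][length(levels_of[[m]])]))
    }
    list(overall = overall, by_mod = by_mod)
  })
  hdr <- c(sprintf("covariate profile: %s",
                   paste(names(attr(eff$overall, "profile")),
                         unlist(attr(eff$overall, "profile")),
                         sep = "=", collapse = ", ")),
           sprintf("reference hour: %d (%s)", config$reference_hour,
                   hour_label(config$reference_hour)),
           interval_convention())
  write_csv_with_header(
    eff$overall[c("hour", "label", "odds_ratio", "ci_low", "ci_high")],
    file.path(config$out_dir, "or_table_overall.csv"), hdr)
  write_csv_with_header(
    eff$overall[c("hour", "label", "hazard_prob", "survival_prob")],
    file.path(config$out_dir, "hazard_survival.csv"), hdr)
  for (m in names(eff$by_mod))
    for (lv in names(eff$by_mod[[m]]$tables))
      write_csv_with_header(
        as.data.frame(eff$by_mod[[m]]$tables[[lv]]),
        file.path(config$out_dir, sprintf("or_table_%s_%s.csv", m, lv)),
        c(sprintf("moderator %s = %s", m, lv), hdr))

  ## ---- decision points
  dec <- stage("decide", {
    moderator_decision_points(eff$overall,
                              lapply(eff$by_mod, function(x)
                                x[c("comparison", "label_a", "label_b")]),
                              hypotheses = config$hypotheses,
                              rel_tolerance = config$rel_tolerance,
                              span = config$span)
  })
  dec_rows <- data.frame(
    moderator = c("(overall)", names(dec$moderator_findings)),
    criterion1 = c(NA, vapply(dec$moderator_findings,
                              function(f) f$criterion1_met, logical(1))),
    criterion2 = c(NA, vapply(dec$moderator_findings,
                              function(f) f$criterion2_met, logical(1))),
    window = c(paste(dec$overall_window$label[1], "-",
                     dec$overall_window$label[nrow(dec$overall_window)]),
               vapply(dec$moderator_findings, function(f)
                 if (is.null(f$window)) "" else
                   paste(f$window$label[1], "-",
                         f$window$label[nrow(f$window)]), character(1))),
    rationale = c("peak-hazard run", vapply(dec$moderator_findings,
                                            function(f) f$rationale,
                                            character(1))),
    stringsAsFactors = FALSE)
  write_csv_with_header(dec_rows,
                        file.path(config$out_dir, "decision_points.csv"),
                        c("intervention decision points", interval_convention()))
  writeLines(utils::capture.output(print(dec)),
             file.path(config$out_dir, "decision_report.txt"))

  writeLines(log_lines, log_path)
  invisible(list(preprocess = pre, events = ev, hazard = haz,
                 effects = eff, decisions = dec, config = config,
                 out_dir = config$out_dir))
}

#' Published per-hour hazard and survival probabilities
#'
#' The printed hazard and survival columns reported for an observed
#' adolescent cohort (16 hourly rows, "Before 8 AM" through "Before 11 PM"),
#' shipped as a plain-text reference input: feeding the hazard column to
#' [survival_from_hazard] reproduces the survival column to within printed
#' rounding, and the decision-window rules applied to it reproduce the
#' published 5-8 PM intervention window.
#'
#' @return data.frame `hour`, `label`, `hazard_prob`, `survival_prob`.
#' @export
published_hazard_survival <- function() {
  path <- system.file("extdata", "published_hazard_survival.csv",
                      package = "mvpatiming")
  assert_that(nzchar(path), "reference table not installed")
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  out
}
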