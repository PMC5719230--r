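# Study-level orchestration: run configuration with YAML round-trip,
# simulation to CSV, end-to-end analysis and a JSON report.

#' Run configuration
#'
#' Bundles the root seed, task and cohort parameters, and the analysis
#' switches into one object that round-trips losslessly through YAML.
#'
#' @param seed root integer seed; all substreams derive from it.
#' @param task list of [task_config()] overrides.
#' @param cohort list of [cohort_config()] overrides.
#' @param analysis list of analysis switches: `min_rt_ms` (anticipatory
#'   filter), `min_stop_responses`, `verbatim_rt_rule`,
#'   `presignal_as_response`, `censor_at` (`NA` = treat all exits as
#'   events), `welch`, `k_sessions`, `outlier_iqr`, `conforming_only`.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, task = list(), cohort = list(),
                       analysis = list()) {
  an <- utils::modifyList(list(min_rt_ms = 150, min_stop_responses = 10,
                               verbatim_rt_rule = FALSE,
                               presignal_as_response = TRUE,
                               censor_at = 10, welch = FALSE,
                               k_sessions = 4, outlier_iqr = 4,
                               conforming_only = TRUE),
                          analysis)
  structure(list(seed = as.integer(seed), task = task, cohort = cohort,
                 analysis = an),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  run_config(seed = raw$seed %||% 1L, task = raw$task %||% list(),
             cohort = raw$cohort %||% list(),
             analysis = raw$analysis %||% list())
}

build_task <- function(config) do.call(task_config, config$task)

build_cohort_cfg <- function(config) {
  args <- config$cohort
  args$seed <- config$seed
  do.call(cohort_config, args)
}

#' Simulate a study and write its artifacts
#'
#' Generates a cohort under `config` and writes `trials.csv`,
#' `sessions.csv`, `truth.csv` and the effective configuration
#' (`run_config.yaml`) into `dir`.
#'
#' @param config a [run_config()].
#' @param dir output directory.
#' @return the `sst_cohort`, invisibly.
#' @export
simulate_study <- function(config = run_config(), dir) {
  cohort <- generate_cohort(build_cohort_cfg(config), build_task(config))
  write_cohort(cohort, dir)
  write_run_config(config, file.path(dir, "run_config.yaml"))
  invisible(cohort)
}

session_scores <- function(sessions) {
  # per-session questionnaire mean on the form delivered that session
  vapply(seq_len(nrow(sessions)), function(i) {
    s <- sessions[i, ]
    q <- as.numeric(s[paste0("q", 1:10)])
    names(q) <- paste0("q", 1:10)
    suppressWarnings(score_questionnaire(q, questionnaire_form(s$session_number)))
  }, numeric(1))
}

return_pairs <- function(sessions, compulsory = 4L, maximum = 10L) {
  # (day-k questionnaire score, returned on day k+1) over the optional phase
  sc <- session_scores(sessions)
  out <- list()
  for (pid in unique(sessions$participant_id)) {
    srows <- sessions$session_number[sessions$participant_id == pid]
    for (k in compulsory:(maximum - 1L)) {
      idx <- which(sessions$participant_id == pid &
                     sessions$session_number == k)
      if (length(idx) == 1L && !is.na(sc[idx])) {
        out[[length(out) + 1L]] <- data.frame(
          participant_id = pid, day = k, score = sc[idx],
          returned = as.integer((k + 1L) %in% srows))
      }
    }
  }
  do.call(rbind, out)
}

#' Analyze a simulated or replayed study
#'
#' Runs the full analysis pipeline on a cohort (an `sst_cohort` or a
#' directory of CSVs): conformance classification, attrition summary and
#' tests (log-rank, one-way ANOVA, JZS Bayes factors on sessions
#' completed), per-session SSRT summaries with race-model exclusions,
#' participant aggregation and outlier screening, questionnaire scoring
#' with the mixed ANOVA and post hoc tests, objective-engagement ANOVAs,
#' and the next-day-return logistic regression.
#'
#' @param cohort an `sst_cohort` or a directory path.
#' @param config a [run_config()]; analysis switches are honoured.
#' @return list of class `sst_analysis`; see `$report` for the serializable
#'   summary written by [write_report()].
#' @export
analyze_study <- function(cohort, config = run_config()) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stopifnot(inherits(cohort, "sst_cohort"))
  an <- config$analysis
  if (nrow(cohort$sessions) == 0L) stop("empty cohort: no sessions to analyze")

  records <- attrition_records(cohort$sessions)
  analyzed <- if (isTRUE(an$conforming_only))
    records$participant_id[records$conformance == "conforming"] else
      records$participant_id
  rec_a <- records[records$participant_id %in% analyzed, , drop = FALSE]
  if (nrow(rec_a) == 0L) stop("no participants left after conformance filter")
  attr_sum <- attrition_summary(rec_a)

  censor_at <- an$censor_at
  if (is.null(censor_at) || (length(censor_at) == 1 && is.na(censor_at)))
    censor_at <- NULL
  tests <- list()
  if (length(unique(rec_a$variant)) >= 2) {
    tests$logrank <- logrank_test(rec_a$sessions_completed, rec_a$variant,
                                  censor_at = censor_at)
    tests$anova_sessions <- oneway_anova(rec_a$sessions_completed,
                                         rec_a$variant)
    vs <- sort(unique(rec_a$variant))
    bf <- list()
    for (i in seq_along(vs)) for (j in seq_along(vs)) if (i < j) {
      a <- rec_a$sessions_completed[rec_a$variant == vs[i]]
      b <- rec_a$sessions_completed[rec_a$variant == vs[j]]
      bf[[paste(vs[i], vs[j], sep = "_vs_")]] <- jzs_bayes_t(a, b)
    }
    tests$bayes_sessions <- bf
  }

  sessions_a <- cohort$sessions[cohort$sessions$participant_id %in% analyzed, ,
                                drop = FALSE]
  trials_a <- cohort$trials[cohort$trials$participant_id %in% analyzed, ,
                            drop = FALSE]
  summaries <- summarize_sessions(
    trials_a, sessions_a, min_rt_ms = an$min_rt_ms,
    min_stop_responses = an$min_stop_responses,
    presignal_as_response = an$presignal_as_response,
    verbatim_rt_rule = an$verbatim_rt_rule)
  participants <- aggregate_participants(summaries, k = an$k_sessions)
  participants <- merge(participants,
                        rec_a[, c("participant_id", "variant",
                                  "sessions_completed", "conformance")],
                        by = "participant_id")
  screened <- exclude_outlier_participants(participants,
                                           k_iqr = an$outlier_iqr)
  focus <- stats::aggregate(
    loss_of_focus_count ~ participant_id,
    data = sessions_a[sessions_a$session_number <= an$k_sessions, ],
    FUN = mean)
  names(focus)[2] <- "mean_loss_of_focus"
  screened <- merge(screened, focus, by = "participant_id", all.x = TRUE)

  if (length(unique(screened$variant)) >= 2) {
    ok <- !is.na(screened$mean_ssrt_ms)
    tests$anova_ssrt <- oneway_anova(screened$mean_ssrt_ms[ok],
                                     screened$variant[ok])
    tests$anova_cv <- oneway_anova(screened$mean_cv_percent,
                                   screened$variant)
    tests$anova_focus <- oneway_anova(screened$mean_loss_of_focus,
                                      screened$variant)
  }

  # subjective engagement: sessions 1 and 4 (both long form)
  sc <- session_scores(sessions_a)
  s1 <- sc[sessions_a$session_number == 1]
  names(s1) <- sessions_a$participant_id[sessions_a$session_number == 1]
  s4 <- sc[sessions_a$session_number == 4]
  names(s4) <- sessions_a$participant_id[sessions_a$session_number == 4]
  ids <- intersect(names(s1), names(s4))
  ids <- intersect(ids, screened$participant_id)
  if (length(ids) >= 6) {
    gv <- screened$variant[match(ids, screened$participant_id)]
    if (length(unique(gv)) >= 2) {
      tests$rm_anova_engagement <- rm_anova(s1[ids], s4[ids], gv)
      comb <- combined_score(s1[ids], s4[ids])
      vs <- sort(unique(gv))
      ph <- list()
      for (i in seq_along(vs)) for (j in seq_along(vs)) if (i < j)
        ph[[paste(vs[i], vs[j], sep = "_vs_")]] <-
          posthoc_t(comb[gv == vs[i]], comb[gv == vs[j]], welch = an$welch)
      tests$posthoc_engagement <- ph
    }
  }

  rp <- return_pairs(sessions_a, maximum = max(cohort$sessions$session_number,
                                               10))
  if (!is.null(rp) && nrow(rp) >= 10 && length(unique(rp$returned)) == 2)
    tests$logistic_return <- logistic_return_model(rp$score, rp$returned)

  excl_tab <- table(summaries$exclusion_reason[!summaries$valid])
  report <- list(
    n_participants = nrow(records),
    n_analyzed = nrow(rec_a),
    n_after_outlier_screen = nrow(screened),
    outliers_excluded = attr(screened, "excluded"),
    conformance = as.list(table(records$conformance)),
    sessions_summarized = nrow(summaries),
    sessions_excluded = sum(!summaries$valid),
    exclusion_reasons = as.list(excl_tab),
    ssrt_excluded_participants = sum(screened$ssrt_excluded),
    attrition = attr_sum,
    tests = lapply(tests, serialize_result)
  )
  structure(list(records = records, summaries = summaries,
                 participants = screened, attrition = attr_sum,
                 tests = tests, return_data = rp, report = report,
                 config = config),
            class = "sst_analysis")
}

serialize_result <- function(x) {
  if (inherits(x, "sst_test"))
    return(list(name = x$name, statistic = x$statistic, df = x$df,
                p_value = x$p_value, effect_size = x$effect_size,
                ci_95 = x$ci_95))
  if (inherits(x, "sst_bayes"))
    return(list(bf10 = x$bf10, prior_scale = x$prior_scale, t = x$t,
                df = x$df, label = x$label, favors = x$favors))
  if (inherits(x, "sst_rm_anova"))
    return(lapply(x[c("between", "within", "interaction")], serialize_result))
  if (inherits(x, "sst_logistic"))
    return(list(beta = x$beta, se = x$se, wald_chisq = x$wald_chisq,
                p_value = x$p_value, odds_ratio = x$odds_ratio,
                or_ci_95 = x$or_ci_95, separation = x$separation, n = x$n))
  if (is.list(x)) return(lapply(x, serialize_result))
  x
}

#' Write the analysis report as JSON
#'
#' Serializes `analysis$report` with fixed precision so a fixed-seed run
#' yields a byte-stable file.
#'
#' @param analysis an `sst_analysis`.
#' @param path output file.
#' @param digits significant digits for numbers.
#' @return `path`, invisibly.
#' @export
write_report <- function(analysis, path, digits = 8) {
  stopifnot(inherits(analysis, "sst_analysis"))
  jsonlite::write_json(analysis$report, path, auto_unbox = TRUE,
                       digits = digits, pretty = TRUE, force = TRUE)
  invisible(path)
}
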