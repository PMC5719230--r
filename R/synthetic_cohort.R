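# Race-model cohort simulator. Generates cohorts with the statistical
# structure the analysis assumes -- independent-race trial behaviour with a
# known true stopping latency, variant-specific dropout hazards over a
# 4-compulsory + 6-optional session design, visual-analog questionnaire
# scores and Poisson loss-of-focus counts -- so every downstream estimate
# has a recoverable ground truth.

#' Participant profile (latent simulator truth)
#'
#' @param id participant identifier.
#' @param variant task variant label: `nongame`, `points` or `theme`.
#' @param go_mu,go_sigma,go_tau ex-Gaussian go-RT parameters (ms).
#' @param stop_mean,stop_sd stopping-latency mean and trial-to-trial SD (ms);
#'   `stop_mean` is the participant's true SSRT.
#' @param lapse_prob probability of an omission on a go trial.
#' @param choice_error_prob probability a go response hits the wrong key.
#' @param dropout_hazard per-optional-day probability of dropping out;
#'   scalar or a vector over optional days.
#' @param q_mean_s1,q_mean_s4 expected questionnaire score (0-100, after
#'   reverse scoring) at sessions 1 and 4; intermediate sessions
#'   interpolate linearly, later sessions hold the session-4 level.
#' @param q_sd item-level SD of questionnaire responses.
#' @param focus_rate expected loss-of-focus events per session (Poisson).
#' @return a list of class `participant_profile`.
#' @export
participant_profile <- function(id, variant = "nongame",
                                go_mu = 380, go_sigma = 50, go_tau = 120,
                                stop_mean = 270, stop_sd = 20,
                                lapse_prob = 0.02, choice_error_prob = 0.02,
                                dropout_hazard = 0.15,
                                q_mean_s1 = 56, q_mean_s4 = 51, q_sd = 20,
                                focus_rate = 0.95) {
  stopifnot(go_mu > 0, go_sigma > 0, go_tau > 0, stop_mean > 0, stop_sd >= 0,
            lapse_prob >= 0, lapse_prob <= 1,
            choice_error_prob >= 0, choice_error_prob <= 1,
            all(dropout_hazard >= 0), all(dropout_hazard <= 1),
            q_mean_s1 >= 0, q_mean_s1 <= 100, q_mean_s4 >= 0, q_mean_s4 <= 100)
  structure(as.list(environment()), class = "participant_profile")
}

#' Simulate one trial under the independent race model
#'
#' Go trials: with probability `lapse_prob` the trial is an omission;
#' otherwise the RT is a truncated ex-Gaussian draw on (0, 900\] and the
#' response is an error with probability `choice_error_prob`. Stop trials:
#' the go finishing time races a stopping process started at the SSD; the
#' participant responds iff the go process finishes before SSD + stopping
#' latency. A response landing before the SSD is a `stop_presignal` (the
#' signal was never shown); a lapse on a stop trial counts as an inhibition.
#'
#' @param profile a `participant_profile`.
#' @param trial_type `"go"` or `"stop"`.
#' @param ssd_ms stop-signal delay (ms); required for stop trials.
#' @param display_ms display window upper bound for RTs (ms).
#' @return list with `outcome` and `rt_ms` (`NA` when no response occurred).
#' @export
simulate_trial_response <- function(profile, trial_type, ssd_ms = NULL,
                                    display_ms = 900) {
  stopifnot(inherits(profile, "participant_profile"))
  if (trial_type == "go") {
    if (runif(1) < profile$lapse_prob)
      return(list(outcome = "go_omission", rt_ms = NA_real_))
    rt <- rexgauss_trunc(1, profile$go_mu, profile$go_sigma, profile$go_tau,
                         hi = display_ms)
    out <- if (runif(1) < profile$choice_error_prob) "go_error" else "go_success"
    return(list(outcome = out, rt_ms = rt))
  }
  if (is.null(ssd_ms) || is.na(ssd_ms)) stop("ssd_ms required for stop trials")
  if (runif(1) < profile$lapse_prob)
    return(list(outcome = "stop_inhibit", rt_ms = NA_real_))
  t_go <- rexgauss_trunc(1, profile$go_mu, profile$go_sigma, profile$go_tau,
                         hi = display_ms)
  t_stop <- rnorm(1, profile$stop_mean, profile$stop_sd)
  while (t_stop <= 0) t_stop <- rnorm(1, profile$stop_mean, profile$stop_sd)
  if (t_go < ssd_ms + t_stop) {
    out <- if (t_go < ssd_ms) "stop_presignal" else "stop_respond"
    list(outcome = out, rt_ms = t_go)
  } else {
    list(outcome = "stop_inhibit", rt_ms = NA_real_)
  }
}

#' Simulate a full task session
#'
#' Generates a schedule, runs every trial through the race model while the
#' four SSD staircases and (for the points variant) the scoring state evolve,
#' and attaches a questionnaire response and a loss-of-focus count.
#'
#' @param profile a `participant_profile`.
#' @param session_number 1-based session index.
#' @param config a [task_config()].
#' @param seed integer seed for this participant; session-specific
#'   substreams are derived internally.
#' @param high_score carried-over best score (points variant).
#' @return list with elements `trials` (data frame in the trial-log schema),
#'   `questionnaire` (named numeric, `NA` for items absent from the short
#'   form), `loss_of_focus`, `total_score`, `high_score`.
#' @export
simulate_session <- function(profile, session_number, config = task_config(),
                             seed = NULL, high_score = 0) {
  sched <- generate_schedule(config$n_blocks, config$trials_per_block,
                             config$stop_fraction,
                             seed = substream_seed(seed %||% 0L, "schedule",
                                                   session_number))
  n <- nrow(sched)
  scored <- identical(profile$variant, "points")
  with_seed(substream_seed(seed %||% 0L, "responses", session_number), {
    bank <- new_staircase_bank(config$staircase_start_ms,
                               config$staircase_step_ms,
                               config$staircase_bounds_ms)
    state <- new_scoring_state(config, high_score = high_score)
    ssd <- rep(NA_real_, n); sc_id <- rep(NA_integer_, n)
    outcome <- character(n); rt <- rep(NA_real_, n)
    points <- rep(NA_real_, n); bonus_after <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if (sched$trial_type[i] == "stop") {
        draw <- next_stop_ssd(bank)
        bank <- draw$bank
        ssd[i] <- draw$ssd_ms; sc_id[i] <- draw$staircase_id
        res <- simulate_trial_response(profile, "stop", ssd[i],
                                       config$display_ms)
        bank <- update_staircase(bank, sc_id[i],
                                 inhibited = res$outcome == "stop_inhibit")
      } else {
        res <- simulate_trial_response(profile, "go",
                                       display_ms = config$display_ms)
      }
      outcome[i] <- res$outcome; rt[i] <- res$rt_ms
      if (scored) {
        sc <- apply_scoring(state, res$outcome, res$rt_ms)
        state <- sc$state
        points[i] <- sc$points; bonus_after[i] <- state$bonus
      }
    }
    trials <- data.frame(
      participant_id = profile$id, session_number = session_number,
      block = sched$block, trial_index = sched$trial_index,
      trial_type = sched$trial_type, ssd_ms = ssd, staircase_id = sc_id,
      outcome = outcome, rt_ms = rt, points = points,
      bonus_after = bonus_after, stringsAsFactors = FALSE
    )
    list(trials = trials,
         questionnaire = simulate_questionnaire(profile, session_number, seed),
         loss_of_focus = rpois_sub(seed, "focus", session_number,
                                   profile$focus_rate),
         total_score = if (scored) state$total_score else NA_real_,
         high_score = if (scored) state$high_score else NA_real_)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rpois_sub <- function(seed, stream, index, lambda) {
  with_seed(substream_seed(seed %||% 0L, stream, index), rpois(1, lambda))
}

# Long form (10 items) on sessions 1, 4, 7, 10; short form carries items
# 1, 2, 5, 8, 9. Items 2, 3, 6, 8 are phrased negatively, so they are
# generated around 100 - mean and recovered by reverse scoring.
simulate_questionnaire <- function(profile, session_number, seed = NULL) {
  items <- questionnaire_items(questionnaire_form(session_number))
  m1 <- profile$q_mean_s1; m4 <- profile$q_mean_s4
  mean_t <- if (session_number >= 4) m4 else m1 + (session_number - 1) / 3 * (m4 - m1)
  with_seed(substream_seed(seed %||% 0L, "questionnaire", session_number), {
    out <- rep(NA_real_, 10)
    names(out) <- paste0("q", 1:10)
    for (i in items) {
      centre <- if (i %in% reverse_items()) 100 - mean_t else mean_t
      out[i] <- min(100, max(0, rnorm(1, centre, profile$q_sd)))
    }
    out
  })
}

#' @rdname score_questionnaire
#' @export
questionnaire_form <- function(session_number) {
  if (session_number %in% c(1, 4, 7, 10)) "long" else "short"
}

#' @rdname score_questionnaire
#' @param form `"long"` (all 10 items) or `"short"` (items 1, 2, 5, 8, 9).
#' @export
questionnaire_items <- function(form = c("long", "short")) {
  form <- match.arg(form)
  if (form == "long") 1:10 else c(1L, 2L, 5L, 8L, 9L)
}

reverse_items <- function() c(2L, 3L, 6L, 8L)

#' Draw the number of sessions a participant completes
#'
#' Four compulsory sessions, then up to six optional days; each optional day
#' is attempted with probability `1 - hazard` given the previous day was
#' attempted (memoryless given the hazard). `hazard` may be a vector over
#' optional days.
#'
#' @param n number of participants.
#' @param hazard per-optional-day dropout probability (scalar or length-6).
#' @param compulsory,maximum session design constants.
#' @return integer vector of completed-session counts in
#'   `[compulsory, maximum]`.
#' @export
simulate_sessions_completed <- function(n, hazard, compulsory = 4L,
                                        maximum = 10L) {
  n_opt <- maximum - compulsory
  h <- rep_len(hazard, n_opt)
  vapply(seq_len(n), function(i) {
    s <- compulsory
    for (d in seq_len(n_opt)) {
      if (runif(1) < h[d]) break
      s <- s + 1L
    }
    as.integer(s)
  }, integer(1))
}

#' Simulate one participant's study trajectory
#'
#' Always runs the four compulsory sessions (optionally with a calendar gap
#' injected to exercise conformance classification), then draws optional
#' sessions from day 5 under the participant's dropout hazard. Each
#' completed session carries a full trial log, a questionnaire vector and a
#' loss-of-focus count.
#'
#' @param profile a `participant_profile`.
#' @param config a [task_config()].
#' @param seed integer seed.
#' @param compulsory,maximum session design constants (4 and 10).
#' @param p_noncompliance probability that the participant's compulsory
#'   block contains a 1- or 2-day calendar gap.
#' @return list with `trials` (all sessions row-bound) and `sessions`
#'   (one row per session in the session-log schema).
#' @export
simulate_participant <- function(profile, config = task_config(), seed = NULL,
                                 compulsory = 4L, maximum = 10L,
                                 p_noncompliance = 0) {
  n_done <- with_seed(substream_seed(seed %||% 0L, "attrition"),
                      simulate_sessions_completed(1, profile$dropout_hazard,
                                                  compulsory, maximum))
  days <- seq_len(n_done)
  if (p_noncompliance > 0) {
    days <- with_seed(substream_seed(seed %||% 0L, "calendar"), {
      if (runif(1) < p_noncompliance && n_done >= 2) {
        at <- sample(2:min(compulsory, n_done), 1)
        gap <- sample(1:2, 1)
        days[at:length(days)] <- days[at:length(days)] + gap
      }
      days
    })
  }
  trials <- vector("list", n_done)
  sessions <- vector("list", n_done)
  hs <- 0
  for (s in seq_len(n_done)) {
    sess <- simulate_session(profile, s, config, seed = seed, high_score = hs)
    if (!is.na(sess$high_score)) hs <- sess$high_score
    trials[[s]] <- sess$trials
    sessions[[s]] <- data.frame(
      participant_id = profile$id, variant = profile$variant,
      session_number = s, calendar_day = days[s], completed = TRUE,
      loss_of_focus_count = sess$loss_of_focus,
      total_score = sess$total_score,
      t(sess$questionnaire), stringsAsFactors = FALSE
    )
  }
  list(trials = do.call(rbind, trials), sessions = do.call(rbind, sessions))
}

#' Cohort configuration
#'
#' Study-level simulation settings. Defaults encode the study design (three
#' variants, 97 participants each for a total of 291; 4 compulsory + 6
#' optional sessions) with per-variant dropout hazards and questionnaire
#' levels; stopping-latency and go-RT population parameters are shared
#' across variants unless overridden.
#'
#' @param n_per_variant participants per variant.
#' @param variants variant labels.
#' @param hazard named per-variant per-optional-day dropout hazard.
#' @param stop_mean named per-variant mean of the true stopping latency (ms).
#' @param stop_between_sd between-participant SD of stopping latency (ms).
#' @param stop_sd trial-to-trial stopping-latency SD (ms).
#' @param go_mu,go_sigma,go_tau population ex-Gaussian go-RT parameters (ms).
#' @param go_mu_between_sd between-participant SD of the Gaussian mean (ms).
#' @param q_mean_s1,q_mean_s4 named per-variant questionnaire levels (0-100).
#' @param q_sd item-level questionnaire SD.
#' @param lapse_prob,choice_error_prob go-trial omission and wrong-key rates.
#' @param focus_rate expected loss-of-focus events per session.
#' @param p_noncompliance probability of a calendar gap in the compulsory
#'   block (0 disables non-conformance injection).
#' @param compulsory_sessions,max_sessions session design constants.
#' @param seed root integer seed.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_variant = 97L,
                          variants = c("nongame", "points", "theme"),
                          hazard = c(nongame = 0.16, points = 0.152,
                                     theme = 0.115),
                          stop_mean = c(nongame = 270, points = 270,
                                        theme = 270),
                          stop_between_sd = 40,
                          stop_sd = 20,
                          go_mu = 380, go_sigma = 50, go_tau = 120,
                          go_mu_between_sd = 40,
                          q_mean_s1 = c(nongame = 56, points = 58, theme = 53),
                          q_mean_s4 = c(nongame = 50, points = 52, theme = 51),
                          q_sd = 20,
                          lapse_prob = 0.02, choice_error_prob = 0.02,
                          focus_rate = 0.95,
                          p_noncompliance = 0,
                          compulsory_sessions = 4L, max_sessions = 10L,
                          seed = 1L) {
  stopifnot(n_per_variant >= 1, length(variants) >= 1,
            compulsory_sessions >= 1, max_sessions >= compulsory_sessions)
  structure(as.list(environment()), class = "cohort_config")
}

per_variant <- function(x, v) {
  if (!is.null(names(x)) && v %in% names(x)) x[[v]] else x[[1]]
}

#' Generate a full synthetic cohort
#'
#' Draws participant profiles per variant, simulates every participant's
#' trajectory, and returns the trial log, session log and a ground-truth
#' table holding every generated quantity the pipeline later estimates
#' (true SSRT, hazard, questionnaire means, focus rate).
#'
#' @param config a [cohort_config()].
#' @param task a [task_config()].
#' @return a list of class `sst_cohort` with elements `trials`, `sessions`,
#'   `truth`, `config`, `task`.
#' @examples
#' \donttest{
#' co <- generate_cohort(cohort_config(n_per_variant = 2, seed = 7))
#' table(co$truth$variant)
#' }
#' @export
generate_cohort <- function(config = cohort_config(), task = task_config()) {
  stopifnot(inherits(config, "cohort_config"))
  profiles <- list(); truth <- list()
  pid <- 0L
  for (v in config$variants) {
    pars <- with_seed(substream_seed(config$seed, paste0("profiles_", v)), {
      n <- config$n_per_variant
      list(stop_mean = pmax(120, rnorm(n, per_variant(config$stop_mean, v),
                                       config$stop_between_sd)),
           go_mu = pmax(200, rnorm(n, config$go_mu, config$go_mu_between_sd)))
    })
    for (i in seq_len(config$n_per_variant)) {
      pid <- pid + 1L
      id <- sprintf("P%03d", pid)
      profiles[[pid]] <- participant_profile(
        id = id, variant = v,
        go_mu = pars$go_mu[i], go_sigma = config$go_sigma,
        go_tau = config$go_tau,
        stop_mean = pars$stop_mean[i], stop_sd = config$stop_sd,
        lapse_prob = config$lapse_prob,
        choice_error_prob = config$choice_error_prob,
        dropout_hazard = per_variant(config$hazard, v),
        q_mean_s1 = per_variant(config$q_mean_s1, v),
        q_mean_s4 = per_variant(config$q_mean_s4, v),
        q_sd = config$q_sd, focus_rate = config$focus_rate)
      truth[[pid]] <- data.frame(
        participant_id = id, variant = v,
        true_ssrt_ms = pars$stop_mean[i], go_mu_ms = pars$go_mu[i],
        go_sigma_ms = config$go_sigma, go_tau_ms = config$go_tau,
        dropout_hazard = mean(per_variant(config$hazard, v)),
        q_mean_s1 = per_variant(config$q_mean_s1, v),
        q_mean_s4 = per_variant(config$q_mean_s4, v),
        focus_rate = config$focus_rate, stringsAsFactors = FALSE)
    }
  }
  sims <- lapply(seq_along(profiles), function(i) {
    simulate_participant(profiles[[i]], task,
                         seed = substream_seed(config$seed, "participant", i),
                         compulsory = config$compulsory_sessions,
                         maximum = config$max_sessions,
                         p_noncompliance = config$p_noncompliance)
  })
  structure(list(
    trials = do.call(rbind, lapply(sims, `[[`, "trials")),
    sessions = do.call(rbind, lapply(sims, `[[`, "sessions")),
    truth = do.call(rbind, truth),
    config = config, task = task
  ), class = "sst_cohort")
}

#' Write / read a cohort as CSV
#'
#' Writes `trials.csv`, `sessions.csv` and `truth.csv` (comma-separated,
#' UTF-8, header row, empty field = missing) into `dir`;
#' `read_cohort()` reads them back.
#'
#' @param cohort an `sst_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` an
#'   `sst_cohort` (without config elements).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sst_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$trials, file.path(dir, "trials.csv"),
            row.names = FALSE, na = "")
  write.csv(cohort$sessions, file.path(dir, "sessions.csv"),
            row.names = FALSE, na = "")
  write.csv(cohort$truth, file.path(dir, "truth.csv"),
            row.names = FALSE, na = "")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  pth <- function(f) file.path(dir, f)
  for (f in c("trials.csv", "sessions.csv"))
    if (!file.exists(pth(f))) stop("missing ", f, " in ", dir)
  truth <- if (file.exists(pth("truth.csv"))) read.csv(pth("truth.csv")) else NULL
  structure(list(trials = read.csv(pth("trials.csv")),
                 sessions = read.csv(pth("sessions.csv")),
                 truth = truth, config = NULL, task = task_config()),
            class = "sst_cohort")
}
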