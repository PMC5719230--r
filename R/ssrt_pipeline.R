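# Per-session SSRT estimation: anticipatory-response filtering, race-model
# consistency checks, inhibition-function fitting, and participant-level
# aggregation with outlier exclusion.

#' Remove anticipatory responses
#'
#' Drops response trials with RT below `min_rt_ms` (strictly less than);
#' non-response trials (omissions, successful inhibitions) are retained.
#'
#' @param trials trial-log data frame (columns `rt_ms`, `outcome`, ...).
#' @param min_rt_ms threshold in ms (default 150).
#' @return the filtered data frame.
#' @export
filter_trials <- function(trials, min_rt_ms = 150) {
  if (nrow(trials) == 0L) return(trials)
  keep <- is.na(trials$rt_ms) | trials$rt_ms >= min_rt_ms
  trials[keep, , drop = FALSE]
}

stop_response_outcomes <- function(presignal_as_response = TRUE) {
  if (presignal_as_response) c("stop_respond", "stop_presignal")
  else "stop_respond"
}

#' Check the race-model assumptions for one session
#'
#' Three checks, applied in order, with the first failure recorded as the
#' exclusion reason:
#'
#' 1. `race_rt_order` — under the race model, failed-stop responses are the
#'    fast tail of the go distribution, so the median failed-stop RT must be
#'    strictly below the median no-stop (go) RT. With
#'    `verbatim_rt_rule = TRUE` the direction is inverted (sessions are
#'    excluded when the go median exceeds the failed-stop median), matching
#'    a literal reading of the published exclusion sentence; the default
#'    follows the standard race-model prediction.
#' 2. `ssd_rt_corr` — per-SSD median failed-stop RTs must be positively
#'    rank-correlated with SSD (Spearman rho > 0).
#' 3. `ssd_acc_corr` — per-SSD inhibition rate ("stop-trial accuracy") must
#'    be negatively rank-correlated with SSD (Spearman rho < 0).
#'
#' @param trials one session's (already filtered) trial log.
#' @param min_stop_responses minimum stop-trial responses required.
#' @param min_ssd_bins minimum distinct SSD values required.
#' @param presignal_as_response count pre-signal responses as stop-trial
#'   responses (the go process won the race)?
#' @param verbatim_rt_rule see above.
#' @return list with `valid` (logical) and `reason` (`"none"`,
#'   `"race_rt_order"`, `"ssd_rt_corr"`, `"ssd_acc_corr"` or
#'   `"insufficient_data"`).
#' @export
check_race_model <- function(trials, min_stop_responses = 10,
                             min_ssd_bins = 3,
                             presignal_as_response = TRUE,
                             verbatim_rt_rule = FALSE) {
  res <- function(valid, reason) list(valid = valid, reason = reason)
  go <- trials[trials$trial_type == "go" & !is.na(trials$rt_ms), , drop = FALSE]
  stopt <- trials[trials$trial_type == "stop", , drop = FALSE]
  resp_out <- stop_response_outcomes(presignal_as_response)
  fails <- stopt[stopt$outcome %in% resp_out & !is.na(stopt$rt_ms), ,
                 drop = FALSE]
  if (nrow(go) < 2 || nrow(fails) < min_stop_responses ||
      length(unique(stopt$ssd_ms)) < min_ssd_bins ||
      length(unique(fails$ssd_ms)) < min_ssd_bins)
    return(res(FALSE, "insufficient_data"))
  med_go <- median(go$rt_ms)
  med_fail <- median(fails$rt_ms)
  bad_order <- if (verbatim_rt_rule) med_go > med_fail else med_fail >= med_go
  if (bad_order) return(res(FALSE, "race_rt_order"))
  med_by_ssd <- tapply(fails$rt_ms, fails$ssd_ms, median)
  ssd_rt <- as.numeric(names(med_by_ssd))
  rho_rt <- suppressWarnings(cor(ssd_rt, as.numeric(med_by_ssd),
                                 method = "spearman"))
  if (is.na(rho_rt) || rho_rt <= 0) return(res(FALSE, "ssd_rt_corr"))
  inh <- tapply(stopt$outcome == "stop_inhibit", stopt$ssd_ms, mean)
  ssd_acc <- as.numeric(names(inh))
  rho_acc <- suppressWarnings(cor(ssd_acc, as.numeric(inh),
                                  method = "spearman"))
  if (is.na(rho_acc) || rho_acc >= 0) return(res(FALSE, "ssd_acc_corr"))
  res(TRUE, "none")
}

#' Fit the inhibition function
#'
#' Maximum-likelihood logistic fit of P(respond) against SSD over a
#' session's stop trials; `ssd50_ms` is the SSD at which the fitted
#' response probability is 50%. Under complete separation (every response
#' SSD above every inhibition SSD) the logistic MLE diverges, so the fit is
#' flagged `converged = FALSE` and `ssd50_ms` falls back to the midpoint
#' between the highest all-inhibit SSD and the lowest all-respond SSD.
#'
#' @param stop_trials stop-trial rows of a session log.
#' @param presignal_as_response count pre-signal responses as responses?
#' @return list of class `inhibition_fit` with `slope` (per ms),
#'   `intercept`, `ssd50_ms`, `n_stop_trials`, `converged`.
#' @export
fit_inhibition_function <- function(stop_trials,
                                    presignal_as_response = TRUE) {
  stopt <- stop_trials[stop_trials$trial_type == "stop", , drop = FALSE]
  if (nrow(stopt) == 0L) stop("no stop trials supplied")
  respond <- stopt$outcome %in% stop_response_outcomes(presignal_as_response)
  ssd <- stopt$ssd_ms
  if (length(unique(ssd)) < 3)
    stop("need at least 3 distinct SSDs to fit an inhibition function")
  if (all(respond) || all(!respond))
    stop("both responded and inhibited stop trials are required")
  out <- list(slope = NA_real_, intercept = NA_real_, ssd50_ms = NA_real_,
              n_stop_trials = nrow(stopt), converged = FALSE)
  class(out) <- "inhibition_fit"
  if (min(ssd[respond]) > max(ssd[!respond])) { # complete separation
    p_resp <- tapply(respond, ssd, mean)
    lv <- as.numeric(names(p_resp))
    out$ssd50_ms <- (max(lv[p_resp == 0]) + min(lv[p_resp == 1])) / 2
    return(out)
  }
  fit <- suppressWarnings(glm(respond ~ ssd, family = binomial()))
  b <- coef(fit)
  if (!fit$converged || !all(is.finite(b)) || b[2] <= 0) return(out)
  out$slope <- unname(b[2]); out$intercept <- unname(b[1])
  out$ssd50_ms <- unname(-b[1] / b[2])
  out$converged <- TRUE
  out
}

#' Coefficient of variation of go RTs
#'
#' 100 x sample SD (n-1 denominator) of no-stop-trial response RTs divided
#' by their mean — a proxy for fluctuating engagement.
#'
#' @param trials one session's (filtered) trial log.
#' @return CV in percent, or `NA` (with a warning) when fewer than 2 go
#'   responses are available.
#' @export
session_cv <- function(trials) {
  rts <- trials$rt_ms[trials$trial_type == "go" & !is.na(trials$rt_ms)]
  if (length(rts) < 2) {
    warning("fewer than 2 go-response RTs; CV undefined")
    return(NA_real_)
  }
  100 * sd(rts) / mean(rts)
}

#' Summarize one session (SSRT, CV, validity)
#'
#' Applies the anticipatory-response filter, the race-model checks and the
#' inhibition-function fit, and derives the session's SSRT as
#' `median go RT - SSD50`. Invalid sessions keep their descriptive columns
#' but carry no SSRT.
#'
#' @param trials one session's raw trial log.
#' @param min_rt_ms anticipatory-response threshold (ms).
#' @param min_stop_responses,presignal_as_response,verbatim_rt_rule passed
#'   to [check_race_model()] / [fit_inhibition_function()].
#' @return one-row data frame: `participant_id`, `session_number`, `valid`,
#'   `exclusion_reason`, `median_go_rt_ms`, `ssd50_ms`, `ssrt_ms`,
#'   `cv_percent`, `go_accuracy`, `score`.
#' @export
summarize_session <- function(trials, min_rt_ms = 150,
                              min_stop_responses = 10,
                              presignal_as_response = TRUE,
                              verbatim_rt_rule = FALSE) {
  pid <- trials$participant_id[1]
  snum <- trials$session_number[1]
  ft <- filter_trials(trials, min_rt_ms)
  go <- ft[ft$trial_type == "go", , drop = FALSE]
  go_rts <- go$rt_ms[!is.na(go$rt_ms)]
  med_go <- if (length(go_rts)) median(go_rts) else NA_real_
  acc <- if (nrow(go)) mean(go$outcome == "go_success") else NA_real_
  cv <- if (length(go_rts) >= 2) 100 * sd(go_rts) / mean(go_rts) else NA_real_
  score <- if (all(is.na(trials$points))) NA_real_ else
    sum(trials$points, na.rm = TRUE)
  chk <- check_race_model(ft, min_stop_responses = min_stop_responses,
                          presignal_as_response = presignal_as_response,
                          verbatim_rt_rule = verbatim_rt_rule)
  ssd50 <- NA_real_; ssrt <- NA_real_
  valid <- chk$valid; reason <- chk$reason
  if (valid) {
    fit <- fit_inhibition_function(ft[ft$trial_type == "stop", , drop = FALSE],
                                   presignal_as_response)
    ssd50 <- fit$ssd50_ms
    if (is.na(ssd50)) {
      valid <- FALSE; reason <- "insufficient_data"
    } else {
      ssrt <- med_go - ssd50
    }
  }
  data.frame(participant_id = pid, session_number = snum,
             valid = valid, exclusion_reason = reason,
             median_go_rt_ms = med_go, ssd50_ms = ssd50, ssrt_ms = ssrt,
             cv_percent = cv, go_accuracy = acc, score = score,
             stringsAsFactors = FALSE)
}

#' Summarize every completed session of a cohort
#'
#' @param trials trial log covering multiple participants/sessions.
#' @param sessions optional session log; when supplied, sessions with
#'   `completed == FALSE` (started but not finished) are dropped before
#'   estimation.
#' @param ... passed to [summarize_session()].
#' @return data frame with one row per summarized session.
#' @export
summarize_sessions <- function(trials, sessions = NULL, ...) {
  if (!is.null(sessions)) {
    done <- sessions[sessions$completed, c("participant_id", "session_number")]
    key <- paste(trials$participant_id, trials$session_number)
    trials <- trials[key %in% paste(done$participant_id, done$session_number), ,
                     drop = FALSE]
  }
  parts <- split(trials, list(trials$participant_id, trials$session_number),
                 drop = TRUE)
  out <- do.call(rbind, lapply(parts, summarize_session, ...))
  out <- out[order(out$participant_id, out$session_number), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate session summaries to participant level
#'
#' Means over the first `k` sessions: SSRT over valid sessions only (a
#' participant whose first `k` sessions are all invalid is flagged
#' `ssrt_excluded` and carries no SSRT), CV, median go RT and go accuracy
#' over all summarized sessions among the first `k`.
#'
#' @param summaries output of [summarize_sessions()].
#' @param k number of leading sessions to aggregate (default 4, the
#'   compulsory block).
#' @return data frame with one row per participant.
#' @export
aggregate_participants <- function(summaries, k = 4) {
  parts <- split(summaries, summaries$participant_id)
  out <- lapply(parts, function(df) {
    df <- df[df$session_number <= k, , drop = FALSE]
    ok <- df$valid & !is.na(df$ssrt_ms)
    data.frame(
      participant_id = df$participant_id[1],
      n_sessions = nrow(df),
      n_valid = sum(ok),
      ssrt_excluded = !any(ok),
      mean_ssrt_ms = if (any(ok)) mean(df$ssrt_ms[ok]) else NA_real_,
      mean_cv_percent = mean(df$cv_percent, na.rm = TRUE),
      mean_go_rt_ms = mean(df$median_go_rt_ms, na.rm = TRUE),
      mean_accuracy = mean(df$go_accuracy, na.rm = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Exclude outlier participants
#'
#' Removes participants whose value on any screening column lies more than
#' `k_iqr` interquartile ranges from that column's median, computed over the
#' full supplied sample. A degenerate column (IQR = 0) keeps only
#' exact-median values and emits a warning.
#'
#' @param participants participant-level data frame.
#' @param cols columns to screen (default mean RT and accuracy).
#' @param k_iqr exclusion multiplier (default 4).
#' @return the filtered data frame, with excluded ids in
#'   `attr(, "excluded")`.
#' @export
exclude_outlier_participants <- function(participants,
                                         cols = c("mean_go_rt_ms",
                                                  "mean_accuracy"),
                                         k_iqr = 4) {
  keep <- rep(TRUE, nrow(participants))
  for (cl in cols) {
    x <- participants[[cl]]
    med <- median(x, na.rm = TRUE)
    iqr <- quantile(x, 0.75, na.rm = TRUE, names = FALSE) -
      quantile(x, 0.25, na.rm = TRUE, names = FALSE)
    if (isTRUE(iqr == 0)) {
      warning("IQR of ", cl, " is 0; retaining exact-median values only")
      keep <- keep & (is.na(x) | x == med)
    } else {
      keep <- keep & (is.na(x) | abs(x - med) <= k_iqr * iqr)
    }
  }
  out <- participants[keep, , drop = FALSE]
  attr(out, "excluded") <- participants$participant_id[!keep]
  out
}
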