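# Subjective engagement scoring, conformance classification and attrition
# tabulation.

#' Score an enjoyment/engagement questionnaire response
#'
#' Visual-analog item scores (0-100) are averaged after reverse-scoring the
#' negatively phrased items (2, 3, 6 and 8). The long form (sessions 1, 4,
#' 7, 10) carries all ten items; the short form carries items 1, 2, 5, 8
#' and 9 only.
#'
#' @param scores named numeric vector (`q1` ... `q10`); items outside the
#'   form are ignored.
#' @param form `"long"` or `"short"`.
#' @return mean score on the 0-100 scale, or `NA` when any of the form's
#'   items is missing (the response is excluded).
#' @export
score_questionnaire <- function(scores, form = c("long", "short")) {
  form <- match.arg(form)
  items <- questionnaire_items(form)
  nm <- paste0("q", items)
  x <- unname(scores[nm])
  if (anyNA(x) || length(x) < length(items)) {
    warning("missing item(s); questionnaire response excluded")
    return(NA_real_)
  }
  if (any(x < 0 | x > 100)) stop("item scores must lie in [0, 100]")
  rev <- items %in% reverse_items()
  x[rev] <- 100 - x[rev]
  mean(x)
}

#' Combined subjective engagement score
#'
#' Arithmetic mean of the session-1 and session-4 questionnaire scores; if
#' either is missing the participant is dropped from the combined analysis
#' (`NA` returned).
#'
#' @param score_s1,score_s4 session-level mean scores.
#' @return the mean, or `NA`.
#' @export
combined_score <- function(score_s1, score_s4) {
  ifelse(is.na(score_s1) | is.na(score_s4), NA_real_,
         (score_s1 + score_s4) / 2)
}

#' Classify compulsory-block conformance
#'
#' `conforming`: the first four completed sessions fall on four consecutive
#' calendar days (days 1-4 of participation). `loose`: four sessions
#' completed within a five-day window from the first day. `non`: anything
#' else, including fewer than four completed sessions.
#'
#' @param session_days calendar days of the participant's completed
#'   sessions.
#' @return one of `"conforming"`, `"loose"`, `"non"`.
#' @export
classify_conformance <- function(session_days) {
  d <- sort(unique(session_days))
  if (length(d) < 4) return("non")
  d4 <- d[1:4]
  if (all(d4 == d4[1] + 0:3)) return("conforming")
  if (d4[4] - d4[1] <= 4) return("loose")
  "non"
}

#' Build per-participant attrition records
#'
#' @param sessions session log (columns `participant_id`, `variant`,
#'   `session_number`, `calendar_day`, `completed`).
#' @return data frame: `participant_id`, `variant`, `sessions_completed`
#'   (started-but-not-finished sessions excluded), `conformance`.
#' @export
attrition_records <- function(sessions) {
  done <- sessions[sessions$completed, , drop = FALSE]
  parts <- split(done, done$participant_id)
  out <- lapply(parts, function(df) {
    data.frame(participant_id = df$participant_id[1],
               variant = df$variant[1],
               sessions_completed = nrow(df),
               conformance = classify_conformance(df$calendar_day),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-variant attrition summary
#'
#' Mean sessions completed per participant with a t-based 95% CI, and the
#' percentage of participants completing at least k sessions for
#' k = 1..`max_sessions`.
#'
#' @param records output of [attrition_records()] (or any data frame with
#'   `variant` and `sessions_completed`).
#' @param max_sessions design maximum (default 10).
#' @return list with `means` (per-variant mean, CI, n) and `survival`
#'   (per-variant percentage surviving to each k).
#' @export
attrition_summary <- function(records, max_sessions = 10) {
  vs <- unique(records$variant)
  means <- list(); surv <- list()
  for (v in vs) {
    x <- records$sessions_completed[records$variant == v]
    if (length(x) == 0L) {
      warning("variant ", v, " has no participants; omitted")
      next
    }
    n <- length(x); m <- mean(x)
    half <- if (n > 1) qt(0.975, n - 1) * sd(x) / sqrt(n) else NA_real_
    means[[v]] <- data.frame(variant = v, n = n, mean_sessions = m,
                             ci_lo = m - half, ci_hi = m + half,
                             stringsAsFactors = FALSE)
    surv[[v]] <- data.frame(
      variant = v, k = seq_len(max_sessions),
      pct_at_least_k = 100 * vapply(seq_len(max_sessions),
                                    function(k) mean(x >= k), numeric(1)),
      stringsAsFactors = FALSE)
  }
  means <- do.call(rbind, means); surv <- do.call(rbind, surv)
  rownames(means) <- NULL; rownames(surv) <- NULL
  list(means = means, survival = surv)
}
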