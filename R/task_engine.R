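# Task engine: the rules any simulated or replayed SST session must obey.
# Trial scheduling, round-robin four-staircase SSD tracking, and the
# points-variant scoring state machine.

#' Default task configuration
#'
#' Structural constants of the task: five blocks of 48 trials with stop
#' signals on 25% of trials, four 1-up/1-down SSD staircases starting at
#' 50/150/250/350 ms with a 50 ms step clipped to \[0, 800\] ms, a 900 ms
#' stimulus display window, and the points-variant scoring constants
#' (points = 0.2 x bonus x (800 - RT); bonus +1 every 3 scored go
#' responses, -3 on a failed stop, floored at 1).
#'
#' Fixation (500 ms) and the 500–1000 ms intertrial interval are carried as
#' metadata only; no real-time behaviour is simulated.
#'
#' @param n_blocks number of blocks per session.
#' @param trials_per_block trials per block.
#' @param stop_fraction proportion of stop trials per block.
#' @param staircase_start_ms initial SSDs of the four staircases (ms).
#' @param staircase_step_ms staircase step size (ms).
#' @param staircase_bounds_ms two-element SSD bounds (ms).
#' @param display_ms stimulus display window (ms); responses later than this
#'   are omissions.
#' @param scoring list of scoring constants: `rate`, `rt_ceiling_ms`,
#'   `bonus_every`, `bonus_penalty`, `bonus_floor`, `bonus_start`.
#' @return a list of class `task_config`.
#' @export
task_config <- function(n_blocks = 5L,
                        trials_per_block = 48L,
                        stop_fraction = 0.25,
                        staircase_start_ms = c(50, 150, 250, 350),
                        staircase_step_ms = 50,
                        staircase_bounds_ms = c(0, 800),
                        display_ms = 900,
                        scoring = list(rate = 0.2, rt_ceiling_ms = 800,
                                       bonus_every = 3L, bonus_penalty = 3L,
                                       bonus_floor = 1L, bonus_start = 1L)) {
  stopifnot(n_blocks >= 1, trials_per_block >= 1,
            stop_fraction >= 0, stop_fraction <= 1,
            length(staircase_start_ms) == 4L,
            length(staircase_bounds_ms) == 2L,
            staircase_bounds_ms[1] < staircase_bounds_ms[2])
  structure(list(n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 stop_fraction = stop_fraction,
                 staircase_start_ms = staircase_start_ms,
                 staircase_step_ms = staircase_step_ms,
                 staircase_bounds_ms = staircase_bounds_ms,
                 display_ms = display_ms,
                 fixation_ms = 500,
                 iti_range_ms = c(500, 1000),
                 scoring = scoring),
            class = "task_config")
}

#' Generate a trial schedule
#'
#' Lays out `n_blocks` blocks of `trials_per_block` trials with an exact
#' per-block stop count of `round(stop_fraction * trials_per_block)`; stop
#' positions are uniformly shuffled within each block. The same seed always
#' yields the same schedule.
#'
#' @param n_blocks number of blocks.
#' @param trials_per_block trials per block.
#' @param stop_fraction proportion of stop trials.
#' @param seed integer seed.
#' @return a data frame of class `trial_schedule` with columns `block`,
#'   `trial_index` (1-based, global) and `trial_type` (`"go"`/`"stop"`).
#' @examples
#' sched <- generate_schedule(5, 48, 0.25, seed = 1)
#' table(sched$trial_type) # 180 go, 60 stop
#' @export
generate_schedule <- function(n_blocks, trials_per_block, stop_fraction,
                              seed = NULL) {
  stopifnot(n_blocks >= 1, trials_per_block >= 1)
  if (!is.numeric(stop_fraction) || stop_fraction < 0 || stop_fraction > 1)
    stop("stop_fraction must lie in [0, 1]")
  n_stop <- as.integer(round(stop_fraction * trials_per_block))
  with_seed(seed, {
    types <- unlist(lapply(seq_len(n_blocks), function(b) {
      v <- rep("go", trials_per_block)
      v[sample.int(trials_per_block, n_stop)] <- "stop"
      v
    }))
    out <- data.frame(
      block = rep(seq_len(n_blocks), each = trials_per_block),
      trial_index = seq_len(n_blocks * trials_per_block),
      trial_type = types,
      stringsAsFactors = FALSE
    )
    attr(out, "stop_per_block") <- n_stop
    class(out) <- c("trial_schedule", "data.frame")
    out
  })
}

#' Create a staircase bank
#'
#' Four independent 1-up/1-down staircases tracking the SSD, assigned to
#' stop trials round-robin. Starting the staircases at spread-out SSDs
#' samples the inhibition-probability-by-SSD space on both sides of the
#' participant's 50% point.
#'
#' @param ssd_ms initial SSDs, one per staircase (ms).
#' @param step_ms step size (ms).
#' @param bounds_ms two-element vector of SSD bounds (ms).
#' @return a list of class `staircase_bank`.
#' @export
new_staircase_bank <- function(ssd_ms = c(50, 150, 250, 350),
                               step_ms = 50, bounds_ms = c(0, 800)) {
  stopifnot(length(ssd_ms) == 4L, step_ms > 0, length(bounds_ms) == 2L,
            all(ssd_ms >= bounds_ms[1]), all(ssd_ms <= bounds_ms[2]))
  structure(list(ssd_ms = as.numeric(ssd_ms), step_ms = step_ms,
                 bounds_ms = as.numeric(bounds_ms), next_index = 1L),
            class = "staircase_bank")
}

#' Draw the next stop-signal delay
#'
#' Returns the SSD of the staircase at the round-robin pointer and advances
#' the pointer (1 -> 2 -> 3 -> 4 -> 1).
#'
#' @param bank a `staircase_bank`.
#' @return list with `ssd_ms`, `staircase_id`, and the updated `bank`.
#' @export
next_stop_ssd <- function(bank) {
  stopifnot(inherits(bank, "staircase_bank"))
  id <- bank$next_index
  bank$next_index <- if (id == 4L) 1L else id + 1L
  list(ssd_ms = bank$ssd_ms[id], staircase_id = id, bank = bank)
}

#' Update one staircase after a stop trial
#'
#' 1-up/1-down rule: a successful inhibition makes the next stop harder
#' (SSD + step); a response makes it easier (SSD - step). The result is
#' clipped to the bank's bounds; the other staircases are untouched.
#'
#' @param bank a `staircase_bank`.
#' @param staircase_id which staircase (1..4).
#' @param inhibited logical; did the participant withhold the response?
#' @return the updated `staircase_bank`.
#' @export
update_staircase <- function(bank, staircase_id, inhibited) {
  stopifnot(inherits(bank, "staircase_bank"))
  if (!staircase_id %in% 1:4) stop("staircase_id must be in 1..4")
  d <- if (isTRUE(inhibited)) bank$step_ms else -bank$step_ms
  x <- bank$ssd_ms[staircase_id] + d
  bank$ssd_ms[staircase_id] <- min(max(x, bank$bounds_ms[1]), bank$bounds_ms[2])
  bank
}

#' Create a scoring state
#'
#' Points-variant scoring state: the bonus multiplier starts at 1 at the
#' start of each session, the running total starts at 0, and the high score
#' persists across sessions.
#'
#' @param config a `task_config` (its `scoring` element is used).
#' @param high_score best total from previous sessions.
#' @return a list of class `scoring_state`.
#' @export
new_scoring_state <- function(config = task_config(), high_score = 0) {
  sc <- config$scoring
  structure(list(bonus = as.integer(sc$bonus_start),
                 trials_since_increment = 0L,
                 total_score = 0,
                 high_score = high_score,
                 constants = sc),
            class = "scoring_state")
}

#' Apply the scoring rule for one trial
#'
#' On a successful go response (and on a stop trial answered before the
#' signal appeared, which to the participant is indistinguishable from a go
#' trial) the trial earns `0.2 x bonus x (800 - RT)` points, floored at 0
#' for RTs above 800 ms, and counts toward the bonus increment (+1 every 3
#' scored responses). A failed stop trial earns nothing and costs 3 bonus
#' levels (floored at 1); a successful inhibition earns nothing but keeps
#' the bonus. Go errors and omissions earn nothing and leave the counter
#' unchanged. Points are kept at full precision internally;
#' `round_half_up()` is applied only for display.
#'
#' @param state a `scoring_state`.
#' @param outcome one of `go_success`, `go_error`, `go_omission`,
#'   `stop_inhibit`, `stop_respond`, `stop_presignal`.
#' @param rt_ms response latency (ms); required for response outcomes.
#' @return list with the updated `state` and the `points` awarded.
#' @examples
#' st <- new_scoring_state()
#' st$bonus <- 2L
#' apply_scoring(st, "go_success", 400)$points # 160
#' @export
apply_scoring <- function(state, outcome, rt_ms = NULL) {
  stopifnot(inherits(state, "scoring_state"))
  k <- state$constants
  outcome <- match.arg(outcome, c("go_success", "go_error", "go_omission",
                                  "stop_inhibit", "stop_respond",
                                  "stop_presignal"))
  needs_rt <- outcome %in% c("go_success", "go_error", "stop_respond",
                             "stop_presignal")
  if (needs_rt) {
    if (is.null(rt_ms) || is.na(rt_ms)) stop("rt_ms required for ", outcome)
    if (rt_ms < 0) stop("rt_ms must be non-negative")
  }
  points <- 0
  if (outcome %in% c("go_success", "stop_presignal")) {
    points <- k$rate * state$bonus * max(0, k$rt_ceiling_ms - rt_ms)
    state$trials_since_increment <- state$trials_since_increment + 1L
    if (state$trials_since_increment >= k$bonus_every) {
      state$bonus <- state$bonus + 1L
      state$trials_since_increment <- 0L
    }
  } else if (outcome == "stop_respond") {
    state$bonus <- max(k$bonus_floor, state$bonus - k$bonus_penalty)
  }
  # stop_inhibit, go_error, go_omission: no points, bonus untouched
  state$total_score <- state$total_score + points
  state$high_score <- max(state$high_score, state$total_score)
  list(state = state, points = points)
}
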