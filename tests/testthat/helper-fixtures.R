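# Hand-built trial logs for the estimation-stage tests.

# One trial-log row per element; defaults give a well-formed go response.
make_trials <- function(trial_type, outcome, rt_ms, ssd_ms = NA_real_,
                        points = NA_real_, participant_id = "T1",
                        session_number = 1L) {
  n <- max(length(trial_type), length(outcome), length(rt_ms),
           length(ssd_ms))
  outcome <- rep_len(outcome, n)
  data.frame(participant_id = participant_id, session_number = session_number,
             block = rep(1L, n), trial_index = seq_len(n),
             trial_type = rep_len(trial_type, n), ssd_ms = rep_len(ssd_ms, n),
             staircase_id = NA_integer_, outcome = outcome,
             rt_ms = rep_len(rt_ms, n), points = rep_len(points, n),
             bonus_after = NA_integer_, stringsAsFactors = FALSE)
}

# A session that satisfies every race-model check by construction:
# go median 520; failed-stop RTs faster and increasing with SSD;
# inhibition rate decreasing with SSD; respond proportions .25/.50/.75 at
# SSDs 100/200/300 (symmetric around 200 with balanced n).
make_valid_session <- function(participant_id = "T1") {
  go <- make_trials("go", "go_success", seq(450, 590, length.out = 101),
                    participant_id = participant_id)
  stops <- list()
  resp_n <- c(`100` = 5, `200` = 10, `300` = 15)
  fail_ctr <- c(`100` = 430, `200` = 460, `300` = 490)
  for (ssd in c(100, 200, 300)) {
    k <- resp_n[[as.character(ssd)]]
    rts <- fail_ctr[[as.character(ssd)]] + seq(-10, 10, length.out = k)
    stops[[length(stops) + 1L]] <-
      make_trials("stop", "stop_respond", rts, ssd_ms = ssd,
                  participant_id = participant_id)
    stops[[length(stops) + 1L]] <-
      make_trials("stop", rep("stop_inhibit", 20 - k), NA_real_,
                  ssd_ms = ssd, participant_id = participant_id)
  }
  out <- rbind(go, do.call(rbind, stops))
  out$trial_index <- seq_len(nrow(out))
  out
}

# Independent brute-force product-limit estimator (oracle for km_estimate).
product_limit_oracle <- function(times, censored = rep(FALSE, length(times))) {
  ev <- sort(unique(times[!censored]))
  surv <- numeric(length(ev))
  s <- 1
  for (i in seq_along(ev)) {
    at_risk <- sum(times >= ev[i])
    d <- sum(times == ev[i] & !censored)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = ev, survival = surv)
}

# Independent JZS oracle: BF10 as a fine-grid quadrature of the noncentral-t
# likelihood against the Cauchy effect-size prior (a different formulation
# from the package's g-mixture integral).
jzs_oracle <- function(t, n1, n2, r = 0.707) {
  N <- n1 * n2 / (n1 + n2)
  nu <- n1 + n2 - 2
  d <- seq(-30, 30, length.out = 40001)
  f <- suppressWarnings(dt(t, nu, ncp = d * sqrt(N))) * dcauchy(d, 0, r)
  num <- sum((f[-1] + f[-length(f)]) / 2) * (d[2] - d[1])
  num / dt(t, nu)
}
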