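test_that("anticipatory responses below 150 ms are removed (strict <)", {
  tr <- make_trials("go", "go_success", c(140, 150, 151))
  out <- filter_trials(tr)
  expect_equal(out$rt_ms, c(150, 151))
  # non-response trials are retained even with all responses anticipatory
  tr2 <- rbind(make_trials("go", "go_success", 100),
               make_trials("go", "go_omission", NA_real_),
               make_trials("stop", "stop_inhibit", NA_real_, ssd_ms = 200))
  out2 <- filter_trials(tr2)
  expect_equal(out2$outcome, c("go_omission", "stop_inhibit"))
  # identity when nothing is anticipatory; empty in, empty out
  expect_equal(nrow(filter_trials(tr[tr$rt_ms >= 150, ])), 2)
  expect_equal(nrow(filter_trials(tr[0, ])), 0)
})

test_that("race-model checks pass a well-formed session and order failures", {
  sess <- make_valid_session()
  chk <- check_race_model(sess)
  expect_true(chk$valid)
  expect_identical(chk$reason, "none")

  # failed-stop RTs slower than go RTs violate the race prediction
  slow <- sess
  resp <- slow$outcome == "stop_respond"
  slow$rt_ms[resp] <- slow$rt_ms[resp] + 300
  chk <- check_race_model(slow)
  expect_false(chk$valid)
  expect_identical(chk$reason, "race_rt_order")
  # ... but the verbatim reading of the exclusion sentence keeps them
  expect_true(check_race_model(slow, verbatim_rt_rule = TRUE)$valid)

  # failed-stop RTs decreasing with SSD fail the RT correlation
  anti <- sess
  resp <- anti$outcome == "stop_respond"
  anti$rt_ms[resp] <- 460 - (anti$ssd_ms[resp] - 200) * 0.15 +
    seq(-5, 5, length.out = sum(resp))
  chk <- check_race_model(anti)
  expect_false(chk$valid)
  expect_identical(chk$reason, "ssd_rt_corr")

  # one SSD only: correlations undefined
  one <- rbind(make_trials("go", "go_success", seq(450, 590, length.out = 50)),
               make_trials("stop", "stop_respond",
                           seq(420, 460, length.out = 20), ssd_ms = 200))
  chk <- check_race_model(one)
  expect_false(chk$valid)
  expect_identical(chk$reason, "insufficient_data")
})

test_that("inhibition-function fit recovers a symmetric SSD50 exactly", {
  sess <- make_valid_session()
  fit <- fit_inhibition_function(sess[sess$trial_type == "stop", ])
  expect_true(fit$converged)
  expect_equal(fit$ssd50_ms, 200, tolerance = 1e-6)
  expect_gt(fit$slope, 0)
})

test_that("inhibition-function fit recovers simulated logistic parameters", {
  set.seed(31)
  ssd <- sample(seq(50, 450, by = 50), 2000, replace = TRUE)
  p <- plogis(0.02 * (ssd - 240))
  out <- ifelse(runif(2000) < p, "stop_respond", "stop_inhibit")
  tr <- make_trials("stop", out, ifelse(out == "stop_respond", 400, NA),
                    ssd_ms = ssd)
  fit <- fit_inhibition_function(tr)
  expect_true(fit$converged)
  expect_equal(fit$ssd50_ms, 240, tolerance = 10 / 240)
  expect_equal(fit$slope, 0.02, tolerance = 0.25)
})

test_that("complete separation falls back to the midpoint rule", {
  tr <- rbind(
    make_trials("stop", "stop_inhibit", NA_real_, ssd_ms = rep(c(100, 200), 5)),
    make_trials("stop", "stop_respond", 400, ssd_ms = rep(c(300, 400), 5)))
  fit <- fit_inhibition_function(tr)
  expect_false(fit$converged)
  expect_equal(fit$ssd50_ms, 250) # midpoint of 200 and 300
  # degenerate inputs are rejected
  expect_error(fit_inhibition_function(
    make_trials("stop", "stop_respond", 400, ssd_ms = c(100, 200, 300))),
    "both")
})

test_that("SSD50 is invariant to trial order", {
  sess <- make_valid_session()
  stops <- sess[sess$trial_type == "stop", ]
  set.seed(2)
  shuffled <- stops[sample(nrow(stops)), ]
  expect_equal(fit_inhibition_function(stops)$ssd50_ms,
               fit_inhibition_function(shuffled)$ssd50_ms)
})

test_that("session CV matches its definition and is scale invariant", {
  tr <- make_trials("go", "go_success", c(400, 600))
  expect_equal(session_cv(tr), 100 * sd(c(400, 600)) / 500)
  expect_equal(session_cv(make_trials("go", "go_success", rep(500, 10))), 0)
  tr2 <- tr; tr2$rt_ms <- tr2$rt_ms * 2
  expect_equal(session_cv(tr2), session_cv(tr))
  expect_warning(cv1 <- session_cv(make_trials("go", "go_success", 500)),
                 "fewer than 2")
  expect_true(is.na(cv1))
})

test_that("session summaries subtract SSD50 from the go median", {
  sess <- make_valid_session()
  sm <- summarize_session(sess)
  expect_true(sm$valid)
  expect_equal(sm$median_go_rt_ms, 520)
  expect_equal(sm$ssrt_ms, sm$median_go_rt_ms - sm$ssd50_ms)
  # invalid sessions carry the reason but no SSRT
  slow <- sess
  resp <- slow$outcome == "stop_respond"
  slow$rt_ms[resp] <- slow$rt_ms[resp] + 300
  sm2 <- summarize_session(slow)
  expect_false(sm2$valid)
  expect_identical(sm2$exclusion_reason, "race_rt_order")
  expect_true(is.na(sm2$ssrt_ms))
  expect_false(is.na(sm2$cv_percent)) # descriptives retained
})

test_that("estimation reads behaviour only, not scoring columns", {
  p <- participant_profile("S", variant = "points", dropout_hazard = 1)
  s <- simulate_session(p, 1, seed = 77)
  with_points <- summarize_session(s$trials)
  stripped <- s$trials
  stripped$points <- NA_real_; stripped$bonus_after <- NA_integer_
  without <- summarize_session(stripped)
  expect_equal(with_points$ssrt_ms, without$ssrt_ms)
  expect_equal(with_points$cv_percent, without$cv_percent)
})

test_that("participant aggregation averages valid sessions among the first k", {
  sm <- data.frame(participant_id = "A", session_number = 1:4,
                   valid = c(TRUE, TRUE, FALSE, TRUE),
                   exclusion_reason = c("none", "none", "ssd_rt_corr", "none"),
                   median_go_rt_ms = 500, ssd50_ms = 250,
                   ssrt_ms = c(250, 260, NA, 270),
                   cv_percent = c(18, 20, 22, 24), go_accuracy = 0.95,
                   score = NA_real_, stringsAsFactors = FALSE)
  agg <- aggregate_participants(sm, k = 4)
  expect_equal(agg$mean_ssrt_ms, 260)
  expect_equal(agg$mean_cv_percent, mean(c(18, 20, 22, 24)))
  expect_false(agg$ssrt_excluded)
  # all four invalid: participant flagged out of the SSRT analysis
  sm$valid <- FALSE; sm$ssrt_ms <- NA_real_
  agg2 <- aggregate_participants(sm, k = 4)
  expect_true(agg2$ssrt_excluded)
  expect_true(is.na(agg2$mean_ssrt_ms))
  # k = 1 is the identity on the first session
  sm$valid <- TRUE; sm$ssrt_ms <- c(250, 260, 255, 270)
  expect_equal(aggregate_participants(sm, k = 1)$mean_ssrt_ms, 250)
})

test_that("outlier screening uses the 4-IQR rule", {
  base <- data.frame(participant_id = sprintf("P%02d", 1:9),
                     mean_go_rt_ms = seq(480, 520, length.out = 9),
                     mean_accuracy = seq(0.90, 0.98, length.out = 9),
                     stringsAsFactors = FALSE)
  iqr <- diff(quantile(base$mean_go_rt_ms, c(0.25, 0.75), names = FALSE))
  med <- median(base$mean_go_rt_ms)
  inside <- base; inside$mean_go_rt_ms[5] <- med + 3 * iqr
  kept <- exclude_outlier_participants(inside, k_iqr = 4)
  expect_equal(nrow(kept), 9)
  outside <- base
  outside$participant_id[9] <- "OUT"
  outside$mean_go_rt_ms[9] <- med + 5 * iqr
  kept <- exclude_outlier_participants(outside, k_iqr = 4)
  expect_false("OUT" %in% kept$participant_id)
  expect_identical(attr(kept, "excluded"), "OUT")
  # degenerate IQR keeps exact-median values only, with a warning
  dg <- data.frame(participant_id = sprintf("P%02d", 1:10),
                   mean_go_rt_ms = c(rep(500, 9), 5000),
                   mean_accuracy = seq(0.9, 0.99, length.out = 10))
  expect_warning(kept <- exclude_outlier_participants(dg, k_iqr = 4), "IQR")
  expect_equal(nrow(kept), 9)
})
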