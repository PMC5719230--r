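test_that("Kaplan-Meier estimate equals the empirical survivor function", {
  km <- km_estimate(c(4, 4, 10, 10))
  expect_equal(km$survival[km$time == 4], 0.5)
  expect_equal(km$survival[km$time == 10], 0)
  one <- km_estimate(7)
  expect_equal(one$time, 7)
  expect_equal(one$survival, 0)
  expect_error(km_estimate(numeric(0)), "no survival times")
  # censoring: a censored time removes risk without an event
  km2 <- km_estimate(c(4, 10, 10), censored = c(FALSE, TRUE, TRUE))
  expect_equal(km2$survival[km2$time == 4], 2 / 3)
})

test_that("log-rank behaves at the null and counts df correctly", {
  x <- c(4, 5, 5, 6, 7, 8, 10, 10)
  lr <- logrank_test(c(x, x), rep(c("a", "b"), each = length(x)))
  expect_lt(lr$statistic, 1e-10)
  expect_equal(lr$df, 1)
  lr3 <- logrank_test(c(x, x + 1, x), rep(c("a", "b", "c"), each = length(x)),
                      censor_at = NULL)
  expect_equal(lr3$df, 2)
  expect_true(lr3$p_value >= 0 && lr3$p_value <= 1)
  # censoring mode: day-10 completers can be censored or counted as events
  lr_cens <- logrank_test(c(x, x + 1), rep(c("a", "b"), each = length(x)),
                          censor_at = 10)
  expect_false(identical(lr_cens$statistic,
                         logrank_test(c(x, x + 1),
                                      rep(c("a", "b"), each = length(x)),
                                      censor_at = NULL)$statistic))
})

test_that("one-way ANOVA matches the pooled t and a matrix oracle", {
  set.seed(41)
  x <- rnorm(12, 5); y <- rnorm(15, 6)
  an <- oneway_anova(c(x, y), rep(c("a", "b"), c(12, 15)))
  tt <- posthoc_t(x, y)
  expect_equal(an$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(an$p_value, tt$p_value, tolerance = 1e-10)

  # identical group means: F ~ 0
  g <- rep(c("a", "b", "c"), each = 4)
  v <- rep(c(1, 2, 3, 4), times = 3)
  an0 <- oneway_anova(v, g)
  expect_lt(an0$statistic, 1e-20)
  expect_lt(an0$effect_size[["partial_eta_sq"]], 1e-20)

  # matrix least-squares oracle on random data
  for (s in 1:5) {
    set.seed(100 + s)
    g <- factor(sample(c("a", "b", "c"), 30, replace = TRUE))
    v <- rnorm(30) + as.integer(g) * 0.3
    X <- model.matrix(~g)
    b <- solve(t(X) %*% X, t(X) %*% v)
    ssw <- sum((v - X %*% b)^2)
    ssb <- sum((X %*% b - mean(v))^2)
    f <- (ssb / (nlevels(g) - 1)) / (ssw / (30 - nlevels(g)))
    an <- oneway_anova(v, g)
    expect_equal(an$statistic, f, tolerance = 1e-10)
    expect_equal(an$effect_size[["partial_eta_sq"]], ssb / (ssb + ssw),
                 tolerance = 1e-10)
  }
})

test_that("mixed ANOVA decomposes into means and differences correctly", {
  set.seed(42)
  g <- rep(c("a", "b", "c"), each = 10)
  s1 <- rnorm(30, 56, 8)
  # pure time effect: shifts with identical group means leave no interaction
  e <- rnorm(30, 0, 2)
  e <- e - ave(e, g) # centre the noise within each group
  s2 <- s1 - 5 + e
  rm0 <- rm_anova(s1, s2, g)
  expect_lt(rm0$interaction$statistic, 1e-20)
  expect_gt(rm0$within$statistic, 10) # shared shift carries the time effect

  # within-subject F equals the squared paired t (single group)
  s2b <- s1 - 5 + rnorm(30, 0, 4)
  rm1 <- rm_anova(s1, s2b, rep("a", 30))
  tp <- t.test(s2b, s1, paired = TRUE)
  expect_equal(rm1$within$statistic, unname(tp$statistic)^2,
               tolerance = 1e-10)
  expect_equal(rm1$within$p_value, tp$p.value, tolerance = 1e-10)

  # balanced data: agrees with the classical Error-stratum ANOVA
  s2c <- s1 - 3 + rnorm(30, 0, 4) + (g == "b") * 2
  rm2 <- rm_anova(s1, s2c, g)
  long <- data.frame(score = c(s1, s2c), time = rep(c("t1", "t2"), each = 30),
                     g = factor(rep(g, 2)), id = factor(rep(1:30, 2)))
  cl <- summary(aov(score ~ g * time + Error(id / time), data = long))
  between_tab <- cl[["Error: id"]][[1]]
  within_tab <- cl[["Error: id:time"]][[1]]
  expect_equal(rm2$between$statistic, between_tab["g", "F value"],
               tolerance = 1e-8)
  expect_equal(rm2$within$statistic, within_tab["time", "F value"],
               tolerance = 1e-8)
  expect_equal(rm2$interaction$statistic, within_tab["g:time", "F value"],
               tolerance = 1e-8)

  # unbalanced missing time points are dropped listwise
  s2d <- s2c; s2d[c(3, 17)] <- NA
  expect_message(rm3 <- rm_anova(s1, s2d, g), "dropped")
  expect_equal(rm3$n_used, 28)
})

test_that("post hoc t matches a hand computation and the df convention", {
  x <- c(1, 2, 3); y <- c(2, 4, 6)
  r <- posthoc_t(x, y)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(r$statistic, t_hand, tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$effect_size[["cohens_d"]], (mean(x) - mean(y)) / sqrt(sp2),
               tolerance = 1e-12)
  # the study's printed df convention: n1 + n2 - 2
  set.seed(6)
  r2 <- posthoc_t(rnorm(86), rnorm(85))
  expect_equal(r2$df, 169)
  # identical groups
  r3 <- posthoc_t(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r3$statistic, 0)
  expect_equal(r3$effect_size[["cohens_d"]], 0)
})

test_that("JZS Bayes factor has the right structure and limits", {
  b <- jzs_bayes_t(t = 0, n1 = 86, n2 = 86)
  expect_lt(b$bf10, 1 / 3)
  expect_identical(b$favors, "H0")
  expect_identical(b$label, "Positive")
  expect_equal(b$bf10 * b$bf01, 1)
  # wider priors penalize the alternative monotonically
  rs <- c(0.5, 0.707, 1, 2, 5, 20)
  bfs <- vapply(rs, function(r)
    jzs_bayes_t(t = 1, n1 = 30, n2 = 30, prior_scale = r)$bf10, numeric(1))
  expect_true(all(diff(bfs) < 0))
  # data route equals statistic route
  set.seed(77)
  x <- rnorm(20, 0.3); y <- rnorm(25)
  sp2 <- (19 * var(x) + 24 * var(y)) / 43
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 20 + 1 / 25))
  expect_equal(jzs_bayes_t(x, y)$bf10,
               jzs_bayes_t(t = tstat, n1 = 20, n2 = 25)$bf10,
               tolerance = 1e-10)
})

test_that("Bayes factor labels follow the evidence bands", {
  expect_identical(bf_label(0.5)$label, "No support either way")
  expect_identical(bf_label(0.2), list(label = "Positive", favors = "H0"))
  expect_identical(bf_label(0.05), list(label = "Strong", favors = "H0"))
  expect_identical(bf_label(0.005), list(label = "Decisive", favors = "H0"))
  expect_identical(bf_label(5), list(label = "Positive", favors = "H1"))
  expect_identical(bf_label(50), list(label = "Strong", favors = "H1"))
  expect_identical(bf_label(500), list(label = "Decisive", favors = "H1"))
})

test_that("logistic return model matches an IRLS oracle and the Wald identity", {
  # fixed 20-row fixture
  score <- c(32, 45, 51, 58, 60, 41, 72, 66, 39, 55,
             48, 70, 63, 36, 52, 68, 44, 59, 75, 50)
  returned <- c(0, 1, 1, 0, 1, 0, 1, 1, 0, 1, 0, 1, 0, 0, 1, 1, 0, 1, 1, 0)
  m <- logistic_return_model(score, returned)
  # hand-rolled IRLS
  X <- cbind(1, score); b <- c(0, 0)
  for (i in 1:50) {
    eta <- X %*% b; mu <- 1 / (1 + exp(-eta)); w <- as.vector(mu * (1 - mu))
    b <- b + solve(t(X) %*% (X * w), t(X) %*% (returned - mu))
  }
  se <- sqrt(diag(solve(t(X) %*% (X * as.vector(
    1 / (1 + exp(-X %*% b)) * (1 - 1 / (1 + exp(-X %*% b))))))))
  expect_equal(m$beta, unname(b[2]), tolerance = 1e-6)
  expect_equal(m$se, unname(se[2]), tolerance = 1e-6)
  expect_equal(m$wald_chisq, (m$beta / m$se)^2)
  expect_equal(m$odds_ratio, exp(m$beta))
  expect_false(m$separation)
  # outcome independent of score: beta ~ 0, OR ~ 1
  set.seed(10)
  m0 <- logistic_return_model(rnorm(400, 50, 10), rbinom(400, 1, 0.7))
  expect_lt(abs(m0$beta), 0.03)
  expect_equal(m0$odds_ratio, 1, tolerance = 0.05)
  # complete separation is detected
  ms <- logistic_return_model(c(1:10, 21:30), rep(c(0, 1), each = 10))
  expect_true(ms$separation)
})

test_that("chi-square sample sizes scale and order as the noncentrality says", {
  n <- chisq_power_n(0.231, 2, 0.05, 0.95)
  # doubling phi divides the noncentrality requirement by 4
  n2 <- chisq_power_n(0.462, 2, 0.05, 0.95)
  expect_lte(abs(n2 - n / 4), 1)
  # monotone: non-increasing in phi, non-decreasing in power
  phis <- c(0.1, 0.2, 0.3, 0.5)
  ns <- vapply(phis, chisq_power_n, numeric(1), df = 2)
  expect_true(all(diff(ns) <= 0))
  pows <- c(0.5, 0.8, 0.9, 0.95, 0.99)
  ns <- vapply(pows, function(p) chisq_power_n(0.231, 2, power = p),
               numeric(1))
  expect_true(all(diff(ns) >= 0))
  # group rounding reproduces the equal-groups enrolment figure
  expect_equal(chisq_power_n(0.231, 2, 0.05, 0.95, groups = 3), 291)
  expect_error(chisq_power_n(0, 2), "phi")
})

test_that("Monte-Carlo power at the returned n meets the target", {
  # 3-category goodness of fit with Cohen's w = 0.231
  phi <- 0.231; dfree <- 2
  n <- chisq_power_n(phi, dfree, 0.05, 0.95)
  p0 <- rep(1 / 3, 3)
  d <- phi / sqrt(6) # symmetric perturbation (+d, 0, -d) has w = d * sqrt(6)
  p1 <- p0 + c(d, 0, -d)
  expect_equal(sqrt(sum((p1 - p0)^2 / p0)), phi, tolerance = 1e-12)
  set.seed(13)
  counts <- rmultinom(10000, n, p1)
  stat <- colSums((counts - n * p0)^2 / (n * p0))
  power_mc <- mean(stat > qchisq(0.95, dfree))
  se <- sqrt(0.95 * 0.05 / 10000)
  expect_gte(power_mc, 0.95 - 3 * se)
})
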