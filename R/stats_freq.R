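# Frequentist inferential layer: survival comparison, ANOVAs with partial
# eta squared, post hoc t tests, next-day-return logistic regression and
# the noncentral chi-square power/sample-size calculation.

#' Generic test result container
#'
#' @param name test label.
#' @param statistic test statistic value.
#' @param df degrees of freedom (1 or 2 components).
#' @param p_value p value.
#' @param effect_size optional named effect size (partial eta squared,
#'   Cohen's d, phi, ...).
#' @param ci_95 optional two-element confidence interval.
#' @param ... extra named fields carried through.
#' @return list of class `sst_test`.
#' @export
sst_test <- function(name, statistic, df, p_value, effect_size = NULL,
                     ci_95 = NULL, ...) {
  structure(list(name = name, statistic = statistic, df = df,
                 p_value = p_value, effect_size = effect_size,
                 ci_95 = ci_95, ...),
            class = "sst_test")
}

#' @export
print.sst_test <- function(x, ...) {
  dfs <- paste(round(x$df, 1), collapse = ",")
  cat(sprintf("%s: statistic=%.4g, df=%s, p=%.4g", x$name, x$statistic,
              dfs, x$p_value))
  if (!is.null(x$effect_size))
    cat(sprintf(", %s=%.4g", names(x$effect_size)[1], x$effect_size[[1]]))
  if (!is.null(x$ci_95))
    cat(sprintf(", 95%% CI [%.4g, %.4g]", x$ci_95[1], x$ci_95[2]))
  cat("\n")
  invisible(x)
}

#' Kaplan-Meier survival estimate over sessions completed
#'
#' Product-limit estimate of the probability of remaining in the study; with
#' all exits observed (no censoring) this equals the empirical survivor
#' function.
#'
#' @param times sessions completed per participant (events).
#' @param censored optional logical vector; `TRUE` marks right-censored
#'   times (e.g. participants who reached the design maximum).
#' @return data frame (`time`, `n_risk`, `n_event`, `survival`) of class
#'   `km_estimate`, with the underlying [survival::survfit] object in
#'   `attr(, "fit")`.
#' @export
km_estimate <- function(times, censored = NULL) {
  if (length(times) == 0L) stop("no survival times supplied")
  status <- if (is.null(censored)) rep(1L, length(times)) else
    as.integer(!censored)
  fit <- survival::survfit(survival::Surv(times, status) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv)
  attr(out, "fit") <- fit
  class(out) <- c("km_estimate", "data.frame")
  out
}

#' Log-rank comparison of attrition distributions
#'
#' Standard log-rank chi-square across variants. By default participants
#' reaching the design maximum (`censor_at`) are treated as right-censored
#' — the study ends, their exit is unobserved; `censor_at = NULL` treats
#' every time as an observed event.
#'
#' @param times sessions completed per participant.
#' @param group variant labels (>= 2 levels).
#' @param censor_at right-censoring threshold, or `NULL`.
#' @return an [sst_test] with the chi-square statistic and df = groups - 1.
#' @export
logrank_test <- function(times, group, censor_at = 10) {
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  status <- if (is.null(censor_at)) rep(1L, length(times)) else
    as.integer(times < censor_at)
  sd <- survival::survdiff(survival::Surv(times, status) ~ group)
  df <- nlevels(group) - 1L
  sst_test("log-rank", statistic = sd$chisq, df = df,
           p_value = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' One-way ANOVA with partial eta squared
#'
#' @param values numeric outcome.
#' @param group factor with >= 2 levels, >= 2 values each.
#' @return an [sst_test] with F, (df_between, df_within), p and
#'   partial eta squared = SSb / (SSb + SSw).
#' @export
oneway_anova <- function(values, group) {
  group <- droplevels(as.factor(group))
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]; group <- droplevels(group[ok])
  if (nlevels(group) < 2 || any(table(group) < 2))
    stop("need >= 2 groups with >= 2 values each")
  tab <- anova(lm(values ~ group))
  ssb <- tab$`Sum Sq`[1]; ssw <- tab$`Sum Sq`[2]
  if (ssw == 0) warning("zero within-group variance; F is unbounded")
  sst_test("one-way ANOVA", statistic = tab$`F value`[1],
           df = tab$Df, p_value = tab$`Pr(>F)`[1],
           effect_size = c(partial_eta_sq = ssb / (ssb + ssw)))
}

#' Mixed (2 x g) repeated-measures ANOVA
#'
#' Two within-subject levels (e.g. questionnaire scores at sessions 1 and
#' 4) crossed with a between-subjects factor. With only two within levels
#' sphericity holds automatically, and the design decomposes exactly:
#' subject means carry the between-subjects effect, difference scores carry
#' the time effect (tested against the unweighted grand mean of group mean
#' differences, i.e. Type III) and the interaction. Participants missing
#' either time point are dropped listwise.
#'
#' @param score_t1,score_t2 outcome at the two within-subject levels.
#' @param group between-subjects factor.
#' @return list of class `sst_rm_anova` with [sst_test] elements `between`,
#'   `within` and `interaction`, plus `n_used`.
#' @export
rm_anova <- function(score_t1, score_t2, group) {
  group <- as.factor(group)
  ok <- complete.cases(score_t1, score_t2, group)
  if (!all(ok)) message(sum(!ok), " participant(s) dropped listwise")
  s1 <- score_t1[ok]; s2 <- score_t2[ok]; g <- droplevels(group[ok])
  if (nlevels(g) < 1 || length(s1) < nlevels(g) + 1)
    stop("insufficient data for mixed ANOVA")
  n <- length(s1); ng <- nlevels(g)
  peta <- function(f, df1, df2) unname(f * df1 / (f * df1 + df2))
  # between subjects: ANOVA on subject means
  m <- (s1 + s2) / 2
  between <- if (ng >= 2) {
    tab <- anova(lm(m ~ g))
    sst_test("variant (between)", statistic = tab$`F value`[1], df = tab$Df,
             p_value = tab$`Pr(>F)`[1],
             effect_size = c(partial_eta_sq =
                               tab$`Sum Sq`[1] /
                               (tab$`Sum Sq`[1] + tab$`Sum Sq`[2])))
  } else NULL
  # within subjects: difference scores
  d <- s2 - s1
  sp <- split(d, g)
  ni <- lengths(sp)
  gm <- vapply(sp, mean, numeric(1))
  sse <- sum(vapply(sp, function(z) sum((z - mean(z))^2), numeric(1)))
  mse <- sse / (n - ng)
  gbar <- mean(gm) # unweighted grand mean of group differences
  var_gbar <- mse * sum(1 / ni) / ng^2
  f_time <- gbar^2 / var_gbar
  within <- sst_test("session (within)", statistic = f_time,
                     df = c(1, n - ng),
                     p_value = pf(f_time, 1, n - ng, lower.tail = FALSE),
                     effect_size = c(partial_eta_sq = peta(f_time, 1, n - ng)))
  interaction <- if (ng >= 2) {
    tab <- anova(lm(d ~ g))
    sst_test("session x variant", statistic = tab$`F value`[1], df = tab$Df,
             p_value = tab$`Pr(>F)`[1],
             effect_size = c(partial_eta_sq =
                               tab$`Sum Sq`[1] /
                               (tab$`Sum Sq`[1] + tab$`Sum Sq`[2])))
  } else NULL
  structure(list(between = between, within = within,
                 interaction = interaction, n_used = n),
            class = "sst_rm_anova")
}

#' @export
print.sst_rm_anova <- function(x, ...) {
  for (el in c("between", "within", "interaction"))
    if (!is.null(x[[el]])) print(x[[el]])
  invisible(x)
}

#' Post hoc two-sample t test with Cohen's d
#'
#' Student's pooled-variance t by default (df = n1 + n2 - 2, the convention
#' behind the study's printed dfs), with a Welch switch. Cohen's d uses the
#' pooled SD in either mode. No multiplicity correction is applied.
#'
#' @param x,y the two samples.
#' @param welch use Welch's unequal-variance t?
#' @param conf_level CI level for the mean difference.
#' @return an [sst_test] with t, df, p, `cohens_d` and the mean-difference
#'   CI; the raw mean difference is in `$mean_diff`.
#' @export
posthoc_t <- function(x, y, welch = FALSE, conf_level = 0.95) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) warning("zero pooled variance")
  tt <- stats::t.test(x, y, var.equal = !welch, conf.level = conf_level)
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  sst_test(if (welch) "Welch t" else "pooled t",
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value, effect_size = c(cohens_d = d),
           ci_95 = unname(tt$conf.int), mean_diff = mean(x) - mean(y))
}

#' Logistic regression of next-day return
#'
#' Fits `returned ~ score` by maximum likelihood and reports the slope,
#' its Wald chi-square (squared z), the odds ratio and its Wald CI.
#' Complete or quasi-complete separation is detected and flagged.
#'
#' @param score predictor (previous day's questionnaire score).
#' @param returned binary outcome (returned the following day).
#' @return list of class `sst_logistic` with `beta`, `se`, `wald_chisq`,
#'   `p_value`, `odds_ratio`, `or_ci_95`, `separation`, `n`.
#' @export
logistic_return_model <- function(score, returned) {
  ok <- complete.cases(score, returned)
  score <- score[ok]; returned <- as.integer(returned[ok])
  if (!all(returned %in% 0:1)) stop("returned must be binary")
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(returned ~ score, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  b <- sm["score", "Estimate"]; se <- sm["score", "Std. Error"]
  if (abs(b) > 20) sep <- TRUE
  structure(list(beta = b, se = se, wald_chisq = (b / se)^2,
                 p_value = pchisq((b / se)^2, 1, lower.tail = FALSE),
                 odds_ratio = exp(b),
                 or_ci_95 = exp(b + c(-1, 1) * qnorm(0.975) * se),
                 separation = sep, n = length(score), fit = fit),
            class = "sst_logistic")
}

#' Sample size for a chi-square test
#'
#' Smallest integer n such that a central-chi-square test with `df` degrees
#' of freedom at level `alpha` reaches the target power against an
#' alternative with effect size `phi`, where the test statistic is
#' noncentral chi-square with noncentrality n * phi^2.
#'
#' @param phi effect size (Cohen's w).
#' @param df degrees of freedom.
#' @param alpha significance level.
#' @param power target power.
#' @param groups optional group count: rounds the result up to the next
#'   multiple so groups can be equal-sized.
#' @return required total n (integer).
#' @examples
#' chisq_power_n(phi = 0.231, df = 2, alpha = 0.05, power = 0.95) # 290
#' @export
chisq_power_n <- function(phi, df, alpha = 0.05, power = 0.95,
                          groups = NULL) {
  stopifnot(phi > 0, df >= 1, alpha > 0, alpha < 1, power > alpha, power < 1)
  crit <- qchisq(1 - alpha, df)
  pow <- function(n) pchisq(crit, df, ncp = n * phi^2, lower.tail = FALSE)
  hi <- 2
  while (pow(hi) < power) {
    hi <- hi * 2
    if (hi > 1e9) stop("required sample size exceeds 1e9; unattainable")
  }
  lo <- 1
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (pow(mid) >= power) hi <- mid else lo <- mid
  }
  n <- hi
  if (!is.null(groups)) n <- as.integer(ceiling(n / groups) * groups)
  as.integer(n)
}
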