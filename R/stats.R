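#' Test result container
#'
#' Uniform result record for the statistical battery: statistic, degrees of
#' freedom, two-sided p value, and optional effect size / observed power.
#'
#' @param test Test label.
#' @param statistic Test statistic.
#' @param df Degrees of freedom (length 1 or 2).
#' @param p_value Two-sided p value.
#' @param eta_squared Optional effect size.
#' @param observed_power Optional post-hoc power.
#' @param estimate Optional effect estimate (e.g. mean difference).
#' @return An object of class `pq_test`.
#' @export
pq_test <- function(test, statistic, df, p_value, eta_squared = NA_real_,
                    observed_power = NA_real_, estimate = NA_real_) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, eta_squared = eta_squared,
                 observed_power = observed_power, estimate = estimate),
            class = "pq_test")
}

#' @export
print.pq_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g", x$test,
              x$statistic, paste(round(x$df, 2), collapse = ", "),
              x$p_value))
  if (!is.na(x$eta_squared))
    cat(sprintf(", eta^2 = %.3f", x$eta_squared))
  if (!is.na(x$observed_power))
    cat(sprintf(", power = %.3f", x$observed_power))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.pq_test <- function(x, ...) {
  data.frame(test = x$test, statistic = x$statistic,
             df1 = x$df[1L], df2 = if (length(x$df) > 1L) x$df[2L] else NA,
             p_value = x$p_value, eta_squared = x$eta_squared,
             observed_power = x$observed_power, estimate = x$estimate)
}

# Validate/standardize a factorial dataset; returns a data.frame with
# factors stimulation, time, replication and numeric response/covariate.
as_factorial <- function(data, covariate_required = FALSE) {
  need <- c("response", "stimulation", "time")
  if (!all(need %in% names(data)))
    stop("data needs columns: ", paste(need, collapse = ", "))
  if (covariate_required && !"covariate" %in% names(data))
    stop("ANCOVA requested but no covariate column present")
  d <- data.frame(
    response = as.numeric(data$response),
    stimulation = factor(data$stimulation),
    time = factor(data$time))
  if (nlevels(d$stimulation) < 2L || nlevels(d$time) < 2L)
    stop("each factor needs at least 2 levels")
  if ("replication" %in% names(data)) {
    r <- factor(data$replication)
    if (nlevels(r) >= 2L) d$replication <- r  # single block carries no term
  }
  if ("covariate" %in% names(data)) d$covariate <- as.numeric(data$covariate)
  d
}

#' ANCOVA interaction test with loading-control covariate
#'
#' Fits the linear model
#' `response ~ covariate + replication + stimulation * time` (replication, the
#' independent blot run, enters as a fixed additive blocking term) and tests
#' the stimulation-by-time interaction with a sequential F in which the
#' interaction is the last term. Partial eta squared and SPSS-style observed
#' power at `alpha` are attached.
#'
#' @param data Data frame with `response`, `stimulation`, `time`, `covariate`,
#'   and optionally `replication`.
#' @param alpha Significance level used for observed power (default 0.05).
#' @return A [pq_test()] with the model attached as attribute `model`.
#' @export
ancova_interaction <- function(data, alpha = 0.05) {
  d <- as_factorial(data, covariate_required = TRUE)
  form <- if ("replication" %in% names(d))
    response ~ covariate + replication + stimulation * time
  else response ~ covariate + stimulation * time
  fit <- stats::lm(form, data = d)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased terms: ", paste(bad, collapse = ", "))
  }
  at <- suppressWarnings(stats::anova(fit))  # perfect fits handled below
  i <- grep("stimulation:time", rownames(at))
  e <- which(rownames(at) == "Residuals")
  Fv <- at$`F value`[i]
  df1 <- at$Df[i]
  df2 <- at$Df[e]
  ss_i <- at$`Sum Sq`[i]
  ss_e <- at$`Sum Sq`[e]
  if (ss_i == 0) Fv <- 0   # identically-flat response gives 0/0
  res <- pq_test(
    "ANCOVA stimulation x time interaction",
    statistic = Fv, df = c(df1, df2),
    p_value = if (Fv == 0) 1 else at$`Pr(>F)`[i],
    eta_squared = if (ss_i + ss_e == 0) 0
      else eta_squared(ss_i, ss_e, partial = TRUE),
    observed_power = observed_power(Fv, df1, df2, alpha))
  attr(res, "model") <- fit
  res
}

#' Planned pairwise LSD comparisons of estimated marginal means
#'
#' Compares stimulation groups within each time level on covariate-adjusted
#' estimated marginal means from the ANCOVA model, with unadjusted
#' (least-significant-difference) p values as planned comparisons following
#' the omnibus test. Holm adjustment can be enabled.
#'
#' @param data As for [ancova_interaction()] (covariate optional; plain
#'   two-way ANOVA is used when absent).
#' @param adjust `"none"` (LSD, default) or any adjustment accepted by
#'   emmeans (e.g. `"holm"`).
#' @param at_level Optional single time level to restrict comparisons to.
#' @return Data frame: `time`, `contrast`, `estimate`, `se`, `df`,
#'   `t_ratio`, `p_value`.
#' @export
pairwise_lsd <- function(data, adjust = "none", at_level = NULL) {
  d <- as_factorial(data)
  has_cov <- "covariate" %in% names(d)
  rhs <- paste(c(if (has_cov) "covariate",
                 if ("replication" %in% names(d)) "replication",
                 "stimulation * time"), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("response ~", rhs)), data = d)
  if (!is.null(at_level)) {
    if (!at_level %in% levels(d$time))
      stop(sprintf("time level '%s' not present", at_level))
  }
  emm <- emmeans::emmeans(fit, ~ stimulation | time)
  prs <- summary(emmeans::contrast(emm, method = "pairwise", adjust = adjust))
  out <- data.frame(time = prs$time, contrast = prs$contrast,
                    estimate = prs$estimate, se = prs$SE, df = prs$df,
                    t_ratio = prs$t.ratio, p_value = prs$p.value)
  if (!is.null(at_level)) out <- out[out$time == at_level, ]
  rownames(out) <- NULL
  out
}

#' Student's t test (two-sample, pooled variance)
#'
#' @param x,y Numeric samples, each with n >= 2.
#' @return A [pq_test()].
#' @export
students_t <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y))
      return(pq_test("Student's t", 0, length(x) + length(y) - 2, 1,
                     estimate = 0))
    stop("zero variance in both samples: t statistic undefined")
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  pq_test("Student's t", unname(ht$statistic), unname(ht$parameter),
          ht$p.value, estimate = mean(x) - mean(y))
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test used to rule out nonparametric effects alongside
#' the t test. The reported statistic is the U of the first sample, computed
#' from rank sums with midranks for ties (normal approximation for p).
#'
#' @param x,y Numeric samples, each with n >= 2.
#' @return A [pq_test()] with `statistic` = U of `x`.
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
  pq_test("Mann-Whitney U", unname(ht$statistic), NA_real_, ht$p.value)
}

#' Tukey HSD pairwise comparisons of group means
#'
#' One-way ANOVA followed by Tukey's honestly-significant-difference test on
#' all pairwise group contrasts (studentized-range p values).
#'
#' @param values Numeric response vector.
#' @param groups Group labels (>= 2 groups, each n >= 2).
#' @return Data frame: `contrast`, `estimate`, `lower`, `upper`, `p_value`.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs n >= 2")
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  data.frame(contrast = rownames(tk), estimate = tk[, "diff"],
             lower = tk[, "lwr"], upper = tk[, "upr"],
             p_value = tk[, "p adj"], row.names = NULL)
}

#' Eta squared effect size
#'
#' Classical eta squared is the effect sum of squares over the total;
#' partial eta squared divides by effect + error sums of squares.
#'
#' @param ss_effect Effect sum of squares (>= 0).
#' @param ss_denom Error sum of squares (partial) or total sum of squares
#'   minus nothing (classical: pass `ss_total` with `partial = FALSE`).
#' @param partial If TRUE, `ss_effect / (ss_effect + ss_denom)`; otherwise
#'   `ss_effect / ss_denom` with `ss_denom` the total SS.
#' @return Effect size in \[0, 1\].
#' @export
eta_squared <- function(ss_effect, ss_denom, partial = FALSE) {
  stopifnot(ss_effect >= 0, ss_denom >= 0)
  denom <- if (partial) ss_effect + ss_denom else ss_denom
  if (denom == 0) stop("zero denominator: eta squared undefined")
  ss_effect / denom
}

#' Observed (post-hoc) power of an F test
#'
#' Power of the F test at the observed effect, taking the noncentrality
#' parameter as `F * df1` (the convention used by SPSS's "observed power"
#' column) against the central critical value at `alpha`.
#'
#' @param f Observed F statistic (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @param alpha Test size (default 0.05).
#' @return Power in \[0, 1\]; equals `alpha` when `f = 0`.
#' @export
observed_power <- function(f, df1, df2, alpha = 0.05) {
  if (!is.finite(f) || f < 0) stop("F must be a non-negative number")
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1")
  crit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(crit, df1, df2, ncp = f * df1, lower.tail = FALSE)
}

#' Tidy results table for a battery of tests
#'
#' @param ... [pq_test()] objects.
#' @return Data frame with one row per test (statistic, df, p, eta squared,
#'   observed power), mirroring a published effect-size/power table.
#' @export
results_table <- function(...) {
  do.call(rbind, lapply(list(...), as.data.frame))
}
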