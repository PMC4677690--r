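# Fixed worked dataset: 2 x 2 factorial, n = 4 per cell, with covariate.
ancova_fixture <- function() {
  data.frame(
    response = c(9.8, 11.2, 10.4, 10.9,  12.1, 13.0, 12.4, 11.8,
                 10.1, 9.6, 10.8, 10.2,  10.5, 9.9, 10.7, 11.1),
    covariate = c(4.9, 5.6, 5.2, 5.5,  5.8, 6.1, 5.9, 5.4,
                  5.0, 4.7, 5.3, 5.1,  5.2, 4.8, 5.4, 5.6),
    stimulation = rep(c("INS", "INS", "control", "control"), each = 4),
    time = rep(rep(c("20min", "2h"), each = 4), 2))
}

test_that("a flat response gives a zero interaction F", {
  d <- ancova_fixture()
  d$response <- 5
  res <- ancova_interaction(d)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$eta_squared, 0)
})

test_that("ANCOVA interaction F matches the normal-equations oracle to 1e-8", {
  d <- ancova_fixture()
  res <- ancova_interaction(d)
  want <- oracle_interaction_f(d$response, d$covariate, d$stimulation, d$time)
  expect_equal(res$statistic, want, tolerance = 1e-8)
  expect_equal(res$df, c(1, 11))
  # p value consistent with the F distribution
  expect_equal(res$p_value, pf(want, 1, 11, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("the covariate reduces residual error when it carries true signal", {
  set.seed(31)
  w <- generate_western_dataset(cell_means = rep(10, 6), covariate_slope = 2,
                                sd = 0.5, seed = 31)
  d <- data.frame(response = w$target, stimulation = w$stimulation,
                  time = w$time, replication = w$replication,
                  covariate = w$loading_control)
  with_cov <- attr(ancova_interaction(d), "model")
  no_cov <- stats::lm(response ~ replication + stimulation * time,
                      data = transform(d, replication = factor(replication)))
  expect_lt(sum(residuals(with_cov)^2), sum(residuals(no_cov)^2))
})

test_that("rank-deficient designs are rejected with the aliased terms named", {
  d <- ancova_fixture()
  d$covariate <- as.numeric(d$stimulation == "INS")  # aliased with stimulation
  expect_error(ancova_interaction(d), "alias")
})

test_that("ANCOVA interaction type-I error is near nominal under the null", {
  alpha <- 0.05
  reps <- 500
  rej <- vapply(seq_len(reps), function(s) {
    w <- generate_western_dataset(cell_means = rep(10, 4),
                                  time_levels = c("20min", "2h"),
                                  n_per_cell = 2L, n_replications = 2L,
                                  sd = 1, covariate_slope = 0.5, seed = s)
    d <- data.frame(response = w$target, stimulation = w$stimulation,
                    time = w$time, replication = w$replication,
                    covariate = w$loading_control)
    ancova_interaction(d)$p_value < alpha
  }, logical(1))
  se <- sqrt(alpha * (1 - alpha) / reps)
  expect_lt(abs(mean(rej) - alpha), 4 * se)
})

test_that("LSD pairwise comparisons match an explicit marginal-mean contrast", {
  d <- ancova_fixture()
  prs <- pairwise_lsd(d)
  expect_equal(nrow(prs), 2L)  # one contrast per time level
  # oracle: solve the normal equations, then contrast stim levels at each
  # time with the covariate held at its grand mean
  a <- factor(d$stimulation); b <- factor(d$time)
  X <- cbind(1, d$covariate, as.numeric(a == levels(a)[2]),
             as.numeric(b == levels(b)[2]),
             as.numeric(a == levels(a)[2]) * as.numeric(b == levels(b)[2]))
  beta <- solve(t(X) %*% X, t(X) %*% d$response)
  # row vectors for (stim, time, covariate = mean)
  rowv <- function(stim2, time2)
    c(1, mean(d$covariate), stim2, time2, stim2 * time2)
  for (i in seq_len(nrow(prs))) {
    t2 <- as.numeric(prs$time[i] == levels(b)[2])
    want <- sum((rowv(0, t2) - rowv(1, t2)) * beta)
    expect_equal(prs$estimate[i], want, tolerance = 1e-8)
  }
})

test_that("identical groups give LSD differences near zero with p near 1", {
  d <- data.frame(response = rep(c(4, 5, 6, 7), 4),
                  stimulation = rep(c("a", "b"), each = 8),
                  time = rep(rep(c("t1", "t2"), each = 4), 2))
  prs <- pairwise_lsd(d)
  expect_true(all(abs(prs$estimate) < 1e-12))
  expect_true(all(prs$p_value > 0.999))
  expect_error(pairwise_lsd(d, at_level = "t9"), "level")
})

test_that("a planted 3-sd shift is detected by LSD in at least 95% of runs", {
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    d <- data.frame(
      response = c(rnorm(8, 3), rnorm(8), rnorm(8), rnorm(8)),
      stimulation = rep(c("INS", "control"), each = 16),
      time = rep(rep(c("20min", "2h"), each = 8), 2))
    prs <- pairwise_lsd(d, at_level = "20min")
    prs$p_value[1] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("t and U behave on forced and random samples", {
  x <- c(4, 5, 6, 7)
  tt <- students_t(x, x)
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p_value, 1)
  expect_error(students_t(c(1, 1), c(2, 2)), "undefined")
  expect_equal(students_t(c(1, 1), c(1, 1))$statistic, 0)
  # complete separation: U of the first sample is 0
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$statistic, 0)
  expect_equal(mann_whitney_u(c(4, 5, 6), c(1, 2, 3))$statistic, 9)
  # brute-force pairwise wins + half-ties, with ties present
  set.seed(17)
  for (k in 1:20) {
    x <- sample(1:6, 8, replace = TRUE)
    y <- sample(1:6, 10, replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$statistic, oracle_u(x, y))
  }
})

test_that("t and U type-I error and direction agreement hold under simulation", {
  alpha <- 0.05
  reps <- 500
  set.seed(23)
  pt_ <- pu_ <- numeric(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(8); y <- rnorm(8)
    pt_[i] <- students_t(x, y)$p_value
    pu_[i] <- mann_whitney_u(x, y)$p_value
  }
  se <- sqrt(alpha * (1 - alpha) / reps)
  expect_lt(abs(mean(pt_ < alpha) - alpha), 4 * se)
  expect_lt(abs(mean(pu_ < alpha) - alpha), 4 * se)
  # large shift: both tests reject, same direction
  x <- rnorm(12, 5); y <- rnorm(12)
  expect_lt(students_t(x, y)$p_value, 0.01)
  expect_lt(mann_whitney_u(x, y)$p_value, 0.01)
  expect_gt(students_t(x, y)$statistic, 0)
  expect_gt(mann_whitney_u(x, y)$statistic, 12 * 12 / 2)
})

test_that("Tukey HSD reduces to the pooled t test with two groups", {
  set.seed(3)
  x <- rnorm(8, 1); y <- rnorm(8)
  tk <- tukey_hsd(c(x, y), rep(c("a", "b"), each = 8))
  tt <- students_t(x, y)
  # ptukey is evaluated numerically; agreement to its quadrature accuracy
  expect_equal(tk$p_value, tt$p_value, tolerance = 1e-4)
  # identical groups: p near 1
  tk0 <- tukey_hsd(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_true(all(tk0$p_value > 0.999))
  expect_error(tukey_hsd(1:5, c("a", "a", "b", "b", "c")), "n >= 2")
})

test_that("only contrasts with a shifted group turn significant", {
  hits_shift <- hits_null <- logical(100)
  for (s in 1:100) {
    set.seed(400 + s)
    v <- c(rnorm(8, 4), rnorm(8), rnorm(8))
    g <- rep(c("shifted", "g2", "g3"), each = 8)
    tk <- tukey_hsd(v, g)
    has_shift <- grepl("shifted", tk$contrast)
    hits_shift[s] <- all(tk$p_value[has_shift] < 0.05)
    hits_null[s] <- tk$p_value[!has_shift] >= 0.05
  }
  expect_gte(mean(hits_shift), 0.95)
  expect_gte(mean(hits_null), 0.9)
})

test_that("Tukey family-wise error stays near nominal under the null", {
  alpha <- 0.05
  reps <- 500
  set.seed(29)
  fam <- vapply(seq_len(reps), function(i) {
    v <- rnorm(15)
    any(tukey_hsd(v, rep(c("a", "b", "c"), each = 5))$p_value < alpha)
  }, logical(1))
  se <- sqrt(alpha * (1 - alpha) / reps)
  expect_lt(abs(mean(fam) - alpha), 4 * se)
})

test_that("eta squared follows its defining ratios", {
  expect_equal(eta_squared(0, 10), 0)
  expect_equal(eta_squared(3, 3, partial = TRUE), 0.5)
  # hand-computed from a small ANOVA table
  fit <- stats::aov(c(1, 2, 3, 7, 8, 9) ~ rep(c("a", "b"), each = 3))
  ss <- summary(fit)[[1]][["Sum Sq"]]
  expect_equal(eta_squared(ss[1], sum(ss)), ss[1] / sum(ss))
  expect_equal(eta_squared(ss[1], ss[2], partial = TRUE),
               ss[1] / (ss[1] + ss[2]))
  expect_error(eta_squared(0, 0), "denominator")
})

test_that("observed power matches the noncentral-F simulation oracle", {
  expect_equal(observed_power(0, 1, 40), 0.05)
  expect_gt(observed_power(100, 1, 40), 0.999)
  set.seed(41)
  f <- 4; df1 <- 1; df2 <- 40
  n <- 2e5
  draws <- (rchisq(n, df1, ncp = f * df1) / df1) / (rchisq(n, df2) / df2)
  crit <- qf(0.95, df1, df2)
  expect_equal(observed_power(f, df1, df2, 0.05), mean(draws > crit),
               tolerance = 0.01)
  expect_error(observed_power(-1, 1, 10), "non-negative")
  expect_error(observed_power(1, 0, 10), "degrees")
})

test_that("results_table rows mirror the battery outputs", {
  tab <- results_table(students_t(c(1, 2, 3), c(2, 3, 4)),
                       mann_whitney_u(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("test", "statistic", "p_value", "eta_squared",
                    "observed_power") %in% names(tab)))
})
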