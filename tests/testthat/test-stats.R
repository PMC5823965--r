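# independent oracle: within-subject 2x2 ANOVA via stats::aov with an
# Error(subject) stratum
aov_oracle <- function(values) {
  n <- dim(values)[1]
  long <- expand.grid(subject = factor(seq_len(n)), A = factor(1:2),
                      B = factor(1:2))
  long$y <- as.vector(values)
  fit <- stats::aov(y ~ A * B + Error(subject / (A * B)), data = long)
  sm <- summary(fit)
  get_f <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  c(A = get_f("Error: subject:A", "A"),
    B = get_f("Error: subject:B", "B"),
    AB = get_f("Error: subject:A:B", "A:B"))
}

test_that("paired t matches the textbook formula and degenerates correctly", {
  res <- paired_t(c(1, 2, 3), c(2, 4, 6))
  oracle <- stats::t.test(c(1, 2, 3), c(2, 4, 6), paired = TRUE)
  expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(res$df, 2L)
  expect_equal(res$d_z, res$t / sqrt(3), tolerance = 1e-12)
  expect_equal(res$d_av, cohens_d_av(2, sd(c(1, 2, 3)), 4, sd(c(2, 4, 6))))

  set.seed(14)
  for (r in 1:10) {
    x <- rnorm(sample(5:40, 1)); y <- rnorm(length(x))
    res <- paired_t(x, y)
    oracle <- stats::t.test(x, y, paired = TRUE)
    expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(res$p, oracle$p.value, tolerance = 1e-10)
  }
  x <- c(3, 5, 9)
  id <- paired_t(x, x)
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
  expect_equal(id$d_av, 0)
  expect_equal(id$d_z, 0)
  expect_error(paired_t(1:3, 1:4), "equal length")
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("rm-ANOVA reproduces aov and the squared-paired-t identities", {
  set.seed(8)
  for (r in 1:5) {
    n <- sample(4:12, 1)
    vals <- array(rnorm(n * 4, mean = rep(c(0, 1, 0.5, 2), each = n)),
                  dim = c(n, 2, 2))
    res <- rm_anova_2x2(vals)
    oracle <- aov_oracle(vals)
    expect_equal(res$F, unname(oracle), tolerance = 1e-10)
    # each 1-df effect equals the squared paired t of its contrast
    tA <- paired_t(apply(vals[, 1, ], 1, mean), apply(vals[, 2, ], 1, mean))
    tB <- paired_t(apply(vals[, , 1], 1, mean), apply(vals[, , 2], 1, mean))
    tI <- paired_t(vals[, 1, 1] - vals[, 2, 1], vals[, 1, 2] - vals[, 2, 2])
    expect_equal(res$F, c(tA$t^2, tB$t^2, tI$t^2), tolerance = 1e-10)
    expect_equal(res$p, c(tA$p, tB$p, tI$p), tolerance = 1e-10)
    # partial eta^2 identity for 1-df within effects
    expect_equal(res$partial_eta_sq, res$F / (res$F + n - 1), tolerance = 1e-12)
  }
  same <- array(rep(rnorm(3), 4), dim = c(3, 2, 2)) # cells identical per subject
  res <- rm_anova_2x2(same)
  expect_equal(res$F, c(0, 0, 0))
  expect_error(rm_anova_2x2(array(NA_real_, c(3, 2, 2))), "missing")
})

test_that("partial eta squared matches published F-to-effect-size conversions", {
  expect_equal(round(partial_eta_sq(5.20, 1, 31), 2), 0.14)
  expect_equal(round(partial_eta_sq(71.81, 1, 31), 2), 0.70)
  expect_equal(partial_eta_sq(0, 1, 31), 0)
  expect_error(partial_eta_sq(-1, 1, 31), "non-negative")
})

test_that("standardized regression matches the normal equations and its identities", {
  set.seed(23)
  n <- 6
  x1 <- rnorm(n); x2 <- rnorm(n); y <- 0.8 * x1 - 0.5 * x2 + rnorm(n)
  fit <- ols_regression_standardized(y, cbind(a = x1, b = x2))
  Z <- scale(cbind(x1, x2)); zy <- as.vector(scale(y))
  oracle <- solve(crossprod(cbind(1, Z)), crossprod(cbind(1, Z), zy))[-1]
  expect_equal(unname(fit$beta), as.vector(oracle), tolerance = 1e-10)
  expect_equal(fit$df2, n - 3L)

  # exact fit: y = x1, second predictor pure noise
  y2 <- x1
  fit2 <- ols_regression_standardized(y2, cbind(a = x1, b = x2))
  expect_equal(unname(fit2$beta), c(1, 0), tolerance = 1e-10)
  expect_equal(fit2$r_squared, 1, tolerance = 1e-12)

  # orthogonal standardized predictors: R^2 = sum of squared correlations
  q <- qr.Q(qr(cbind(1, rnorm(20), rnorm(20))))
  o1 <- q[, 2]; o2 <- q[, 3]
  yy <- 0.6 * o1 + 0.2 * o2 + rnorm(20, sd = 0.3)
  fit3 <- ols_regression_standardized(yy, cbind(o1 = o1, o2 = o2))
  expect_equal(fit3$r_squared, cor(yy, o1)^2 + cor(yy, o2)^2, tolerance = 1e-10)

  expect_error(ols_regression_standardized(y, cbind(a = x1, b = x1)),
               "collinear")
  expect_error(ols_regression_standardized(y, cbind(a = x1, b = rep(1, n))),
               "zero-variance")
})

test_that("pearson correlation matches the covariance-formula oracle", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(pearson_r(x, x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  set.seed(3)
  a <- rnorm(15); b <- rnorm(15)
  res <- pearson_r(a, b)
  oracle <- stats::cor.test(a, b)
  expect_equal(res$r, unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(res$r, cov(a, b) / (sd(a) * sd(b)), tolerance = 1e-12)
  expect_error(pearson_r(a, rep(1, 15)), "zero-variance")
  expect_error(pearson_r(1:2, 2:1), "at least 3")
})

test_that("the dependent-correlation Z test has the stated null and sign behaviour", {
  expect_equal(steiger_z(0.5, 0.5, 0.3, 32)$Z, 0)
  expect_equal(steiger_z(0.5, 0.5, 0.3, 32, "classic")$Z, 0)
  expect_gt(steiger_z(0.6, 0.3, 0.2, 32)$Z, 0)
  expect_lt(steiger_z(0.3, 0.6, 0.2, 32)$Z, 0)
  # antisymmetric in the two compared correlations
  expect_equal(steiger_z(0.6, 0.3, 0.2, 32)$Z,
               -steiger_z(0.3, 0.6, 0.2, 32)$Z)
  # larger samples give larger |Z| at fixed correlations
  expect_gt(abs(steiger_z(0.6, 0.3, 0.2, 64)$Z),
            abs(steiger_z(0.6, 0.3, 0.2, 32)$Z))
  expect_error(steiger_z(1, 0.5, 0.2, 32), "degenerate")
  expect_error(steiger_z(0.5, 0.4, 0.2, 3), "n >= 4")
})

test_that("paired-t power follows the noncentral t distribution", {
  # independent oracle: stats::power.t.test
  for (n in c(10, 32)) for (dz in c(0.2, 0.5, 0.8)) {
    # power.t.test drops the opposite-tail rejection region, so two-sided
    # values agree only up to that (small) term; one-sided agreement is exact
    expect_lt(abs(power_paired_t(n, dz, 0.05, tails = 2) -
                  stats::power.t.test(n = n, delta = dz, sd = 1,
                                      sig.level = 0.05,
                                      type = "paired")$power),
              0.006)
    expect_equal(power_paired_t(n, dz, 0.05, tails = 1),
                 stats::power.t.test(n = n, delta = dz, sd = 1,
                                     sig.level = 0.05, type = "paired",
                                     alternative = "one.sided")$power,
                 tolerance = 1e-6)
  }
  expect_equal(power_paired_t(32, 0, 0.05, tails = 2), 0.05, tolerance = 1e-9)
  expect_equal(power_paired_t(32, 0, 0.05, tails = 1), 0.05, tolerance = 1e-9)
  pw <- vapply(c(8, 16, 32, 64), power_paired_t, numeric(1), dz = 0.5)
  expect_true(all(diff(pw) > 0))
})

test_that("normality screening and Bonferroni behave as documented", {
  set.seed(2)
  normal <- rnorm(300)
  uniform <- runif(500)
  expect_gt(ks_normality(normal)$p, 0.05)
  expect_lt(ks_normality(uniform)$p, 0.05)
  classic <- ks_normality(uniform, lilliefors = FALSE)
  expect_true(classic$D > 0 && classic$p < 0.05)
  expect_error(ks_normality(rep(1, 10)), "zero-variance")
  expect_error(ks_normality(rnorm(4)), "at least 5")

  expect_equal(bonferroni(0.03, m = 2), 0.06)
  expect_equal(bonferroni(0.9, m = 3), 1)
  expect_equal(bonferroni(c(0.01, 0.4)), c(0.02, 0.8))
  expect_error(bonferroni(0.5, m = 0), ">= 1")
})

test_that("paired t and rm-ANOVA keep nominal type-I error under the null", {
  set.seed(99)
  reps <- 2000
  p_t <- numeric(reps)
  p_int <- numeric(reps)
  for (r in seq_len(reps)) {
    x <- rnorm(16); y <- rnorm(16)
    p_t[r] <- paired_t(x, y)$p
    vals <- array(rnorm(8 * 4), dim = c(8, 2, 2))
    p_int[r] <- rm_anova_2x2(vals)$p[3]
  }
  # binomial 99.9% band around 0.05 with 2000 replicates: ~ +/- 0.016
  expect_lt(abs(mean(p_t < 0.05) - 0.05), 0.017)
  expect_lt(abs(mean(p_int < 0.05) - 0.05), 0.017)
})
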