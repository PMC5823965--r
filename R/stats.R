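#' Paired t test with paired-design effect sizes
#'
#' Standard paired t on two matched samples, reporting both common Cohen's d
#' variants for paired designs: \code{d_av} (absolute mean difference over
#' the average of the two condition SDs) and \code{d_z} (mean difference over
#' the SD of the differences, i.e. t / sqrt(n)). Published effect sizes for
#' paired contrasts are computed under either convention, so both are
#' reported and labelled.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @param tails 1 or 2 (default) for the p value.
#' @return a list of class \code{"sst_ttest"}: \code{t}, \code{df}, \code{p},
#'   \code{mean_diff}, \code{d_av}, \code{d_z}, \code{n}.
#' @export
paired_t <- function(x, y, tails = 2) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("need at least 2 pairs")
  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    t <- if (md == 0) 0 else sign(md) * Inf
  } else {
    t <- md / (sdd / sqrt(n))
  }
  p <- if (tails == 2) 2 * stats::pt(-abs(t), n - 1) else stats::pt(-abs(t), n - 1)
  sd_av <- mean(c(stats::sd(x), stats::sd(y)))
  d_av <- if (sd_av == 0) {
    if (md == 0) 0 else Inf
  } else abs(md) / sd_av
  structure(list(t = t, df = n - 1L, p = min(p, 1), mean_diff = md,
                 d_av = d_av, d_z = t / sqrt(n), n = n),
            class = "sst_ttest")
}

#' Cohen's d (average-SD variant) from summary statistics
#'
#' \code{|m1 - m2| / mean(sd1, sd2)} — the paired-design effect size that can
#' be recomputed from printed condition means and SDs.
#'
#' @param m1,m2 condition means.
#' @param sd1,sd2 condition SDs.
#' @return the effect size.
#' @export
cohens_d_av <- function(m1, sd1, m2, sd2) abs(m1 - m2) / mean(c(sd1, sd2))

#' Two-way repeated-measures ANOVA (2 x 2, within subjects)
#'
#' Full within-subject sums-of-squares decomposition for a design with two
#' crossed two-level within-subject factors. Each effect (A, B, A:B) is
#' tested against its own effect-by-subject interaction with df = (1, n-1),
#' and partial eta squared is SS_effect / (SS_effect + SS_error), which for
#' these 1-df effects equals F / (F + n - 1).
#'
#' @param values numeric array \code{n x 2 x 2} (subjects x factor A x
#'   factor B); dimnames of dims 2-3, if present, name the levels.
#' @param factor_names length-2 character, names of factors A and B.
#' @return a data.frame of class \code{"sst_anova"} with one row per effect:
#'   \code{effect}, \code{F}, \code{df1}, \code{df2}, \code{p},
#'   \code{partial_eta_sq}.
#' @export
rm_anova_2x2 <- function(values, factor_names = c("A", "B")) {
  d <- dim(values)
  if (length(d) != 3L || d[2] != 2L || d[3] != 2L)
    stop("values must be an n x 2 x 2 array")
  n <- d[1]
  if (n < 2L) stop("need at least 2 subjects")
  if (anyNA(values)) stop("missing cells are not allowed")

  grand <- mean(values)
  subj <- apply(values, 1, mean)
  a_m <- apply(values, 2, mean)
  b_m <- apply(values, 3, mean)
  ab_m <- apply(values, c(2, 3), mean)
  ia_m <- apply(values, c(1, 2), mean)
  ib_m <- apply(values, c(1, 3), mean)

  ss_a <- 2 * n * sum((a_m - grand)^2)
  ss_b <- 2 * n * sum((b_m - grand)^2)
  # interaction cell deviations: cell - A - B + grand
  dev_ab <- ab_m - outer(a_m, rep(1, 2)) - outer(rep(1, 2), b_m) + grand
  ss_ab <- n * sum(dev_ab^2)
  dev_as <- ia_m - outer(subj, rep(1, 2)) - outer(rep(1, n), a_m) + grand
  ss_as <- 2 * sum(dev_as^2)
  dev_bs <- ib_m - outer(subj, rep(1, 2)) - outer(rep(1, n), b_m) + grand
  ss_bs <- 2 * sum(dev_bs^2)
  full <- values
  for (i in seq_len(n)) for (a in 1:2) for (b in 1:2)
    full[i, a, b] <- values[i, a, b] - ia_m[i, a] - ib_m[i, b] - ab_m[a, b] +
      subj[i] + a_m[a] + b_m[b] - grand
  ss_abs <- sum(full^2)

  df_err <- n - 1L
  row <- function(name, ss_eff, ss_err) {
    mse <- ss_err / df_err
    f <- if (mse == 0) {
      if (ss_eff == 0) 0 else Inf
    } else (ss_eff / 1) / mse
    data.frame(effect = name, F = f, df1 = 1L, df2 = df_err,
               p = stats::pf(f, 1, df_err, lower.tail = FALSE),
               partial_eta_sq = if (ss_eff + ss_err == 0) 0
                                else ss_eff / (ss_eff + ss_err),
               stringsAsFactors = FALSE)
  }
  out <- rbind(row(factor_names[1], ss_a, ss_as),
               row(factor_names[2], ss_b, ss_bs),
               row(paste(factor_names, collapse = " x "), ss_ab, ss_abs))
  class(out) <- c("sst_anova", "data.frame")
  out
}

#' Partial eta squared from an F statistic
#'
#' \code{F * df1 / (F * df1 + df2)} — recomputable directly from a printed F
#' value and its degrees of freedom.
#'
#' @param F F statistic (>= 0).
#' @param df_effect,df_error degrees of freedom.
#' @return partial eta squared in [0, 1).
#' @examples
#' partial_eta_sq(5.20, 1, 31) # ~0.14
#' @export
partial_eta_sq <- function(F, df_effect, df_error) {
  if (any(F < 0)) stop("F must be non-negative")
  stopifnot(df_effect >= 1, df_error >= 1)
  F * df_effect / (F * df_effect + df_error)
}

#' Multiple regression on standardized variables
#'
#' z-scores the outcome and every predictor, fits ordinary least squares and
#' reports standardized coefficients (betas), their t statistics with
#' n - k - 1 df, the model R-squared and F(k, n - k - 1).
#'
#' @param y numeric outcome.
#' @param predictors numeric matrix or data.frame of predictors (columns are
#'   variables).
#' @return a list of class \code{"sst_regression"}: \code{beta} (named),
#'   \code{t}, \code{p}, \code{r_squared}, \code{F}, \code{df1}, \code{df2},
#'   \code{p_model}, \code{n}.
#' @export
ols_regression_standardized <- function(y, predictors) {
  X <- as.matrix(predictors)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  k <- ncol(X)
  if (nrow(X) != n) stop("y and predictors must have matching rows")
  if (n <= k + 1L) stop("need n > k + 1 observations")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance predictor: ", paste(colnames(X)[sds == 0], collapse = ", "))
  if (stats::sd(y) == 0) stop("outcome has zero variance")
  Z <- scale(X)
  zy <- as.vector(scale(y))
  qrZ <- qr(cbind(1, Z))
  if (qrZ$rank < k + 1L) {
    drop_idx <- qrZ$pivot[seq_len(qrZ$rank)]
    offending <- setdiff(seq_len(k + 1L), drop_idx) - 1L
    stop("collinear predictor: ", paste(colnames(X)[offending], collapse = ", "))
  }
  fit <- stats::lm(zy ~ Z)
  # summary.lm warns on exact fits; R^2 = 1 is a legitimate limiting case here
  sm <- suppressWarnings(summary(fit))
  beta <- stats::coef(fit)[-1]
  names(beta) <- colnames(X)
  r2 <- sm$r.squared
  df2 <- n - k - 1L
  Fstat <- if (r2 >= 1) Inf else (r2 / k) / ((1 - r2) / df2)
  tvals <- sm$coefficients[-1, "t value"]
  pvals <- sm$coefficients[-1, "Pr(>|t|)"]
  names(tvals) <- names(pvals) <- colnames(X)
  structure(list(beta = beta, t = tvals, p = pvals, r_squared = r2,
                 F = Fstat, df1 = k, df2 = df2,
                 p_model = stats::pf(Fstat, k, df2, lower.tail = FALSE),
                 n = n),
            class = "sst_regression")
}

#' Pearson correlation with two-tailed t-based p value
#'
#' @param x,y numeric vectors (n >= 3), non-constant.
#' @return a list of class \code{"sst_correlation"}: \code{r}, \code{n},
#'   \code{p}.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance input")
  r <- stats::cor(x, y)
  t <- r * sqrt((n - 2) / (1 - r^2))
  structure(list(r = r, n = n, p = 2 * stats::pt(-abs(t), n - 2)),
            class = "sst_correlation")
}

#' Dependent-correlation Z test (Steiger)
#'
#' Compares two correlations that share one variable within the same sample
#' (r12 vs r13, with r23 the correlation of the non-shared variables).
#' Both Fisher-transformed correlations are compared with the asymptotic
#' dependent-correlation covariance. The \code{"updated"} variant (default)
#' plugs the average of r12 and r13 into the covariance term, which improves
#' the small-sample behaviour of the classic statistic; \code{"classic"} uses
#' the individual correlations. Positive Z means r12 > r13.
#'
#' @param r12,r13 the two correlations sharing variable 1.
#' @param r23 correlation between variables 2 and 3.
#' @param n sample size (>= 4).
#' @param variant \code{"updated"} or \code{"classic"}.
#' @return a list of class \code{"sst_steiger"}: \code{Z}, \code{p} (two
#'   tailed), \code{variant}.
#' @export
steiger_z <- function(r12, r13, r23, n, variant = c("updated", "classic")) {
  variant <- match.arg(variant)
  rs <- c(r12, r13, r23)
  if (any(abs(rs) > 1)) stop("correlations must lie in [-1, 1]")
  if (any(abs(c(r12, r13)) == 1)) stop("degenerate |r| = 1")
  if (n < 4L) stop("need n >= 4")
  z1 <- atanh(r12)
  z2 <- atanh(r13)
  cov_term <- function(ra, rb) {
    (r23 * (1 - ra^2 - rb^2) - 0.5 * ra * rb * (1 - ra^2 - rb^2 - r23^2)) /
      ((1 - ra^2) * (1 - rb^2))
  }
  cterm <- if (variant == "updated") {
    rbar <- (r12 + r13) / 2
    cov_term(rbar, rbar)
  } else {
    cov_term(r12, r13)
  }
  Z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cterm))
  structure(list(Z = Z, p = 2 * stats::pnorm(-abs(Z)), variant = variant),
            class = "sst_steiger")
}

#' Power of a paired t test (noncentral t)
#'
#' Exact power from the noncentral t distribution with noncentrality
#' \code{dz * sqrt(n)} and \code{n - 1} df, where \code{dz} is the
#' standardized mean of the paired differences.
#'
#' @param n number of pairs (>= 2).
#' @param dz effect size (mean difference / SD of differences), >= 0.
#' @param alpha significance level.
#' @param tails 1 or 2.
#' @return the power (a proportion).
#' @examples
#' power_paired_t(32, 0.5, alpha = 0.05, tails = 1) # > 0.8
#' @export
power_paired_t <- function(n, dz, alpha = 0.05, tails = 2) {
  if (n < 2) stop("need n >= 2")
  if (dz < 0) stop("dz must be >= 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!tails %in% c(1, 2)) stop("tails must be 1 or 2")
  df <- n - 1
  ncp <- dz * sqrt(n)
  if (tails == 1) {
    crit <- stats::qt(1 - alpha, df)
    stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp = ncp)
  }
}

#' Kolmogorov-Smirnov normality screen
#'
#' Default is the Lilliefors-corrected test (normal reference with
#' sample-estimated mean and SD, p value from the Lilliefors distribution);
#' \code{lilliefors = FALSE} gives the classic KS test against a normal with
#' the sample mean and SD treated as known (its p value is conservative when
#' parameters are estimated).
#'
#' @param x numeric vector (n >= 5), non-constant.
#' @param lilliefors logical.
#' @return a list with \code{D} and \code{p}.
#' @export
ks_normality <- function(x, lilliefors = TRUE) {
  if (length(x) < 5L) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("zero-variance input")
  if (lilliefors) {
    res <- nortest::lillie.test(x)
  } else {
    res <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  }
  list(D = unname(res$statistic), p = res$p.value)
}

#' Bonferroni correction
#'
#' @param p_values numeric vector of p values.
#' @param m number of comparisons (default: length of \code{p_values}).
#' @return adjusted p values, \code{min(1, p * m)}.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < 1) stop("m must be >= 1")
  pmin(1, p_values * m)
}
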