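# Age-adjusted models: equality with a brute-force normal-equations
# oracle, score-equation residuals, parameter recovery against the
# generator truth, degenerate-input errors, CI coverage, and the gate.

test_that("linear fit equals the normal-equations oracle on small cohorts", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(15:50, 1)
    dat <- data.frame(
      sex = "woman",
      age = runif(n, 50, 90),
      ucd = rlnorm(n, 1.5, 0.6))
    dat$crcl <- 150 - 1.2 * dat$ucd - 1.1 * dat$age + rnorm(n, 0, 15)
    f <- fit_linear_age_adjusted(dat, "crcl", "woman")

    X <- cbind(1, dat$ucd, dat$age)
    beta_oracle <- solve(t(X) %*% X, t(X) %*% dat$crcl)
    expect_equal(unname(f$coef), drop(beta_oracle), tolerance = 1e-10)
    r <- dat$crcl - X %*% beta_oracle
    sigma_oracle <- sqrt(sum(r^2) / (n - 3))
    expect_equal(f$sigma, sigma_oracle, tolerance = 1e-10)
    vcov_oracle <- sigma_oracle^2 * solve(t(X) %*% X)
    expect_equal(unname(f$vcov), unname(vcov_oracle), tolerance = 1e-8)
    # residual orthogonality X'r = 0
    expect_lt(max(abs(t(X) %*% r)) / max(abs(dat$crcl)), 1e-8)
  }
})

test_that("linear fit recovers the generator truth at large n", {
  strata <- renalbmd:::.default_strata
  strata$n <- c(0L, 5000L, 0L, 0L)  # women, polluted only
  co <- sample_cohort(cohort_config(strata = strata, mode = "endpoint", seed = 8))
  f <- fit_linear_age_adjusted(co, "crcl", "woman")
  expect_equal(unname(f$coef["ucd"]), -1.24, tolerance = 0.05 / 1.24)
  expect_equal(f$sigma, 19.4549, tolerance = 0.02)
  expect_lt(f$p["ucd"], 1e-10)
})

test_that("null slope is recovered when the endpoint ignores dose", {
  set.seed(31)
  dat <- data.frame(sex = "man", age = runif(200, 50, 90),
                    ucd = rlnorm(200, 1, 0.7))
  dat$egfr <- 60 + rnorm(200, 0, 1e-6)
  f <- fit_linear_age_adjusted(dat, "egfr", "man")
  expect_lt(abs(f$coef["ucd"]), 1e-6)
  expect_gt(f$p["ucd"], 0.05)
})

test_that("ln transform excludes non-positive beta2-MG with a count", {
  set.seed(41)
  dat <- data.frame(sex = "man", age = runif(40, 50, 90),
                    ucd = rlnorm(40, 1, 0.7))
  dat$u_b2mg <- exp(-6 + 0.3 * dat$ucd + 0.15 * dat$age + rnorm(40, 0, 2))
  dat$u_b2mg[1:3] <- 0
  f <- fit_linear_age_adjusted(dat, "ln_b2mg", "man")
  expect_identical(f$n, 37L)
  expect_identical(f$n_excluded, 3L)
})

test_that("degenerate designs raise informative errors", {
  dat <- data.frame(sex = "man", age = rep(70, 30), ucd = rlnorm(30), crcl = rnorm(30, 60))
  expect_error(fit_linear_age_adjusted(dat, "crcl", "man"), "rank-deficient")
  expect_error(fit_linear_age_adjusted(dat[1:5, ], "crcl", "man"), "< 10")
})

test_that("logistic fit recovers a known odds ratio and satisfies the score", {
  strata <- renalbmd:::.default_strata
  strata$n <- c(10000L, 0L, 10000L, 0L)  # 20k men across both areas
  co <- sample_cohort(cohort_config(strata = strata, mode = "endpoint", seed = 17))
  f <- fit_logistic_age_adjusted(co, "tr_below_95", "man")
  expect_true(f$converged)
  expect_equal(unname(f$or["ucd"]), 1.17, tolerance = 0.02 / 1.17)
  # score equations X'(y - p) = 0 at the reported optimum
  X <- cbind(1, f$data$ucd, f$data$age)
  mu <- plogis(drop(X %*% f$coef))
  expect_lt(max(abs(t(X) %*% (f$data$y - mu))), 1e-8)
  # odds ratios are the exact exponential of the coefficients
  expect_identical(f$or, exp(f$coef))
})

test_that("logistic degeneracies are explicit errors", {
  set.seed(51)
  dat <- data.frame(sex = "man", age = runif(40, 50, 90), ucd = rlnorm(40, 1, 0.7))
  dat$tr_below_95 <- FALSE
  expect_error(fit_logistic_age_adjusted(dat, "tr_below_95", "man"),
               "single class")
  # complete separation in dose
  dat$tr_below_95 <- dat$ucd > median(dat$ucd)
  dat$age <- 70 + 0.01 * seq_len(40)  # age nearly constant, dose separates
  expect_error(fit_logistic_age_adjusted(dat, "tr_below_95", "man"),
               "separation")
})

test_that("dose permuted against outcome gives a null odds ratio", {
  strata <- renalbmd:::.default_strata
  strata$n <- c(2000L, 0L, 2000L, 0L)
  co <- sample_cohort(cohort_config(strata = strata, mode = "endpoint", seed = 19))
  set.seed(19)
  co$ucd <- sample(co$ucd)
  f <- fit_logistic_age_adjusted(co, "tr_below_95", "man")
  expect_equal(unname(f$or["ucd"]), 1, tolerance = 0.05)
  expect_gt(f$p["ucd"], 0.05)
})

test_that("t-based Wald CIs cover the true slope about 95% of the time", {
  hits <- 0L
  for (r in 1:500) {
    co <- sample_cohort(cohort_config(mode = "endpoint", seed = 20000 + r))
    f <- fit_linear_age_adjusted(co, "crcl", "woman")
    hits <- hits + (f$ci["ucd", "lower"] <= -1.24 && -1.24 <= f$ci["ucd", "upper"])
  }
  expect_gte(hits / 500, 0.92)
  expect_lte(hits / 500, 0.98)
})

test_that("the significance gate follows the dose p-value", {
  expect_identical(significance_gate(make_linear_fit(endpoint = "crcl", sex = "man",
                                                     p_dose = 0.118)), "skip")
  expect_identical(significance_gate(make_linear_fit(endpoint = "egfr", sex = "woman",
                                                     p_dose = 0.082)), "skip")
  expect_identical(significance_gate(make_linear_fit(endpoint = "egfr", sex = "man",
                                                     p_dose = 0.041)), "proceed")
  expect_identical(significance_gate(make_logistic_fit(p_dose = 0.022)), "proceed")
  expect_identical(significance_gate(make_linear_fit(p_dose = 0.05)), "skip")
})
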