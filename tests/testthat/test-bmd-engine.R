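# BMD engine: closed forms against an independent tail-probability
# root-find, quantile-ratio laws, cut-off and background examples, BMDL
# methods (profile / delta / slope bound) and their limits.

test_that("hybrid closed form agrees with the tail-probability root-find", {
  set.seed(7)
  for (i in 1:100) {
    adv <- sample(c("low_is_adverse", "high_is_adverse"), 1)
    beta <- (if (adv == "low_is_adverse") -1 else 1) * runif(1, 0.05, 3)
    sigma <- runif(1, 0.5, 30)
    p0 <- runif(1, 0.01, 0.2)
    bmr <- runif(1, 0.01, min(0.3, 0.9 - p0))
    rt <- sample(c("additional", "extra"), 1)
    fit <- make_linear_fit(endpoint = if (adv == "low_is_adverse") "crcl" else "ln_b2mg",
                           beta_dose = beta, sigma = sigma)
    spec <- bmd_spec(fit$endpoint, "hybrid_continuous", bmr = bmr, p0 = p0,
                     risk_type = rt, adversity = adv)
    expect_equal(hybrid_bmd(fit, spec),
                 oracle_hybrid_bmd(beta, sigma, p0, bmr, rt, adv),
                 tolerance = 1e-8)
  }
})

test_that("hybrid BMD is homogeneous in sigma and beta", {
  spec <- bmd_spec("crcl", "hybrid_continuous")
  f <- make_linear_fit(beta_dose = -1.1, sigma = 12)
  b <- hybrid_bmd(f, spec)
  expect_equal(hybrid_bmd(make_linear_fit(beta_dose = -1.1, sigma = 36), spec),
               3 * b, tolerance = 1e-12)
  expect_equal(hybrid_bmd(make_linear_fit(beta_dose = -3.3, sigma = 12), spec),
               b / 3, tolerance = 1e-12)
  # a slope signed away from adversity is refused with a diagnostic
  expect_error(hybrid_bmd(make_linear_fit(beta_dose = 1.1), spec), "adverse-signed")
})

test_that("additional- and extra-risk BMR ratios are distinct constants", {
  # frozen from the standard-normal quantile oracle
  spec05 <- bmd_spec("crcl", "hybrid_continuous", bmr = 0.05)
  spec10 <- bmd_spec("crcl", "hybrid_continuous", bmr = 0.10)
  f <- make_linear_fit()
  expect_equal(hybrid_bmd(f, spec10) / hybrid_bmd(f, spec05),
               1.674695, tolerance = 1e-4)
  e05 <- bmd_spec("crcl", "hybrid_continuous", bmr = 0.05, risk_type = "extra")
  e10 <- bmd_spec("crcl", "hybrid_continuous", bmr = 0.10, risk_type = "extra")
  expect_equal(hybrid_bmd(f, e10) / hybrid_bmd(f, e05),
               1.681543, tolerance = 1e-4)
  expect_false(isTRUE(all.equal(hybrid_bmd(f, e05), hybrid_bmd(f, spec05))))
})

test_that("hybrid cut-off sits at the background quantile", {
  spec <- bmd_spec("crcl", "hybrid_continuous")
  f <- make_linear_fit(intercept = 100, beta_age = 0, sigma = 20)
  expect_equal(hybrid_cutoff(f, spec), 67.102927, tolerance = 1e-6)
  # high-is-adverse, ln scale: 7 + 1.6449 * 0.8
  fh <- make_linear_fit(endpoint = "ln_b2mg", intercept = 7, beta_age = 0,
                        beta_dose = 0.3, sigma = 0.8)
  sh <- bmd_spec("ln_b2mg", "hybrid_continuous")
  expect_equal(hybrid_cutoff(fh, sh), 8.315883, tolerance = 1e-6)
  expect_equal(exp(hybrid_cutoff(fh, sh)), 4088.29, tolerance = 1e-4)
  # p0 = 0.5 puts the cut-off at the age-adjusted mean
  s5 <- bmd_spec("crcl", "hybrid_continuous", p0 = 0.5, bmr = 0.1)
  expect_equal(hybrid_cutoff(f, s5), 100)
})

test_that("hybrid BMDL methods behave in their limits and on data", {
  # zero-variance limit: delta and slope-bound BMDLs collapse onto the BMD
  f0 <- make_linear_fit(se_dose = 1e-12, n = 1e9)
  spec_d <- bmd_spec("crcl", "hybrid_continuous", bmdl_method = "delta")
  spec_s <- bmd_spec("crcl", "hybrid_continuous", bmdl_method = "slope_bound")
  b0 <- hybrid_bmd(f0, spec_d)
  expect_equal(hybrid_bmdl(f0, spec_d), b0, tolerance = 1e-4)
  expect_equal(hybrid_bmdl(f0, spec_s), b0, tolerance = 1e-4)

  # on a large simulated cohort: bmdl < bmd, profile and delta agree to a
  # few percent, and bmdl/bmd approaches 1 as n grows
  strata <- renalbmd:::.default_strata
  strata$n <- c(0L, 5000L, 0L, 0L)
  co <- sample_cohort(cohort_config(strata = strata, mode = "endpoint", seed = 23))
  f <- fit_linear_age_adjusted(co, "crcl", "woman")
  spec_p <- bmd_spec("crcl", "hybrid_continuous", bmdl_method = "profile")
  bmd <- hybrid_bmd(f, spec_p)
  bl_p <- hybrid_bmdl(f, spec_p)
  bl_d <- hybrid_bmdl(f, spec_d)
  expect_lt(bl_p, bmd)
  expect_gt(bl_p / bmd, 0.95)          # consistency at n = 5000
  expect_equal(bl_p, bl_d, tolerance = 0.02)

  co_small <- sample_cohort(cohort_config(mode = "endpoint", seed = 23))
  f_small <- fit_linear_age_adjusted(co_small, "crcl", "woman")
  expect_lt(hybrid_bmdl(f_small, spec_p) / hybrid_bmd(f_small, spec_p),
            bl_p / bmd)                # wider gap at study scale
})

test_that("logistic background and closed-form BMD match hand values", {
  fl <- make_logistic_fit(intercept = -4.0, beta_age = 0.03)
  spec <- bmd_spec("tr_below_95", "logistic")
  expect_equal(logistic_background(fl, spec), 0.1301085, tolerance = 1e-6)
  fl0 <- make_logistic_fit(intercept = 0, beta_age = 0)
  expect_equal(logistic_background(fl0, spec), 0.5)

  expect_equal(logistic_bmd(log(1.17), 0.118, 0.05), 2.621842, tolerance = 1e-6)
  expect_equal(logistic_bmd(log(1.21), 0.034, 0.05), 5.023617, tolerance = 1e-6)
  expect_equal(logistic_bmd(log(1.12), 0.066, 0.10), 9.137811, tolerance = 1e-6)
  expect_error(logistic_bmd(-0.1, 0.1, 0.05), "beta_dose")

  # the naive slope bound from the printed upper CI does not reproduce the
  # published BMDL (1.37 vs 1.8) — the motivation for profile/delta defaults
  expect_equal(logistic_bmd(log(1.35), 0.118, 0.05), 1.371, tolerance = 1e-3)
})

test_that("logistic BMD is invariant to the age slope at fixed p0", {
  spec <- bmd_spec("tr_below_95", "logistic", p0 = 0.118)
  f1 <- make_logistic_fit(beta_age = 0.01)
  f2 <- make_logistic_fit(beta_age = 0.12)
  est1 <- renalbmd:::logistic_bmd_from_fit(f1, spec)
  est2 <- renalbmd:::logistic_bmd_from_fit(f2, spec)
  expect_identical(est1$bmd, est2$bmd)
})

test_that("logistic BMDL methods behave in their limits and on data", {
  spec_d <- bmd_spec("tr_below_95", "logistic", bmdl_method = "delta")
  f0 <- make_logistic_fit(se_dose = 1e-12)
  est <- renalbmd:::logistic_bmd_from_fit(f0, spec_d)
  expect_equal(logistic_bmdl(f0, spec_d), est$bmd, tolerance = 1e-4)

  strata <- renalbmd:::.default_strata
  strata$n <- c(3000L, 0L, 3000L, 0L)
  co <- sample_cohort(cohort_config(strata = strata, mode = "endpoint", seed = 29))
  f <- fit_logistic_age_adjusted(co, "tr_below_95", "man")
  spec_p <- bmd_spec("tr_below_95", "logistic", bmdl_method = "profile")
  est <- renalbmd:::logistic_bmd_from_fit(f, spec_p)
  bl_p <- logistic_bmdl(f, spec_p)
  bl_d <- logistic_bmdl(f, spec_d)
  expect_lt(bl_p, est$bmd)
  expect_equal(bl_p, bl_d, tolerance = 0.05)
})

test_that("bmd_table emits skip rows, ordered doses and the ratio law", {
  # study-shaped gate pattern: men CrCl and women eGFR not significant
  fits <- list(
    make_linear_fit("crcl", "man", beta_dose = -1.37, p_dose = 0.118),
    make_linear_fit("crcl", "woman", beta_dose = -1.24, p_dose = 0.002),
    make_linear_fit("egfr", "man", beta_dose = -1.02, sigma = 16.0, p_dose = 0.041),
    make_linear_fit("egfr", "woman", beta_dose = -0.65, sigma = 16.0, p_dose = 0.082),
    make_logistic_fit("tr_below_95", "man", p_dose = 0.022))
  tab <- bmd_table(fits, bmdl_method = "delta")
  skip <- tab$status != "ok"
  expect_identical(sort(unique(paste(tab$endpoint[skip], tab$sex[skip]))),
                   c("crcl man", "egfr woman"))
  expect_true(all(is.na(tab$bmd[skip])))
  ok <- !skip
  expect_true(all(tab$bmdl[ok] <= tab$bmd[ok]))
  hyb <- tab$model == "hybrid_continuous" & ok
  for (key in unique(paste(tab$endpoint[hyb], tab$sex[hyb]))) {
    rows <- hyb & paste(tab$endpoint, tab$sex) == key
    expect_equal(tab$bmd[rows & tab$bmr == 0.10] / tab$bmd[rows & tab$bmr == 0.05],
                 1.674695, tolerance = 1e-3)
  }
})
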