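# Hand-built fit objects for engine tests where the exact coefficients
# (not a data fit) are the point. `se_dose` fills the dose entry of an
# otherwise near-zero covariance; profile-likelihood methods need real
# data, so these are used with the delta / slope_bound methods.

make_linear_fit <- function(endpoint = "crcl", sex = "woman",
                            intercept = 180, beta_dose = -1.24,
                            beta_age = -1.55, sigma = 19.45, n = 62,
                            se_dose = 1e-8, p_dose = 0.002) {
  coefs <- c(intercept = intercept, ucd = beta_dose, age = beta_age)
  vc <- diag(c(1e-16, se_dose^2, 1e-16))
  dimnames(vc) <- list(names(coefs), names(coefs))
  structure(list(endpoint = endpoint, sex = sex, model = "linear",
                 coef = coefs, vcov = vc, sigma = sigma, n = n, df = n - 3L,
                 se = sqrt(diag(vc)),
                 p = c(intercept = 0, ucd = p_dose, age = 0),
                 ci = cbind(lower = coefs - 1, upper = coefs + 1),
                 n_excluded = 0L, data = NULL),
            class = "linear_fit")
}

make_logistic_fit <- function(endpoint = "tr_below_95", sex = "man",
                              intercept = -4.757, beta_dose = log(1.17),
                              beta_age = log(1.04), n = 48,
                              se_dose = 1e-8, p_dose = 0.022) {
  coefs <- c(intercept = intercept, ucd = beta_dose, age = beta_age)
  vc <- diag(c(1e-16, se_dose^2, 1e-16))
  dimnames(vc) <- list(names(coefs), names(coefs))
  structure(list(endpoint = endpoint, sex = sex, model = "logistic",
                 coef = coefs, vcov = vc, n = n, se = sqrt(diag(vc)),
                 p = c(intercept = 0, ucd = p_dose, age = 0.3),
                 ci = cbind(lower = coefs - 1, upper = coefs + 1),
                 or = exp(coefs), or_ci = exp(cbind(lower = coefs - 1, upper = coefs + 1)),
                 converged = TRUE, n_excluded = 0L, data = NULL),
            class = "logistic_fit")
}

# small deterministic subject table exercising every marker path
demo_records <- function() {
  data.frame(
    subject_id = c("A", "B", "C", "D"),
    sex = c("man", "woman", "man", "woman"),
    area = c("polluted", "polluted", "non_polluted", "non_polluted"),
    age = c(70, 72, 65, 60),
    s_cr_jaffe = c(1.2, 1.0, 2.0, 1.1),
    u_cr = c(1.0, 0.5, 1.0, 1.3),
    urine_volume_2h = c(120, 100, 90, 110),
    u_cd_per_L = c(10, 5, 2, 0),
    u_b2mg_per_L = c(0, 5000, 20000, 100),
    s_b2mg = c(2000, 2500, 4000, 1800),
    height = c(160, 150, 170, 148),
    weight = c(60, 50, 70, 52),
    stringsAsFactors = FALSE)
}
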