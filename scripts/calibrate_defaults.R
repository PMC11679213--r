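#!/usr/bin/env Rscript
# Regenerates the frozen default-generator constants in R/cohort-config.R.
#
# The published per-stratum summary tables and dose-response coefficient
# tables are the calibration inputs:
#   - residual SDs are backed out of the printed BMR-5% hybrid BMDs,
#     sigma = BMD5 * |beta_dose| / (z(0.95) - z(0.90));
#     endpoints with no printed BMD (men CrCl, women eGFR: the significance
#     gate fails for them) borrow the other sex's residual SD;
#   - linear intercepts are moment-matched at the sex-pooled means:
#     intercept = mean(endpoint) - beta_dose * mean(U-Cd) - beta_age * mean(age),
#     with mean(U-Cd) the arithmetic lognormal mean GM * exp(ln(GSD)^2 / 2);
#   - logistic intercepts are set so the background prevalence at the
#     reference age of 70 equals the printed backgrounds:
#     intercept = logit(P0) - beta_age * 70.

K5 <- qnorm(0.95) - qnorm(0.90)

# sex-pooled summary values: mean age, U-Cd GM (GSD), endpoint means
men   <- list(age = 69.9, ucd_gm = 5.0, ucd_gsd = 2.5,
              crcl = 69.3, egfr = 58.1, lnb2 = log(600.3))
women <- list(age = 70.5, ucd_gm = 9.0, ucd_gsd = 1.9,
              crcl = 60.9, egfr = 58.1, lnb2 = log(2597.5))
lnmean <- function(s) s$ucd_gm * exp(log(s$ucd_gsd)^2 / 2)

# age-adjusted linear coefficients (beta_dose, beta_age) and printed BMR-5% BMDs
lin <- rbind(
  data.frame(endpoint = "crcl",    sex = "man",   beta_dose = -1.37, beta_age = -1.32, bmd5 = NA),
  data.frame(endpoint = "crcl",    sex = "woman", beta_dose = -1.24, beta_age = -1.55, bmd5 = 5.7),
  data.frame(endpoint = "egfr",    sex = "man",   beta_dose = -1.02, beta_age = -0.97, bmd5 = 5.7),
  data.frame(endpoint = "egfr",    sex = "woman", beta_dose = -0.65, beta_age = -1.56, bmd5 = NA),
  data.frame(endpoint = "ln_b2mg", sex = "man",   beta_dose =  0.30, beta_age =  0.15, bmd5 = 2.8),
  data.frame(endpoint = "ln_b2mg", sex = "woman", beta_dose =  0.18, beta_age =  0.16, bmd5 = 3.6))

lin$sigma <- lin$bmd5 * abs(lin$beta_dose) / K5
# borrow the other sex's sigma where the gate failed (no printed BMD)
for (ep in unique(lin$endpoint)) {
  i <- lin$endpoint == ep
  lin$sigma[i][is.na(lin$sigma[i])] <- lin$sigma[i][!is.na(lin$sigma[i])][1]
}
lin$intercept <- mapply(function(ep, sx, bd, ba) {
  s <- if (sx == "man") men else women
  mu <- switch(ep, crcl = s$crcl, egfr = s$egfr, ln_b2mg = s$lnb2)
  mu - bd * lnmean(s) - ba * s$age
}, lin$endpoint, lin$sex, lin$beta_dose, lin$beta_age)

# logistic coefficients: log odds ratios per unit dose and year of age,
# printed background prevalence rates at the reference age of 70
logi <- rbind(
  data.frame(endpoint = "tr_below_95", sex = "man",   or_dose = 1.17, or_age = 1.04, p0 = 0.118),
  data.frame(endpoint = "tr_below_95", sex = "woman", or_dose = 1.17, or_age = 1.08, p0 = 0.081),
  data.frame(endpoint = "tr_below_90", sex = "man",   or_dose = 1.21, or_age = 1.07, p0 = 0.034),
  data.frame(endpoint = "tr_below_90", sex = "woman", or_dose = 1.12, or_age = 1.09, p0 = 0.066))
logi$beta_dose <- log(logi$or_dose)
logi$beta_age <- log(logi$or_age)
logi$intercept <- qlogis(logi$p0) - logi$beta_age * 70

fmt <- function(x) formatC(x, digits = 6, format = "g")
cat("linear truth defaults:\n")
for (i in seq_len(nrow(lin))) {
  cat(sprintf("  %s %s: intercept=%s beta_dose=%s beta_age=%s residual_sd=%s\n",
              lin$endpoint[i], lin$sex[i], fmt(lin$intercept[i]),
              fmt(lin$beta_dose[i]), fmt(lin$beta_age[i]), fmt(lin$sigma[i])))
}
cat("logistic truth defaults:\n")
for (i in seq_len(nrow(logi))) {
  cat(sprintf("  %s %s: intercept=%s beta_dose=%s beta_age=%s\n",
              logi$endpoint[i], logi$sex[i], fmt(logi$intercept[i]),
              fmt(logi$beta_dose[i]), fmt(logi$beta_age[i])))
}
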