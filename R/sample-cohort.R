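# Cohort generator. Ages are truncated-normal by rejection (>= age_min),
# urinary cadmium is lognormal per stratum on the analysis scale
# (ug/g Cr), and continuous endpoints follow the age-adjusted linear truth
# with Gaussian residuals (ln scale for beta2-MG). In analyte mode the raw
# analytes are back-solved so that derive_panel() reproduces the drawn
# endpoint values exactly; the tubular-reabsorption flags then arise
# mechanistically from the simulated serum/urine chemistry. In endpoint
# mode the flags are direct Bernoulli draws from the logistic truth.

# auxiliary analyte distributions (analyte mode only): plausible values for
# an elderly 1980s Japanese cohort; these do not affect the endpoint truth.
.analyte_aux <- list(
  height = list(man = c(160, 6), woman = c(147, 6)),   # cm, N(mean, sd)
  weight = list(man = c(58, 8),  woman = c(50, 7)),    # kg
  u_cr   = c(gm = 1.0, gsd = 1.6),                     # mg/mL, lognormal
  s_b2mg = c(gm = 2000, gsd = 1.3))                    # ug/L, lognormal

rtrunc_norm <- function(n, mean, sd, lower) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

.truth_row <- function(truth_df, ep, sx) {
  row <- truth_df[truth_df$endpoint == ep & truth_df$sex == sx, ]
  if (nrow(row) != 1L) stop_domain("no truth row for endpoint '%s', sex '%s'", ep, sx)
  row
}

#' Sample a synthetic cohort
#'
#' @param config a [cohort_config()].
#' @return data.frame, one row per subject, with stratum columns (`sex`,
#'   `area`, `age`), exposure `ucd` (ug/g Cr), endpoint values (`crcl`,
#'   `egfr`, `ln_b2mg`, `u_b2mg`, `tr_below_95`, `tr_below_90`) and, in
#'   analyte mode, the raw subject-record columns accepted by
#'   [derive_panel()]. Attribute `truth` holds a list of
#'   [true_dose_response()] objects (background means at the reference age
#'   of 70); attribute `seed` records the seed used.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  strata <- config$strata
  rows <- vector("list", nrow(strata))
  offset <- 0L
  for (k in seq_len(nrow(strata))) {
    st <- strata[k, ]
    if (st$n == 0L) next
    rows[[k]] <- sample_stratum(st, config, offset)
    offset <- offset + st$n
  }
  cohort <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(cohort) <- NULL
  attr(cohort, "truth") <- cohort_truth(config)
  attr(cohort, "seed") <- config$seed
  cohort
}

sample_stratum <- function(st, config, offset) {
  n <- st$n
  sx <- st$sex
  age <- rtrunc_norm(n, st$age_mean, st$age_sd, config$age_min)
  ucd <- stats::rlnorm(n, meanlog = log(st$ucd_gm), sdlog = log(st$ucd_gsd))

  draw_endpoints <- function(idx) {
    out <- list()
    for (ep in c("crcl", "egfr", "ln_b2mg")) {
      tr <- .truth_row(config$linear_truth, ep, sx)
      out[[ep]] <- tr$intercept + tr$beta_dose * ucd[idx] + tr$beta_age * age[idx] +
        stats::rnorm(length(idx), 0, tr$residual_sd)
    }
    out
  }

  ep <- draw_endpoints(seq_len(n))
  base <- data.frame(
    subject_id = sprintf("S%05d", offset + seq_len(n)),
    sex = sx, area = st$area, age = age, ucd = ucd,
    crcl = ep$crcl, egfr = ep$egfr, ln_b2mg = ep$ln_b2mg,
    stringsAsFactors = FALSE)
  base$u_b2mg <- exp(base$ln_b2mg)

  if (config$mode == "endpoint") {
    for (flag in c("tr_below_95", "tr_below_90")) {
      tr <- .truth_row(config$logistic_truth, flag, sx)
      p <- stats::plogis(tr$intercept + tr$beta_dose * ucd + tr$beta_age * age)
      base[[flag]] <- stats::rbinom(n, 1, p) == 1
    }
    return(base)
  }

  # analyte mode: back-solve raw analytes; resample rows whose drawn
  # endpoints imply impossible chemistry (non-positive CrCl or eGFR)
  aux <- .analyte_aux
  base$height <- rtrunc_norm(n, aux$height[[sx]][1], aux$height[[sx]][2], 100)
  base$weight <- rtrunc_norm(n, aux$weight[[sx]][1], aux$weight[[sx]][2], 25)
  base$u_cr <- stats::rlnorm(n, log(aux$u_cr["gm"]), log(aux$u_cr["gsd"]))
  base$s_b2mg <- stats::rlnorm(n, log(aux$s_b2mg["gm"]), log(aux$s_b2mg["gsd"]))

  max_retries <- 100L
  for (try in seq_len(max_retries + 1L)) {
    bad <- which(base$crcl <= 0 | base$egfr <= 0)
    if (!length(bad)) break
    if (try > max_retries) {
      stop_domain("analyte back-solve failed after %d retries (%d records)",
                  max_retries, length(bad))
    }
    redraw <- draw_endpoints(bad)
    base$crcl[bad] <- redraw$crcl
    base$egfr[bad] <- redraw$egfr
    base$ln_b2mg[bad] <- redraw$ln_b2mg
    base$u_b2mg[bad] <- exp(redraw$ln_b2mg)
  }

  # invert the eGFR equation for serum creatinine (enzymatic), add the
  # Jaffe offset back; invert the clearance formula for the 2-h volume
  sex_factor <- ifelse(sx == "woman", 0.739, 1)
  s_cr_enz <- (base$egfr / (194 * base$age^(-0.287) * sex_factor))^(-1 / 1.094)
  base$s_cr_jaffe <- s_cr_enz + 0.2
  bsa <- bsa_du_bois(base$height, base$weight)
  base$urine_volume_2h <- base$crcl * base$s_cr_jaffe * 0.01 * 120 * bsa /
    (1.73 * base$u_cr)
  base$u_cd_per_L <- base$ucd * base$u_cr
  base$u_b2mg_per_L <- base$u_b2mg * base$u_cr

  tr_pct <- tr_b2mg(base$u_b2mg_per_L, base$s_cr_jaffe, base$s_b2mg, base$u_cr)
  base$tr_b2mg <- tr_pct
  base$tr_below_95 <- tr_pct < 95
  base$tr_below_90 <- tr_pct < 90
  base
}

cohort_truth <- function(config, reference_age = 70) {
  out <- list()
  for (i in seq_len(nrow(config$linear_truth))) {
    tr <- config$linear_truth[i, ]
    adv <- if (tr$beta_dose < 0) "low_is_adverse" else "high_is_adverse"
    key <- paste(tr$endpoint, tr$sex, sep = ".")
    out[[key]] <- true_dose_response(
      tr$endpoint, tr$beta_dose, tr$residual_sd, adv,
      background_mean = tr$intercept + tr$beta_age * reference_age)
  }
  out
}
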