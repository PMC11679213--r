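# Synthetic-cohort configuration. The defaults encode the published study
# structure: four strata (sex x area) with their sample sizes, age
# means/SDs (truncated at 50 y) and lognormal urinary-cadmium GM/GSD, plus
# the age-adjusted dose-response truth per endpoint and sex. Intercepts and
# residual SDs were calibrated once against the published summary tables
# (see scripts/calibrate_defaults.R) and are frozen here.

.default_strata <- data.frame(
  sex  = c("man", "woman", "man", "woman"),
  area = c("polluted", "polluted", "non_polluted", "non_polluted"),
  n        = c(30, 44, 18, 18),
  age_mean = c(74.1, 73.2, 62.9, 63.9),
  age_sd   = c(7.8, 7.2, 9.9, 9.0),
  ucd_gm   = c(9.0, 11.6, 1.9, 4.8),
  ucd_gsd  = c(1.6, 1.7, 1.7, 1.5),
  stringsAsFactors = FALSE)

.default_linear_truth <- data.frame(
  endpoint  = rep(c("crcl", "egfr", "ln_b2mg"), each = 2),
  sex       = rep(c("man", "woman"), 3),
  intercept = c(171.991, 183.888, 133.663, 175.268, -6.37004, -5.40825),
  beta_dose = c(-1.37, -1.24, -1.02, -0.65, 0.30, 0.18),
  beta_age  = c(-1.32, -1.55, -0.97, -1.56, 0.15, 0.16),
  residual_sd = c(19.4549, 19.4549, 16.0032, 16.0032, 2.31213, 1.78364),
  stringsAsFactors = FALSE)

.default_logistic_truth <- data.frame(
  endpoint  = rep(c("tr_below_95", "tr_below_90"), each = 2),
  sex       = rep(c("man", "woman"), 2),
  intercept = c(-4.75696, -7.81611, -8.08291, -8.68226),
  beta_dose = c(0.157004, 0.157004, 0.19062, 0.113329),
  beta_age  = c(0.0392207, 0.076961, 0.0676586, 0.0861777),
  stringsAsFactors = FALSE)

#' Build a synthetic-cohort configuration
#'
#' @param strata data.frame with columns `sex`, `area`, `n`, `age_mean`,
#'   `age_sd`, `ucd_gm`, `ucd_gsd`; defaults to the four study strata
#'   (30/44 exposed men/women, 18/18 controls).
#' @param scale multiplier applied to every stratum size (rounded).
#' @param linear_truth per endpoint x sex: `intercept`, `beta_dose` (per
#'   ug/g Cr), `beta_age` (per year), `residual_sd`.
#' @param logistic_truth per flag endpoint x sex: `intercept`, `beta_dose`,
#'   `beta_age` on the log-odds scale.
#' @param mode `"endpoint"` draws endpoint values directly from the truth
#'   models; `"analyte"` back-solves raw analytes so that [derive_panel()]
#'   reproduces the drawn endpoints.
#' @param age_min lower truncation for ages (study enrolled over-50s).
#' @param seed integer seed; identical configs give identical cohorts.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(strata = .default_strata,
                          scale = 1,
                          linear_truth = .default_linear_truth,
                          logistic_truth = .default_logistic_truth,
                          mode = c("analyte", "endpoint"),
                          age_min = 50,
                          seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(strata$n >= 0), all(strata$ucd_gsd > 1),
            all(strata$age_sd > 0), scale > 0,
            all(linear_truth$residual_sd > 0))
  strata$n <- as.integer(round(strata$n * scale))
  structure(
    list(strata = strata, linear_truth = linear_truth,
         logistic_truth = logistic_truth, mode = mode,
         age_min = age_min, seed = as.integer(seed)),
    class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort config (", x$mode, " mode, seed ", x$seed, ")\n", sep = "")
  cat("Strata:\n"); print(x$strata, row.names = FALSE)
  invisible(x)
}

#' Ground-truth dose-response for a continuous endpoint
#'
#' Carries what is needed to compute the true hybrid BMD of a simulated
#' endpoint: the dose slope, residual SD, adversity direction and the
#' age-adjusted background mean at the reference age.
#'
#' @param endpoint endpoint id (`"crcl"`, `"egfr"`, `"ln_b2mg"`).
#' @param beta_dose true dose slope (endpoint units per ug/g Cr).
#' @param residual_sd true residual SD (> 0).
#' @param adversity `"low_is_adverse"` or `"high_is_adverse"`.
#' @param background_mean endpoint mean at dose 0 and the reference age.
#' @return object of class `true_dose_response`.
#' @export
true_dose_response <- function(endpoint, beta_dose, residual_sd,
                               adversity = c("low_is_adverse", "high_is_adverse"),
                               background_mean = NA_real_) {
  adversity <- match.arg(adversity)
  if (!is.finite(residual_sd) || residual_sd <= 0) {
    stop_domain("true_dose_response: residual_sd must be > 0")
  }
  structure(list(endpoint = endpoint, beta_dose = beta_dose,
                 residual_sd = residual_sd, adversity = adversity,
                 background_mean = background_mean),
            class = "true_dose_response")
}

#' Closed-form true hybrid BMD for a known dose-response
#'
#' Under the hybrid model with background adverse probability `p0` and an
#' additional-risk benchmark response `bmr`, the benchmark dose is
#' `(z(1 - p0) - z(1 - p0 - bmr)) * sigma / |beta|`, independent of the
#' cut-off location. Used as the oracle in parameter-recovery and coverage
#' simulations.
#'
#' @param truth a [true_dose_response()] object.
#' @param p0 background adverse probability, in (0, 1).
#' @param bmr benchmark response (additional risk), with `p0 + bmr < 1`.
#' @return benchmark dose in ug/g Cr.
#' @examples
#' tr <- true_dose_response("crcl", -1, 1)
#' true_bmd(tr, 0.05, 0.05) # 0.3633
#' @export
true_bmd <- function(truth, p0, bmr) {
  stopifnot(inherits(truth, "true_dose_response"))
  if (!(p0 > 0 && bmr >= 0 && p0 + bmr < 1)) {
    stop_domain("true_bmd: need 0 < p0, bmr >= 0, p0 + bmr < 1")
  }
  b <- truth$beta_dose
  adverse_sign <- if (truth$adversity == "low_is_adverse") -1 else 1
  if (b == 0 || sign(b) != adverse_sign) {
    stop_domain("true_bmd: beta_dose must be nonzero and adverse-signed (%s)",
                truth$adversity)
  }
  (stats::qnorm(1 - p0) - stats::qnorm(1 - p0 - bmr)) * truth$residual_sd / abs(b)
}

#' Residual SD that yields a given hybrid BMD
#'
#' Inverts the closed-form hybrid BMD: `sigma = bmd * |beta| / K` with
#' `K = z(1 - p0) - z(1 - p0 - bmr)`. Used to calibrate generator defaults
#' against published benchmark doses.
#'
#' @param target_bmd benchmark dose to reproduce, ug/g Cr.
#' @param beta_dose dose slope (adverse-signed or absolute).
#' @param p0 background adverse probability.
#' @param bmr benchmark response (additional risk).
#' @return residual SD in endpoint units.
#' @export
calibrate_residual_sd <- function(target_bmd, beta_dose, p0 = 0.05, bmr = 0.05) {
  K <- stats::qnorm(1 - p0) - stats::qnorm(1 - p0 - bmr)
  target_bmd * abs(beta_dose) / K
}
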