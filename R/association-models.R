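# Age-adjusted dose-response models, stratified by sex: ordinary least
# squares for continuous endpoints (CrCl, eGFR, naturally log-transformed
# urinary beta2-MG) and binomial logistic regression for the dichotomized
# tubular-reabsorption flags. Confidence intervals are t-based for OLS
# (the study n is small) and normal Wald for logistic, matching standard
# epidemiology software output.

.continuous_endpoints <- c("crcl", "egfr", "ln_b2mg")
.flag_endpoints <- c("tr_below_95", "tr_below_90")

endpoint_column <- function(data, endpoint) {
  if (endpoint == "ln_b2mg") {
    if ("ln_b2mg" %in% names(data)) return(data$ln_b2mg)
    if ("u_b2mg" %in% names(data)) {
      y <- data$u_b2mg
      y[!is.na(y) & y <= 0] <- NA   # no detection-limit policy: excluded
      return(suppressWarnings(log(y)))
    }
    stop_domain("no ln_b2mg or u_b2mg column for endpoint 'ln_b2mg'")
  }
  if (!endpoint %in% names(data)) stop_domain("no column '%s' in data", endpoint)
  data[[endpoint]]
}

#' Fit the age-adjusted linear dose-response model for one sex
#'
#' Ordinary least squares of the endpoint on urinary cadmium (ug/g Cr) and
#' age, restricted to one sex. Urinary beta2-MG is naturally
#' log-transformed; non-positive values are excluded (with a count) since
#' no detection-limit policy is defined. Records with any missing model
#' variable are dropped listwise.
#'
#' @param data cohort data.frame with columns `sex`, `age`, `ucd` and the
#'   endpoint (for `ln_b2mg`, either an `ln_b2mg` or a positive `u_b2mg`
#'   column).
#' @param endpoint one of `"crcl"`, `"egfr"`, `"ln_b2mg"`.
#' @param sex `"man"` or `"woman"`.
#' @return object of class `linear_fit`: coefficients
#'   (`intercept`, `ucd`, `age`), covariance, `sigma` (residual SD with
#'   denominator n - 3), `n`, `df`, two-sided p-values, t-based 95% CIs,
#'   excluded-record count, and the model frame (used by profile-likelihood
#'   BMDL).
#' @export
fit_linear_age_adjusted <- function(data, endpoint = .continuous_endpoints,
                                    sex = c("man", "woman")) {
  endpoint <- match.arg(endpoint)
  sex <- match.arg(sex)
  y_all <- endpoint_column(data, endpoint)
  keep <- data$sex == sex
  y <- y_all[keep]; ucd <- data$ucd[keep]; age <- data$age[keep]
  complete <- is.finite(y) & is.finite(ucd) & is.finite(age)
  n_excluded <- sum(!complete)
  y <- y[complete]; ucd <- ucd[complete]; age <- age[complete]
  n <- length(y)
  if (n < 10L) stop_domain("fit_linear_age_adjusted: only %d usable records (< 10)", n)
  X <- cbind(intercept = 1, ucd = ucd, age = age)
  qrX <- qr(X)
  if (qrX$rank < 3L) stop_domain("fit_linear_age_adjusted: rank-deficient design")

  fit <- stats::lm(y ~ ucd + age)
  sm <- summary(fit)
  coefs <- stats::coef(fit)
  names(coefs) <- c("intercept", "ucd", "age")
  vc <- stats::vcov(fit)
  dimnames(vc) <- list(names(coefs), names(coefs))
  df <- n - 3L
  se <- sqrt(diag(vc))
  tcrit <- stats::qt(0.975, df)
  ci <- cbind(lower = coefs - tcrit * se, upper = coefs + tcrit * se)
  pvals <- 2 * stats::pt(abs(coefs / se), df, lower.tail = FALSE)

  structure(list(
    endpoint = endpoint, sex = sex, model = "linear",
    coef = coefs, vcov = vc, sigma = sm$sigma, n = n, df = df,
    se = se, p = pvals, ci = ci, n_excluded = n_excluded,
    data = data.frame(y = y, ucd = ucd, age = age)),
    class = "linear_fit")
}

#' Fit the age-adjusted logistic dose-response model for one sex
#'
#' Binomial logistic regression (maximum likelihood via iteratively
#' reweighted least squares, convergence tolerance 1e-12, at most 100
#' iterations) of a tubular-reabsorption flag on urinary cadmium and age.
#' Degenerate outcomes (a single class) and complete separation raise
#' explicit errors naming the endpoint.
#'
#' @param data cohort data.frame with columns `sex`, `age`, `ucd` and the
#'   logical/0-1 flag column.
#' @param flag `"tr_below_95"` or `"tr_below_90"`.
#' @param sex `"man"` or `"woman"`.
#' @return object of class `logistic_fit`: log-odds coefficients,
#'   covariance, odds ratios with normal Wald 95% CIs, p-values,
#'   `converged`, and the model frame.
#' @export
fit_logistic_age_adjusted <- function(data, flag = .flag_endpoints,
                                      sex = c("man", "woman")) {
  flag <- match.arg(flag)
  sex <- match.arg(sex)
  if (!flag %in% names(data)) stop_domain("no column '%s' in data", flag)
  keep <- data$sex == sex
  y <- as.numeric(data[[flag]][keep])
  ucd <- data$ucd[keep]; age <- data$age[keep]
  complete <- is.finite(y) & is.finite(ucd) & is.finite(age)
  n_excluded <- sum(!complete)
  y <- y[complete]; ucd <- ucd[complete]; age <- age[complete]
  n <- length(y)
  if (n < 10L) stop_domain("fit_logistic_age_adjusted: only %d usable records (< 10)", n)
  if (length(unique(y)) < 2L) {
    stop_domain("fit_logistic_age_adjusted: outcome '%s' (%s) has a single class",
                flag, sex)
  }

  fit <- suppressWarnings(stats::glm(
    y ~ ucd + age, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  if (!fit$converged) {
    stop_domain("fit_logistic_age_adjusted: no convergence in 100 iterations for '%s' (%s)",
                flag, sex)
  }
  mu <- stats::fitted(fit)
  # complete separation: fitted probabilities collapse onto the outcomes
  if (all(abs(mu - y) < 1e-6)) {
    stop_domain("fit_logistic_age_adjusted: complete separation for '%s' (%s)",
                flag, sex)
  }
  coefs <- stats::coef(fit)
  names(coefs) <- c("intercept", "ucd", "age")
  vc <- stats::vcov(fit)
  dimnames(vc) <- list(names(coefs), names(coefs))
  se <- sqrt(diag(vc))
  zcrit <- stats::qnorm(0.975)
  ci <- cbind(lower = coefs - zcrit * se, upper = coefs + zcrit * se)
  pvals <- 2 * stats::pnorm(abs(coefs / se), lower.tail = FALSE)

  structure(list(
    endpoint = flag, sex = sex, model = "logistic",
    coef = coefs, vcov = vc, n = n, se = se, p = pvals,
    ci = ci, or = exp(coefs), or_ci = exp(ci),
    converged = fit$converged, n_excluded = n_excluded,
    data = data.frame(y = y, ucd = ucd, age = age)),
    class = "logistic_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Age-adjusted linear fit: %s (%s), n = %d, sigma = %.3f\n",
              x$endpoint, x$sex, x$n, x$sigma))
  tab <- data.frame(B = x$coef, lower = x$ci[, "lower"], upper = x$ci[, "upper"],
                    p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Age-adjusted logistic fit: %s (%s), n = %d\n",
              x$endpoint, x$sex, x$n))
  tab <- data.frame(OR = x$or, lower = x$or_ci[, "lower"],
                    upper = x$or_ci[, "upper"], p = x$p)
  print(round(tab, 4))
  invisible(x)
}

#' Significance gate on the dose coefficient
#'
#' Benchmark doses are only computed when urinary cadmium is statistically
#' significant in the association model (two-sided p < 0.05); otherwise the
#' endpoint is skipped.
#'
#' @param fit a `linear_fit` or `logistic_fit`.
#' @return `"proceed"` or `"skip"`.
#' @export
significance_gate <- function(fit) {
  stopifnot(inherits(fit, c("linear_fit", "logistic_fit")))
  if (unname(fit$p["ucd"]) < 0.05) "proceed" else "skip"
}
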